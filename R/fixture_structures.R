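# Programmatic toy geometries for the worked examples: iodoform photolysis
# species (CHI3, iso-CHI2I-I, CHI2 radical, I atom), cyclohexane, and
# cis/trans azobenzene with its 4,4'-dibromo analogue. Built from standard
# bond lengths/angles; these are synthetic fixtures for simulation and
# testing, not refined experimental geometries.

deg <- function(x) x * pi / 180

rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Iodoform (CHI3) toy geometry
#' @return A `molecular_structure` (5 atoms).
#' @export
chi3_structure <- function() {
  th <- deg(107.6)  # H-C-I angle
  iodines <- t(sapply(deg(c(0, 120, 240)), function(phi)
    2.14 * c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))))
  molecular_structure(
    c("C", "H", "I", "I", "I"),
    rbind(c(0, 0, 0), c(0, 0, 1.09), iodines),
    name = "CHI3")
}

#' iso-CHI2I (CHI2-I-I isomer) toy geometry
#' @return A `molecular_structure` (5 atoms, same formula as CHI3).
#' @export
chi2i_structure <- function() {
  th <- deg(107.6)
  ia <- 2.14 * c(sin(th), 0, cos(th))
  ib <- 2.16 * c(sin(th) * cos(deg(180)), sin(th) * sin(deg(180)), cos(th))
  # terminal I on ib: I-I 3.0 Angstrom, C-I-I angle ~115 degrees
  u <- ib / sqrt(sum(ib^2))                       # C -> I_b direction
  perp <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
  perp <- perp / sqrt(sum(perp^2))
  ic <- ib + 3.0 * (-cos(deg(115)) * u + sin(deg(115)) * perp)
  molecular_structure(
    c("C", "H", "I", "I", "I"),
    rbind(c(0, 0, 0), c(0, 0, 1.09), ia, ib, ic),
    name = "CHI2I")
}

#' CHI2 radical toy geometry
#' @return A `molecular_structure` (4 atoms).
#' @export
chi2_structure <- function() {
  th <- deg(115)
  molecular_structure(
    c("C", "H", "I", "I"),
    rbind(c(0, 0, 0), c(0, 0, 1.08),
          2.12 * c(sin(th) * cos(deg(90)),  sin(th) * sin(deg(90)),  cos(th)),
          2.12 * c(sin(th) * cos(deg(270)), sin(th) * sin(deg(270)), cos(th))),
    name = "CHI2")
}

#' Free iodine atom
#' @return A single-atom `molecular_structure`.
#' @export
iodine_structure <- function() {
  molecular_structure("I", matrix(0, 1, 3), name = "I")
}

#' Cyclohexane (chair) toy geometry
#' @return A `molecular_structure` (18 atoms).
#' @export
cyclohexane_structure <- function() {
  cc <- 1.526; d <- 0.25; ch <- 1.09
  a <- sqrt(cc^2 - (2 * d)^2)
  elements <- character(0); coords <- NULL
  for (i in 0:5) {
    th <- deg(60 * i); sgn <- (-1)^i
    c_i <- c(a * cos(th), a * sin(th), sgn * d)
    ax <- c_i + c(0, 0, sgn * ch)                       # axial H
    eqdir <- c(cos(th), sin(th), -sgn * 0.55)
    eq <- c_i + ch * eqdir / sqrt(sum(eqdir^2))         # equatorial H
    elements <- c(elements, "C", "H", "H")
    coords <- rbind(coords, c_i, ax, eq)
  }
  molecular_structure(elements, coords, name = "cyclohexane")
}

# Phenyl ring attached at its ipso carbon.
#  attach: ipso C position; u: unit vector from the substituent toward the
#  ring; normal: ring-plane normal. Para position may carry H or Br.
phenyl_ring <- function(attach, u, normal, para = "H") {
  cc <- 1.394; ch <- 1.08
  cx <- if (para == "Br") 1.90 else ch
  center <- attach + cc * u
  w0 <- -u                                   # center -> ipso
  elements <- character(0); coords <- NULL
  for (k in 0:5) {
    v <- as.vector(rotation_about(normal, deg(60 * k)) %*% w0)
    ck <- center + cc * v
    elements <- c(elements, "C"); coords <- rbind(coords, ck)
    if (k > 0) {
      el <- if (k == 3) para else "H"
      bl <- if (k == 3) cx else ch
      elements <- c(elements, el); coords <- rbind(coords, ck + bl * v)
    }
  }
  list(elements = elements, coords = coords)
}

#' Azobenzene toy geometry
#'
#' Planar trans isomer or a twisted cis isomer, built from standard aromatic
#' bond lengths (N=N 1.25, C-N 1.43, C-C 1.394 Angstrom, C-N=N 114 degrees).
#'
#' @param isomer `"trans"` or `"cis"`.
#' @param para Substituent at both para positions: `"H"` (azobenzene) or
#'   `"Br"` (4,4'-dibromoazobenzene; the only change is the two para atoms).
#' @return A `molecular_structure` (24 atoms).
#' @export
azobenzene_structure <- function(isomer = c("trans", "cis"), para = "H") {
  isomer <- match.arg(isomer)
  n1 <- c(0, 0, 0); n2 <- c(1.25, 0, 0)
  ang <- deg(114)
  dir_a <- c(cos(ang), sin(ang), 0)
  if (isomer == "trans") {
    dir_b <- c(cos(-(pi - ang)), sin(-(pi - ang)), 0)
    norm_a <- norm_b <- c(0, 0, 1)
  } else {
    dir_b <- c(cos(pi - ang), sin(pi - ang), 0)
    # twist the rings out of plane to mimic the non-planar cis geometry
    norm_a <- as.vector(rotation_about(dir_a,  deg(53)) %*% c(0, 0, 1))
    norm_b <- as.vector(rotation_about(dir_b, -deg(53)) %*% c(0, 0, 1))
  }
  ring_a <- phenyl_ring(n1 + 1.43 * dir_a, dir_a, norm_a, para = para)
  ring_b <- phenyl_ring(n2 + 1.43 * dir_b, dir_b, norm_b, para = para)
  nm <- paste0(if (para == "Br") "Br2AB_" else "AB_", isomer)
  molecular_structure(c("N", "N", ring_a$elements, ring_b$elements),
                      rbind(n1, n2, ring_a$coords, ring_b$coords),
                      name = nm)
}

#' 4,4'-dibromoazobenzene toy geometry
#'
#' Identical to [azobenzene_structure()] except that the two para hydrogens
#' are replaced by bromine (heavy-atom labelling), leaving every other atom
#' untouched.
#'
#' @inheritParams azobenzene_structure
#' @return A `molecular_structure` (24 atoms).
#' @export
dibromoazobenzene_structure <- function(isomer = c("trans", "cis")) {
  azobenzene_structure(match.arg(isomer), para = "Br")
}
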