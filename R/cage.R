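# Solute-solvent cross (cage) term. The pair-distribution function between
# each solute element i and solvent element j is either the trapezoidal
# hard-sphere approximation or a user-supplied RDF; the cage intensity is
# its sine Fourier transform
#   S_cage(q) = sum_i sum_j f_i f_j N_i n_j
#               int 4 pi r^2 [g_ij(r) - 1] sin(qr)/(qr) dr,
# evaluated in closed form on each linear segment of g(r), which is exact
# for the trapezoid and for linearly interpolated file RDFs.

#' Pair-distribution function container
#'
#' @param r Non-decreasing distance grid starting at or above 0 (Angstrom).
#' @param g Pair-distribution values (dimensionless, >= 0); `g` is taken to
#'   be 1 (bulk) beyond the last grid point, and is linearly interpolated
#'   between points.
#' @param element_i,element_j Solute and solvent element symbols.
#' @return An object of class `pair_distribution`.
#' @export
pair_distribution <- function(r, g, element_i, element_j) {
  r <- as.double(r); g <- as.double(g)
  if (length(r) != length(g) || length(r) < 2) stop("r and g must align, length >= 2")
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be finite and >= 0")
  if (any(diff(r) < 0)) stop("r must be non-decreasing")
  if (any(!is.finite(g)) || any(g < 0)) stop("g must be finite and >= 0")
  structure(list(r = r, g = g,
                 element_i = element_i, element_j = element_j),
            class = "pair_distribution")
}

#' Trapezoidal hard-sphere pair-distribution function
#'
#' g(r) = 0 below the van der Waals contact `v_ij` (hard-sphere
#' impenetrability), 1 beyond `v_ij + r_s` (bulk), and a linear ramp in
#' between, `r_s` being the molecular radius of the solute. With `r_s = 0`
#' the trapezoid degenerates to a step function.
#'
#' @param v_ij Contact distance (Angstrom), > 0; see [combined_vdw()].
#' @param r_s Solute molecular radius (Angstrom), >= 0; see
#'   [molecular_radius()].
#' @param element_i,element_j Element symbols carried for bookkeeping.
#' @return A `pair_distribution` with knots at the contact and bulk radii.
#' @export
hard_sphere_gr <- function(v_ij, r_s, element_i = "", element_j = "") {
  if (!is.numeric(v_ij) || v_ij <= 0) stop("v_ij must be > 0")
  if (!is.numeric(r_s) || r_s < 0) stop("r_s must be >= 0")
  pair_distribution(c(0, v_ij, v_ij + r_s), c(0, 0, 1), element_i, element_j)
}

#' Evaluate a pair-distribution function
#' @param pd A `pair_distribution`.
#' @param r Distances (Angstrom).
#' @return g(r), with g = 1 beyond the tabulated range.
#' @export
eval_gr <- function(pd, r) {
  stats::approx(pd$r, pd$g, xout = r, rule = 2,
                yright = pd$g[length(pd$g)], ties = "ordered")$y
}

#' Load a pair-distribution function from a two-column text file
#'
#' Whitespace-delimited `r g` rows, `#` comments. The excess `g - 1` is
#' assumed zero beyond the last tabulated r.
#'
#' @param path File path.
#' @param element_i,element_j Element symbols the RDF belongs to.
#' @return A `pair_distribution` interchangeable with [hard_sphere_gr()]
#'   output.
#' @export
load_rdf <- function(path, element_i = "", element_j = "") {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, comment.char = "#"),
    error = function(e) stop("RDF parse error in ", path, ": ", conditionMessage(e)))
  if (!nrow(tab) || ncol(tab) < 2)
    stop("RDF parse error in ", path, ": need two numeric columns (r, g)")
  r <- tab[[1]]; g <- tab[[2]]
  if (any(diff(r) < 0)) stop("RDF parse error in ", path, ": r not monotone")
  if (any(g < 0)) stop("RDF parse error in ", path, ": negative g values")
  pair_distribution(r, g, element_i, element_j)
}

# int_{r0}^{r1} (a + b r) r^2 sin(qr)/(qr) dr in closed form, vectorized
# over q. Antiderivatives:
#   A1 = int r sin(qr) dr   = sin(qr)/q^2 - r cos(qr)/q
#   A2 = int r^2 sin(qr) dr = 2 r sin(qr)/q^2 + (2/q^3 - r^2/q) cos(qr)
segment_sineft <- function(q, r0, r1, a, b) {
  if (r1 <= r0) return(numeric(length(q)))
  small <- q < 1e-8
  out <- numeric(length(q))
  if (any(!small)) {
    qq <- q[!small]
    A1 <- function(r) sin(qq * r) / qq^2 - r * cos(qq * r) / qq
    A2 <- function(r) 2 * r * sin(qq * r) / qq^2 +
      (2 / qq^3 - r^2 / qq) * cos(qq * r)
    out[!small] <- (a * (A1(r1) - A1(r0)) + b * (A2(r1) - A2(r0))) / qq
  }
  if (any(small))   # q -> 0 limit: int (a r^2 + b r^3) dr
    out[small] <- a * (r1^3 - r0^3) / 3 + b * (r1^4 - r0^4) / 4
  out
}

# int 4 pi r^2 [g(r) - 1] sinc(qr) dr for piecewise-linear g with g == 1
# beyond the last grid point (compact-support excess, no windowing needed)
excess_sine_transform <- function(pd, q) {
  total <- numeric(length(q))
  r <- pd$r; gm1 <- pd$g - 1
  for (k in seq_len(length(r) - 1)) {
    r0 <- r[k]; r1 <- r[k + 1]
    if (r1 <= r0) next
    b <- (gm1[k + 1] - gm1[k]) / (r1 - r0)
    a <- gm1[k] - b * r0
    total <- total + segment_sineft(q, r0, r1, a, b)
  }
  4 * pi * total
}

#' Solvent composition and number density
#'
#' @param counts Named integer vector: atoms of each element per solvent
#'   molecule (e.g. `c(C = 6, H = 12)` for cyclohexane).
#' @param number_density Solvent molecules per cubic Angstrom; either given
#'   directly or derived from `mass_density` (g/mL) and `molar_mass`
#'   (g/mol).
#' @param mass_density,molar_mass Used when `number_density` is missing.
#' @return An object of class `solvent_composition`.
#' @examples
#' solvent_composition(c(C = 6, H = 12), mass_density = 0.779,
#'                     molar_mass = 84.16)
#' @export
solvent_composition <- function(counts, number_density = NULL,
                                mass_density = NULL, molar_mass = NULL) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of per-molecule atom counts")
  check_element(names(counts))
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("atom counts must be positive integers")
  if (is.null(number_density)) {
    if (is.null(mass_density) || is.null(molar_mass))
      stop("give number_density, or mass_density with molar_mass")
    # molecules / A^3 = (g/cm^3) / (g/mol) * N_A / 1e24
    number_density <- mass_density / molar_mass * 6.02214076e23 / 1e24
  }
  if (number_density <= 0) stop("number density must be > 0")
  structure(list(counts = counts, number_density = number_density),
            class = "solvent_composition")
}

#' Cage (solute-solvent cross) intensity of one solute species
#'
#' Sums the excess sine Fourier transforms over every solute-element /
#' solvent-element pair, weighted by the form factors, the solute atom
#' counts, and the solvent per-element number density. By default each pair
#' uses the trapezoidal hard-sphere g(r) built from the pair contact
#' distance and the solute molecular radius; user RDFs (e.g. from MD) may
#' be supplied instead.
#'
#' @param solute A `molecular_structure` (or list of fragments, each cage
#'   contribution computed with its own molecular radius).
#' @param solvent A [solvent_composition()].
#' @param q Momentum-transfer grid (1/Angstrom).
#' @param pdfs Optional list of `pair_distribution` objects, one per
#'   (solute element, solvent element) pair present; element labels must be
#'   set. Default: hard-sphere trapezoids.
#' @return A `scattering_curve`, e.u. per solute molecule.
#' @export
cage_intensity <- function(solute, solvent, q, pdfs = NULL) {
  stopifnot(inherits(solvent, "solvent_composition"))
  if (inherits(solute, "molecular_structure")) solute <- list(solute)
  total <- numeric(length(q))
  for (frag in solute) {
    check_element(frag$elements)
    r_s <- molecular_radius(frag)
    n_i <- table(frag$elements)
    for (ei in names(n_i)) {
      f_i <- form_factor(ei, q)
      for (ej in names(solvent$counts)) {
        pd <- if (is.null(pdfs)) {
          hard_sphere_gr(combined_vdw(ei, ej), r_s, ei, ej)
        } else {
          hit <- Filter(function(p) p$element_i == ei && p$element_j == ej, pdfs)
          if (!length(hit))
            stop("missing pair distribution for pair (", ei, ", ", ej, ")")
          hit[[1]]
        }
        n_j <- solvent$number_density * solvent$counts[[ej]]   # atoms / A^3
        total <- total + as.numeric(n_i[[ei]]) * n_j * f_i *
          form_factor(ej, q) * excess_sine_transform(pd, q)
      }
    }
  }
  scattering_curve(q, total, normalization = "per_solute_molecule")
}

#' Cage difference signal of a reaction channel
#'
#' \deqn{\Delta S_{cage}(q) = \frac{c_{solu}}{c_{solv}} \, r_{str}
#'   \left[\sum_p \phi_p S_{cage,p}(q) - S_{cage,r}(q)\right]}
#' with each species' pair-distribution functions built from its own
#' molecular radius and element inventory.
#'
#' @inheritParams solute_difference
#' @param solvent A [solvent_composition()].
#' @return A `scattering_curve`, e.u. per solvent molecule.
#' @export
cage_difference <- function(channel, solvent, c_solu, c_solv, q) {
  stopifnot(inherits(channel, "reaction_channel"))
  if (c_solu <= 0 || c_solv <= 0) stop("concentrations must be positive")
  diff <- -cage_intensity(channel$reactant, solvent, q)$intensity
  for (p in channel$products)
    diff <- diff + p$fraction * cage_intensity(p$fragments, solvent, q)$intensity
  scattering_curve(q, (c_solu / c_solv) * channel$r_str * diff,
                   normalization = "per_solvent_molecule")
}
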