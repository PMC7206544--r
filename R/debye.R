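# Solute-only signal: orientationally averaged elastic scattering of one
# molecule via the Debye equation, and the reactant-to-product difference
# scaled to one mole of solvent.

sinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small]^2 / 6
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

#' Debye scattering intensity of one molecule
#'
#' \deqn{S(q) = \sum_m \sum_n f_m(q) f_n(q) \frac{\sin(q r_{nm})}{q r_{nm}}}
#' over all atom pairs including the self (m = n) terms, so that
#' \eqn{S(0) = (\sum_n Z_n)^2} up to form-factor fit accuracy. Assumes
#' randomly oriented molecules (isotropic average).
#'
#' @param s A `molecular_structure`.
#' @param q Momentum-transfer grid (1/Angstrom), values >= 0.
#' @return A `scattering_curve` in e.u. per solute molecule.
#' @examples
#' s <- chi3_structure()
#' S <- debye_intensity(s, default_q_grid())
#' @export
debye_intensity <- function(s, q) {
  check_element(s$elements)
  k <- n_atoms(s)
  f <- vapply(s$elements, function(el) form_factor(el, q), numeric(length(q)))
  f <- matrix(f, nrow = length(q))   # nq x k, per-atom form factors
  S <- rowSums(f^2)                  # self terms
  if (k > 1) {
    d <- as.matrix(stats::dist(s$coords))
    for (m in 1:(k - 1)) for (n in (m + 1):k) {
      S <- S + 2 * f[, m] * f[, n] * sinc(q * d[m, n])
    }
  }
  scattering_curve(q, S, normalization = "per_solute_molecule")
}

#' Define a product species of a reaction channel
#'
#' A product may consist of several fragments (e.g. a dissociation into a
#' radical pair); fragment intensities add without cross terms, the
#' fragments being treated as uncorrelated after separation.
#'
#' @param ... One or more `molecular_structure` fragments.
#' @param fraction Branching fraction of this channel (>= 0).
#' @return An object of class `reaction_product`.
#' @export
reaction_product <- function(..., fraction) {
  frags <- list(...)
  if (length(frags) == 1 && is.list(frags[[1]]) &&
      !inherits(frags[[1]], "molecular_structure"))
    frags <- frags[[1]]
  if (!length(frags) || !all(vapply(frags, inherits, TRUE, "molecular_structure")))
    stop("reaction_product needs one or more molecular_structure fragments")
  if (!is.numeric(fraction) || fraction < 0)
    stop("branching fraction must be >= 0")
  structure(list(fragments = frags, fraction = fraction),
            class = "reaction_product")
}

#' Define a photoreaction channel
#'
#' @param reactant The reactant `molecular_structure`.
#' @param products List of [reaction_product()] entries; branching fractions
#'   must sum to 1.
#' @param r_str Excitation (conversion) ratio: fraction of solute molecules
#'   converted to products, in `[0, 1]`.
#' @return An object of class `reaction_channel`.
#' @export
reaction_channel <- function(reactant, products, r_str) {
  stopifnot(inherits(reactant, "molecular_structure"))
  if (inherits(products, "reaction_product")) products <- list(products)
  if (!length(products) ||
      !all(vapply(products, inherits, TRUE, "reaction_product")))
    stop("products must be a list of reaction_product objects")
  fr <- vapply(products, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8)
    stop("branching fractions must sum to 1 (got ", sum(fr), ")")
  if (!is.numeric(r_str) || r_str < 0 || r_str > 1)
    stop("r_str must lie in [0, 1]")
  structure(list(reactant = reactant, products = products, r_str = r_str),
            class = "reaction_channel")
}

# total Debye intensity of a (possibly multi-fragment) species
species_intensity <- function(fragments, q) {
  if (inherits(fragments, "molecular_structure")) fragments <- list(fragments)
  curves <- lapply(fragments, debye_intensity, q = q)
  curve_lincomb(curves, rep(1, length(curves)), "per_solute_molecule")
}

#' Solute-only difference signal
#'
#' \deqn{\Delta S_{solute}(q) = \frac{c_{solu}}{c_{solv}} \, r_{str}
#'   \left[\sum_p \phi_p S_p(q) - S_r(q)\right]}
#' The concentration ratio scales the per-solute-molecule Debye difference
#' to one mole of solvent molecules, the convention used for displayed
#' difference curves.
#'
#' @param channel A [reaction_channel()].
#' @param c_solu,c_solv Solute and solvent concentrations (mol/L), > 0.
#' @param q Momentum-transfer grid (1/Angstrom).
#' @return A `scattering_curve`, e.u. per solvent molecule.
#' @export
solute_difference <- function(channel, c_solu, c_solv, q) {
  stopifnot(inherits(channel, "reaction_channel"))
  if (!is.numeric(c_solu) || c_solu <= 0 || !is.numeric(c_solv) || c_solv <= 0)
    stop("concentrations must be positive")
  s_r <- debye_intensity(channel$reactant, q)
  diff <- -s_r$intensity
  for (p in channel$products)
    diff <- diff + p$fraction * species_intensity(p$fragments, q)$intensity
  scattering_curve(q, (c_solu / c_solv) * channel$r_str * diff,
                   normalization = "per_solvent_molecule")
}
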