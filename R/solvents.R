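# Packaged solvents. Thermophysical constants are standard room-temperature
# literature values; the two differential scattering curves are SYNTHETIC
# damped-oscillation shapes with realistic amplitude and q-extent, generated
# in code so the package runs fully offline. They stand in for measured
# solvent differentials, which users should load from their own two-column
# files (see load_curve()) for quantitative work.

solvent_constants <- function() {
  list(
    cyclohexane  = list(counts = c(C = 6, H = 12), molar_mass = 84.16,
                        rho0 = 0.779, c_v = 126.0, c_p = 156.3,
                        alpha_p = 1.22e-3,
                        shape = list(a_t = 0.9, r_t = 4.9, l_t = 1.3,
                                     a_r = 45,  r_r = 4.5, l_r = 1.6)),
    acetonitrile = list(counts = c(C = 2, H = 3, N = 1), molar_mass = 41.05,
                        rho0 = 0.786, c_v = 71.0, c_p = 91.7,
                        alpha_p = 1.37e-3,
                        shape = list(a_t = 0.5, r_t = 4.2, l_t = 1.4,
                                     a_r = 25,  r_r = 3.8, l_r = 1.7)),
    methanol     = list(counts = c(C = 1, H = 4, O = 1), molar_mass = 32.04,
                        rho0 = 0.792, c_v = 68.0, c_p = 79.5,
                        alpha_p = 1.49e-3,
                        shape = list(a_t = 0.4, r_t = 3.8, l_t = 1.5,
                                     a_r = 18,  r_r = 3.4, l_r = 1.8)),
    ethanol      = list(counts = c(C = 2, H = 6, O = 1), molar_mass = 46.07,
                        rho0 = 0.789, c_v = 95.0, c_p = 112.3,
                        alpha_p = 1.09e-3,
                        shape = list(a_t = 0.5, r_t = 4.0, l_t = 1.4,
                                     a_r = 22,  r_r = 3.6, l_r = 1.7))
  )
}

#' Names of the packaged solvents
#' @return Character vector.
#' @export
packaged_solvents <- function() names(solvent_constants())

# synthetic differential shape: damped oscillation that integrates the
# qualitative features of measured solvent differentials (sign change at low
# q, decaying oscillation at high q)
synthetic_differential <- function(q, amplitude, r0, decay) {
  amplitude * exp(-(q / decay)^2 / 2) * (q * r0 * cos(q * r0) - sin(q * r0)) /
    (q * r0)
}

#' Packaged solvent model
#'
#' Returns a [solvent_model()] for one of the packaged solvents, with
#' synthetic differential curves evaluated on `q` (see the package vignette
#' for what the synthetic shapes do and do not emulate).
#'
#' @param name One of [packaged_solvents()].
#' @param q Momentum-transfer grid (default [default_q_grid()]).
#' @return A `solvent_model`.
#' @examples
#' cyh <- packaged_solvent("cyclohexane")
#' @export
packaged_solvent <- function(name, q = default_q_grid()) {
  tab <- solvent_constants()
  if (!name %in% names(tab))
    stop("unknown solvent ", sQuote(name), "; packaged solvents: ",
         paste(names(tab), collapse = ", "))
  sc <- tab[[name]]
  c_solv <- sc$rho0 / sc$molar_mass * 1000   # mol / L
  dsdt <- scattering_curve(
    q, synthetic_differential(q, sc$shape$a_t, sc$shape$r_t, sc$shape$l_t),
    normalization = "per_solvent_molecule")
  dsdrho <- scattering_curve(
    q, synthetic_differential(q, sc$shape$a_r, sc$shape$r_r, sc$shape$l_r),
    normalization = "per_solvent_molecule")
  solvent_model(name, c_solv = c_solv, rho0 = sc$rho0, c_v = sc$c_v,
                c_p = sc$c_p, alpha_p = sc$alpha_p,
                dsdt = dsdt, dsdrho = dsdrho,
                composition = solvent_composition(
                  sc$counts, mass_density = sc$rho0,
                  molar_mass = sc$molar_mass))
}
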