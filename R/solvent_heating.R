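# Solvent-only (heating) term. The pump energy retained by excited solute
# molecules that relax non-structurally is deposited as heat; the resulting
# temperature and density changes are contracted against the solvent's two
# differential scattering curves:
#   dS_solvent(q) = dT * (dS/dT)_rho(q) + drho * (dS/drho)_T(q).

PLANCK    <- 6.62607015e-34   # J s
C_LIGHT   <- 2.99792458e8     # m / s
AVOGADRO  <- 6.02214076e23    # 1 / mol

#' Molar photon energy of the pump pulse
#' @param wavelength_nm Pump wavelength in nm.
#' @return Energy in J per mole of photons.
#' @export
molar_photon_energy <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || wavelength_nm <= 0)
    stop("wavelength must be > 0")
  PLANCK * C_LIGHT / (wavelength_nm * 1e-9) * AVOGADRO
}

#' Maximum heat deposited in the solvent
#'
#' Upper-bound estimate assuming every excited solute molecule that does not
#' enter a structural channel returns its full photon energy to the solvent
#' without loss:
#' \deqn{Q_{max} = \frac{h c}{\lambda} N_A \, r_{heat} \,
#'   \frac{c_{excited}}{c_{solv}}.}
#'
#' @param pump_wavelength_nm Pump wavelength (nm), > 0.
#' @param c_excited Concentration of excited solute (mol/L), > 0.
#' @param r_heat Fraction of excited molecules releasing their energy purely
#'   as heat, in `[0, 1]`.
#' @param c_solv Solvent concentration (mol/L), > 0.
#' @return Q_max in J per mole of solvent.
#' @export
max_heat <- function(pump_wavelength_nm, c_excited, r_heat, c_solv) {
  if (!is.numeric(r_heat) || r_heat < 0 || r_heat > 1)
    stop("r_heat must lie in [0, 1]")
  if (c_excited <= 0 || c_solv <= 0) stop("concentrations must be > 0")
  molar_photon_energy(pump_wavelength_nm) * r_heat * c_excited / c_solv
}

#' Maximum temperature rise (isochoric limit)
#' @param q_max Heat per mole of solvent (J/mol); see [max_heat()].
#' @param c_v Heat capacity at constant volume (J/mol/K), > 0.
#' @return dT_max in K.
#' @export
max_temperature_rise <- function(q_max, c_v) {
  if (!is.numeric(c_v) || c_v <= 0) stop("C_v must be > 0")
  q_max / c_v
}

#' Maximum density change (isobaric limit)
#'
#' \deqn{\Delta\rho_{max} = -\alpha_p \frac{Q_{max}}{C_p} \rho_0,}
#' negative because isobaric heating expands the solvent.
#'
#' @param q_max Heat per mole of solvent (J/mol).
#' @param c_p Heat capacity at constant pressure (J/mol/K), > 0.
#' @param alpha_p Volumetric thermal expansion coefficient (1/K), > 0.
#' @param rho0 Equilibrium solvent density (g/mL), > 0.
#' @return drho_max in g/mL (<= 0).
#' @export
max_density_change <- function(q_max, c_p, alpha_p, rho0) {
  if (c_p <= 0 || alpha_p <= 0 || rho0 <= 0)
    stop("C_p, alpha_p and rho0 must be > 0")
  -alpha_p * (q_max / c_p) * rho0
}

#' Thermal state at a given pump-probe delay
#'
#' Fast approximation of the isochoric-to-isobaric crossover: the
#' temperature change holds at its maximum up to 10 ns, then decreases
#' linearly to zero by 3 us, while the density change is zero up to 10 ns
#' and grows linearly to its maximum by 3 us. Negative delays (before the
#' pump) carry no thermal signal.
#'
#' @param t_delay Pump-probe delay in seconds (may be negative).
#' @param dt_max Maximum temperature rise (K).
#' @param drho_max Maximum density change (g/mL).
#' @return A list with elements `dT` (K) and `drho` (g/mL), class
#'   `thermal_state`.
#' @export
thermal_profile <- function(t_delay, dt_max, drho_max) {
  t_iso <- 10e-9; t_bar <- 3e-6
  if (!is.finite(t_delay)) stop("t_delay must be finite")
  if (t_delay < 0) {
    st <- list(dT = 0, drho = 0)
  } else if (t_delay <= t_iso) {
    st <- list(dT = dt_max, drho = 0)
  } else if (t_delay >= t_bar) {
    st <- list(dT = 0, drho = drho_max)
  } else {
    x <- (t_delay - t_iso) / (t_bar - t_iso)
    st <- list(dT = (1 - x) * dt_max, drho = x * drho_max)
  }
  structure(st, class = "thermal_state")
}

#' Solvent model
#'
#' Bundles the thermophysical constants, composition, and the two
#' differential scattering curves needed for the heating term.
#'
#' @param name Solvent name.
#' @param c_solv Concentration of the neat solvent (mol/L), > 0.
#' @param rho0 Mass density (g/mL), > 0.
#' @param c_v,c_p Heat capacities (J/mol/K), > 0.
#' @param alpha_p Thermal expansion coefficient (1/K), > 0.
#' @param dsdt `(dS/dT)_rho` as a `scattering_curve` (e.u. per solvent
#'   molecule per K).
#' @param dsdrho `(dS/drho)_T` as a `scattering_curve` (e.u. per solvent
#'   molecule per g/mL); must share the q-grid of `dsdt`.
#' @param composition A [solvent_composition()].
#' @return An object of class `solvent_model`.
#' @export
solvent_model <- function(name, c_solv, rho0, c_v, c_p, alpha_p,
                          dsdt, dsdrho, composition) {
  stopifnot(inherits(dsdt, "scattering_curve"),
            inherits(dsdrho, "scattering_curve"),
            inherits(composition, "solvent_composition"))
  if (any(c(c_solv, rho0, c_v, c_p, alpha_p) <= 0))
    stop("all thermophysical constants must be > 0")
  check_same_grid(dsdt, dsdrho)
  structure(list(name = name, c_solv = c_solv, rho0 = rho0, c_v = c_v,
                 c_p = c_p, alpha_p = alpha_p, dsdt = dsdt, dsdrho = dsdrho,
                 composition = composition),
            class = "solvent_model")
}

#' Solvent-only difference signal
#'
#' Contracts a thermal state against the solvent differential curves:
#' `dT * (dS/dT)_rho + drho * (dS/drho)_T`, bilinear in both.
#'
#' @param state A `thermal_state` from [thermal_profile()].
#' @param solvent A [solvent_model()].
#' @return A `scattering_curve`, e.u. per solvent molecule.
#' @export
solvent_signal <- function(state, solvent) {
  stopifnot(inherits(solvent, "solvent_model"))
  scattering_curve(solvent$dsdt$q,
                   state$dT * solvent$dsdt$intensity +
                     state$drho * solvent$dsdrho$intensity,
                   normalization = "per_solvent_molecule")
}
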