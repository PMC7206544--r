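# Signal assembly and time-delay series. The total simulated difference
# signal at each delay is
#   dS_sim(q) = dS_solute(q) + dS_cage(q) + dS_solvent(q) + dS_noise(q),
# with species populations evolved through a linear first-order kinetic
# network and per-delay noise from equal beam-time slices.

#' First-order kinetic scheme
#'
#' A linear rate network among transient species. `rates[i, j]` is the
#' first-order rate constant (1/s) for conversion of species i into species
#' j; populations evolve as `dp/dt = A p` with the usual generator matrix.
#' The initial populations are the branching fractions of the excited
#' ensemble at t = 0+ (they need not sum to 1 if part of the excitation
#' returns instantly to the ground state).
#'
#' @param species Character vector of species names.
#' @param rates Square non-negative matrix of rate constants (1/s), zero
#'   diagonal; dimension = number of species.
#' @param initial Non-negative initial populations at t = 0+, one per
#'   species (fractions of the excited ensemble).
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(species, rates, initial) {
  k <- length(species)
  rates <- as.matrix(rates)
  if (!all(dim(rates) == k)) stop("rates must be a ", k, " x ", k, " matrix")
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be >= 0")
  diag(rates) <- 0
  if (length(initial) != k || any(initial < 0))
    stop("initial populations must be >= 0, one per species")
  structure(list(species = species, rates = rates,
                 initial = as.double(initial)),
            class = "kinetic_scheme")
}

#' Species populations at a time delay
#'
#' Solves the linear first-order system by matrix exponential:
#' `p(t) = expm(A t) p(0)` with `A = t(rates) - diag(rowSums(rates))`.
#' The generator conserves total population exactly (each column of A sums
#' to zero), so the returned fractions sum to `sum(initial)`.
#'
#' @param scheme A [kinetic_scheme()].
#' @param t_delay Delay in seconds; for negative delays all population is
#'   still in the (unexcited) ground state and every species fraction is 0.
#' @return Named numeric vector of per-species population fractions.
#' @export
populations_at <- function(scheme, t_delay) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  k <- length(scheme$species)
  if (t_delay < 0) return(stats::setNames(rep(0, k), scheme$species))
  A <- t(scheme$rates)
  diag(A) <- -rowSums(scheme$rates)
  p <- as.vector(Matrix::expm(A * t_delay) %*% scheme$initial)
  stats::setNames(p, scheme$species)
}

#' Illustrative iodoform photolysis kinetic scheme
#'
#' The excited reactant branches at t = 0+ into an iso-form (fraction 0.4)
#' and a radical pair (fraction 0.6); both relax back to the ground state
#' with illustrative literature-style time constants (870 ns and 50 us).
#' Shipped as an editable example, not a fitted model.
#'
#' @return A `kinetic_scheme` over species `isomer`, `radical`, `ground`.
#' @export
chi3_kinetic_scheme <- function() {
  sp <- c("isomer", "radical", "ground")
  rates <- matrix(0, 3, 3, dimnames = list(sp, sp))
  rates["isomer", "ground"] <- 1 / 870e-9
  rates["radical", "ground"] <- 1 / 50e-6
  kinetic_scheme(sp, rates, initial = c(0.4, 0.6, 0))
}

#' Photochemical system under study
#'
#' Bundles everything the per-delay signal assembly needs: the reactant and
#' transient-species structures, the kinetic scheme that connects them, the
#' solvent model, and the photoexcitation parameters.
#'
#' @param reactant Reactant `molecular_structure`.
#' @param species Named list, one entry per scheme species: a
#'   `molecular_structure`, a list of fragment structures, or `NULL` for a
#'   species indistinguishable from the reactant (recovered ground state).
#' @param scheme A [kinetic_scheme()] whose species names match `species`.
#' @param solvent A [solvent_model()].
#' @param c_solu Solute concentration (mol/L), > 0.
#' @param excitation Fraction of solute excited by the pump, in `[0, 1]`.
#' @param r_heat Fraction of excited molecules relaxing purely by heat
#'   release, in `[0, 1]`.
#' @param pump_wavelength_nm Pump wavelength (nm).
#' @return An object of class `trxl_system`.
#' @export
trxl_system <- function(reactant, species, scheme, solvent, c_solu,
                        excitation, r_heat = NULL, pump_wavelength_nm = 267) {
  stopifnot(inherits(reactant, "molecular_structure"),
            inherits(scheme, "kinetic_scheme"),
            inherits(solvent, "solvent_model"))
  if (!setequal(names(species), scheme$species))
    stop("species list names must match the kinetic scheme species")
  if (c_solu <= 0) stop("c_solu must be > 0")
  if (excitation < 0 || excitation > 1) stop("excitation must lie in [0, 1]")
  if (is.null(r_heat)) r_heat <- max(0, 1 - sum(scheme$initial))
  if (r_heat < 0 || r_heat > 1) stop("r_heat must lie in [0, 1]")
  structure(list(reactant = reactant, species = species, scheme = scheme,
                 solvent = solvent, c_solu = c_solu, excitation = excitation,
                 r_heat = r_heat, pump_wavelength_nm = pump_wavelength_nm),
            class = "trxl_system")
}

# fragments of a species entry; NULL means "same as reactant"
species_fragments <- function(system, name) {
  entry <- system$species[[name]]
  if (is.null(entry)) return(list(system$reactant))
  if (inherits(entry, "molecular_structure")) return(list(entry))
  entry
}

# per-species difference basis, computed once and reused across delays:
# columns hold the solute / cage intensity differences of each transient
# species against the reactant, plus the thermal limits of the system
system_basis <- function(system, q) {
  s_r <- debye_intensity(system$reactant, q)$intensity
  cage_r <- cage_intensity(system$reactant, system$solvent$composition,
                           q)$intensity
  nms <- system$scheme$species
  solute_b <- matrix(0, length(q), length(nms), dimnames = list(NULL, nms))
  cage_b <- solute_b
  for (nm in nms) {
    if (is.null(system$species[[nm]])) next
    frags <- species_fragments(system, nm)
    solute_b[, nm] <- species_intensity(frags, q)$intensity - s_r
    cage_b[, nm] <- cage_intensity(frags, system$solvent$composition,
                                   q)$intensity - cage_r
  }
  q_max <- max_heat(system$pump_wavelength_nm,
                    c_excited = max(system$excitation * system$c_solu, 1e-300),
                    r_heat = system$r_heat, c_solv = system$solvent$c_solv)
  list(q = q, solute = solute_b, cage = cage_b,
       dt_max = max_temperature_rise(q_max, system$solvent$c_v),
       drho_max = max_density_change(q_max, system$solvent$c_p,
                                     system$solvent$alpha_p,
                                     system$solvent$rho0))
}

#' Noise-free signal components at one time delay
#'
#' Computes the three deterministic terms of the difference signal for the
#' species populations at `t_delay`: solute-only (Debye), cage
#' (hard-sphere), and solvent heating. All three are scaled to one mole of
#' solvent molecules.
#'
#' @param system A [trxl_system()].
#' @param t_delay Pump-probe delay (s).
#' @param q Momentum-transfer grid.
#' @param basis Precomputed internal per-species basis (reused by
#'   [simulate_series()] so the structural curves are evaluated once per
#'   system, not once per delay).
#' @return List with `scattering_curve` elements `solute`, `cage`,
#'   `solvent`, plus the population vector used.
#' @export
trxl_components <- function(system, t_delay, q = default_q_grid(),
                            basis = NULL) {
  if (is.null(basis)) basis <- system_basis(system, q)
  pops <- populations_at(system$scheme, t_delay)
  scale <- (system$c_solu / system$solvent$c_solv) * system$excitation
  solute <- as.vector(basis$solute %*% pops)
  cage <- as.vector(basis$cage %*% pops)
  state <- thermal_profile(t_delay, basis$dt_max, basis$drho_max)
  list(solute = scattering_curve(q, scale * solute,
                                 normalization = "per_solvent_molecule"),
       cage = scattering_curve(q, scale * cage,
                               normalization = "per_solvent_molecule"),
       solvent = solvent_signal_on_grid(state, system$solvent, q),
       populations = pops, thermal_state = state)
}

# solvent differentials may live on their own grid; re-evaluate on q
solvent_signal_on_grid <- function(state, solvent, q) {
  if (same_grid(solvent$dsdt, list(q = q))) return(solvent_signal(state, solvent))
  interp <- function(curve) stats::approx(curve$q, curve$intensity, xout = q,
                                          rule = 2)$y
  scattering_curve(q, state$dT * interp(solvent$dsdt) +
                     state$drho * interp(solvent$dsdrho),
                   normalization = "per_solvent_molecule")
}

#' Simulated difference curve at one time delay
#'
#' Assembles `dS_sim = dS_solute + dS_cage + dS_solvent + dS_noise`. With
#' `noise = FALSE` the deterministic three-term sum is returned; otherwise
#' Gaussian noise for `n_curves` averaged difference curves (default: the
#' full accumulation of `beam`) is added and `sigma_target/sqrt(I)` is
#' attached as the per-point uncertainty.
#'
#' @param system A [trxl_system()].
#' @param t_delay Pump-probe delay (s).
#' @param beam [beam_parameters()] of the planned acquisition.
#' @param noise_ref A [noise_reference()].
#' @param q Momentum-transfer grid.
#' @param seed Integer seed; required when `noise = TRUE`.
#' @param noise Logical: add the stochastic noise term?
#' @param n_curves Override for the number of averaged difference curves I.
#' @return A `scattering_curve` with attribute `"components"` holding the
#'   individual terms.
#' @export
simulate_difference <- function(system, t_delay, beam, noise_ref,
                                q = default_q_grid(), seed = NULL,
                                noise = TRUE, n_curves = NULL) {
  comp <- trxl_components(system, t_delay, q)
  total <- comp$solute$intensity + comp$cage$intensity + comp$solvent$intensity
  if (noise) {
    if (is.null(seed)) stop("a seed is required when noise is enabled")
    sigma_t <- scale_sigma(noise_ref, beam)
    sigma_t <- scattering_curve(q, stats::approx(sigma_t$q, sigma_t$intensity,
                                                 xout = q, rule = 2)$y,
                                normalization = sigma_t$normalization)
    I <- if (is.null(n_curves)) n_difference_curves(beam) else floor(n_curves)
    nz <- generate_noise(sigma_t, I, seed)
    comp$noise <- nz
    out <- scattering_curve(q, total + nz$intensity, sigma = nz$sigma,
                            normalization = "per_solvent_molecule")
  } else {
    out <- scattering_curve(q, total, normalization = "per_solvent_molecule")
  }
  attr(out, "components") <- comp
  out
}

#' Measurement plan for a time-delay series
#'
#' Equal beam-time allocation: each of the M delays receives
#' `t_total * d / M` seconds, so the per-delay curve count is
#' `I = floor(f * (t_total * d / M) / 2)`.
#'
#' @param delays Numeric vector of pump-probe delays (s); negative
#'   reference delays are allowed. Sorted internally.
#' @param total_time Total beam time (s), > 0.
#' @param beam [beam_parameters()] (its `t` and `d` are ignored in favour of
#'   `total_time` and `duty_cycle`).
#' @param noise_ref A [noise_reference()].
#' @param duty_cycle Fraction of beam time actually acquiring, in (0, 1].
#' @param seed Integer seed for the per-delay noise realizations.
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(delays, total_time, beam, noise_ref,
                            duty_cycle = 1, seed = 1) {
  if (!length(delays)) stop("at least one delay is required")
  if (total_time <= 0) stop("total_time must be > 0")
  if (duty_cycle <= 0 || duty_cycle > 1) stop("duty cycle must lie in (0, 1]")
  structure(list(delays = sort(delays), total_time = total_time, beam = beam,
                 noise_ref = noise_ref, duty_cycle = duty_cycle, seed = seed),
            class = "simulation_plan")
}

#' Simulate a time-resolved series
#'
#' One simulated difference curve per delay under equal time slices; more
#' delays at fixed total beam time means fewer curves averaged per delay and
#' proportionally (1/sqrt(I)) larger noise.
#'
#' @param plan A [simulation_plan()].
#' @param system A [trxl_system()].
#' @param q Momentum-transfer grid.
#' @param noise Logical: add noise realizations?
#' @return List of class `trxl_series`: `curves` (one `scattering_curve`
#'   per delay) and `manifest` (the [plan_report()] table).
#' @export
simulate_series <- function(plan, system, q = default_q_grid(), noise = TRUE) {
  stopifnot(inherits(plan, "simulation_plan"))
  M <- length(plan$delays)
  t_per <- plan$total_time * plan$duty_cycle / M
  I <- floor(plan$beam$f * t_per / 2)
  if (noise && I < 1)
    warning("equal allocation leaves no complete on/off pair per delay (I = 0)")
  sigma_t <- scale_sigma(plan$noise_ref, plan$beam)
  sigma_t <- scattering_curve(q, stats::approx(sigma_t$q, sigma_t$intensity,
                                               xout = q, rule = 2)$y,
                              normalization = sigma_t$normalization)
  basis <- system_basis(system, q)
  curves <- vector("list", M)
  rows <- vector("list", M)
  for (m in seq_len(M)) {
    comp <- trxl_components(system, plan$delays[m], q, basis = basis)
    clean <- comp$solute$intensity + comp$cage$intensity + comp$solvent$intensity
    if (noise && I >= 1) {
      nz <- generate_noise(sigma_t, I, seed = plan$seed + m)
      cur <- scattering_curve(q, clean + nz$intensity, sigma = nz$sigma,
                              normalization = "per_solvent_molecule")
    } else {
      cur <- scattering_curve(q, clean, normalization = "per_solvent_molecule")
    }
    attr(cur, "components") <- comp
    curves[[m]] <- cur
    sig_bar <- if (noise && I >= 1) stats::median(sigma_t$intensity / sqrt(I)) else 0
    peak <- max(abs(clean))
    rows[[m]] <- data.frame(delay = plan$delays[m], I = if (noise) I else NA,
                            sigma_bar = sig_bar, peak_signal = peak,
                            snr = if (sig_bar > 0) peak / sig_bar else Inf)
  }
  structure(list(curves = curves, manifest = do.call(rbind, rows),
                 plan = plan),
            class = "trxl_series")
}

#' Planning summary of a simulated series
#'
#' Per-delay table of the photon accounting and expected data quality:
#' delay, averaged curve count I, median noise std after averaging, peak
#' noise-free signal, and their ratio as the SNR figure (an artifact
#' convention: peak |signal| over median per-point noise std).
#'
#' @param series A `trxl_series` from [simulate_series()].
#' @return A `data.frame` with one row per delay.
#' @export
plan_report <- function(series) {
  stopifnot(inherits(series, "trxl_series"))
  series$manifest
}
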