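# Run configuration: one YAML file fully determines a simulation (no hidden
# state). Relative paths are resolved against the config file's directory;
# validation collects every problem before failing.

config_defaults <- function() {
  list(q_grid = list(min = 0.3, max = 8.0, step = 0.01),
       duty_cycle = 1.0, total_time = 36,
       noise = list(source = "synthetic", level = 0.03),
       solute = list(pump_wavelength = 267))
}

#' Load and validate a simulation configuration
#'
#' Reads a YAML config, applies documented defaults (each applied default is
#' reported via `message()` when `verbose`), resolves relative paths against
#' the config location, and validates all fields at once, reporting every
#' problem in a single error.
#'
#' @param path Path to a YAML configuration file.
#' @param verbose Report applied defaults.
#' @return A validated object of class `trxl_config`.
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  for (nm in names(config_defaults())) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- config_defaults()[[nm]]
      if (verbose) message("config default applied: ", nm)
    } else if (is.list(config_defaults()[[nm]])) {
      for (sub in names(config_defaults()[[nm]])) {
        if (is.null(cfg[[nm]][[sub]])) {
          cfg[[nm]][[sub]] <- config_defaults()[[nm]][[sub]]
          if (verbose) message("config default applied: ", nm, ".", sub)
        }
      }
    }
  }

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^/", p)) p else file.path(base, p)
  }

  # structures
  if (is.null(cfg$reactant)) note("missing required key: reactant")
  else {
    cfg$reactant <- resolve(cfg$reactant)
    if (!file.exists(cfg$reactant)) note("reactant XYZ not found: ", cfg$reactant)
  }
  if (is.null(cfg$species) || !length(cfg$species))
    note("missing required key: species")
  else for (nm in names(cfg$species)) {
    sp <- cfg$species[[nm]]
    if (identical(sp, "reactant")) next
    if (is.null(sp$structures)) { note("species ", nm, " lacks 'structures'"); next }
    cfg$species[[nm]]$structures <- vapply(sp$structures, resolve, character(1))
    missing <- !file.exists(cfg$species[[nm]]$structures)
    if (any(missing))
      note("species ", nm, " XYZ not found: ",
           paste(cfg$species[[nm]]$structures[missing], collapse = ", "))
  }

  # kinetics
  if (is.null(cfg$kinetics) || is.null(cfg$kinetics$initial))
    note("missing required key: kinetics.initial")
  else {
    ini <- unlist(cfg$kinetics$initial)
    if (any(ini < 0)) note("kinetics.initial values must be >= 0")
    if (sum(ini) > 1 + 1e-9) note("kinetics.initial fractions exceed 1")
    if (!is.null(cfg$species) &&
        !all(names(ini) %in% c(names(cfg$species))))
      note("kinetics.initial names must match species entries")
    for (r in cfg$kinetics$rates) {
      if (is.null(r$from) || is.null(r$to) || is.null(r$k) || r$k < 0)
        note("each kinetics.rates entry needs from, to and k >= 0")
    }
  }

  # solvent / solute
  if (is.null(cfg$solvent)) note("missing required key: solvent")
  else if (is.character(cfg$solvent) && !cfg$solvent %in% packaged_solvents())
    note("unknown solvent ", sQuote(cfg$solvent), "; packaged solvents: ",
         paste(packaged_solvents(), collapse = ", "))
  if (is.null(cfg$solute$concentration) || cfg$solute$concentration <= 0)
    note("solute.concentration must be > 0")
  exc <- cfg$solute$excitation
  if (is.null(exc) || exc < 0 || exc > 1)
    note("solute.excitation must lie in [0, 1]")
  if (!is.null(cfg$solute$r_heat) &&
      (cfg$solute$r_heat < 0 || cfg$solute$r_heat > 1))
    note("solute.r_heat must lie in [0, 1]")

  # beam and noise. YAML 1.1 reads a bare key `n` as boolean FALSE, so a
  # photons-per-pulse entry written unquoted is recovered from that slot.
  if (is.null(cfg$beam$n) && !is.null(cfg$beam[["FALSE"]])) {
    cfg$beam$n <- cfg$beam[["FALSE"]]
    cfg$beam[["FALSE"]] <- NULL
  }
  for (k in c("f", "D", "n")) {
    if (is.null(cfg$beam[[k]]) || cfg$beam[[k]] <= 0)
      note("beam.", k, " must be present and > 0")
  }
  if (!is.null(cfg$beam$d) && (cfg$beam$d <= 0 || cfg$beam$d > 1))
    note("beam.d (duty cycle) must lie in (0, 1]")
  if (cfg$duty_cycle <= 0 || cfg$duty_cycle > 1)
    note("duty_cycle must lie in (0, 1]")
  if (!cfg$noise$source %in% c("synthetic", "file"))
    note("noise.source must be 'synthetic' or 'file'")
  if (identical(cfg$noise$source, "file")) {
    cfg$noise$file <- resolve(cfg$noise$file)
    if (is.null(cfg$noise$file) || !file.exists(cfg$noise$file))
      note("noise.source is 'file' but noise.file is missing")
  } else if (is.null(cfg$noise$level) || cfg$noise$level <= 0) {
    note("synthetic noise needs noise.level > 0")
  }

  # delays and grid
  if (is.null(cfg$delay) && is.null(cfg$delays))
    note("missing required key: delay (single) or delays (series)")
  qg <- cfg$q_grid
  if (qg$min < 0 || qg$max <= qg$min || qg$step <= 0)
    note("q_grid must satisfy 0 <= min < max with step > 0")

  if (length(problems))
    stop("invalid configuration ", path, ":\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  cfg$base_dir <- base
  class(cfg) <- "trxl_config"
  cfg
}

#' Momentum-transfer grid of a configuration
#' @param cfg A `trxl_config`.
#' @return Numeric q vector.
#' @export
config_q_grid <- function(cfg) {
  default_q_grid(cfg$q_grid$min, cfg$q_grid$max, cfg$q_grid$step)
}

#' Build the photochemical system described by a configuration
#' @param cfg A validated `trxl_config`.
#' @return A [trxl_system()].
#' @export
build_system <- function(cfg) {
  stopifnot(inherits(cfg, "trxl_config"))
  reactant <- read_xyz(cfg$reactant)
  species <- lapply(cfg$species, function(sp) {
    if (identical(sp, "reactant")) return(NULL)
    frags <- lapply(sp$structures, read_xyz)
    if (length(frags) == 1) frags[[1]] else frags
  })
  sp_names <- names(species)
  rates <- matrix(0, length(sp_names), length(sp_names),
                  dimnames = list(sp_names, sp_names))
  for (r in cfg$kinetics$rates) rates[r$from, r$to] <- r$k
  ini <- stats::setNames(rep(0, length(sp_names)), sp_names)
  ini[names(cfg$kinetics$initial)] <- unlist(cfg$kinetics$initial)
  scheme <- kinetic_scheme(sp_names, rates, ini)
  solvent <- packaged_solvent(cfg$solvent, q = config_q_grid(cfg))
  trxl_system(reactant, species, scheme, solvent,
              c_solu = cfg$solute$concentration,
              excitation = cfg$solute$excitation,
              r_heat = cfg$solute$r_heat,
              pump_wavelength_nm = cfg$solute$pump_wavelength)
}

#' Beam parameters of a configuration
#' @param cfg A `trxl_config`.
#' @return A [beam_parameters()] object.
#' @export
config_beam <- function(cfg) {
  beam_parameters(f = cfg$beam$f, D = cfg$beam$D, n = cfg$beam$n,
                  t = if (is.null(cfg$beam$t)) cfg$total_time else cfg$beam$t,
                  d = if (is.null(cfg$beam$d)) cfg$duty_cycle else cfg$beam$d)
}

#' Noise reference of a configuration
#' @param cfg A `trxl_config`.
#' @param q Momentum-transfer grid for a synthetic reference.
#' @return A [noise_reference()].
#' @export
config_noise_reference <- function(cfg, q = config_q_grid(cfg)) {
  if (identical(cfg$noise$source, "file")) {
    read_sigma_reference(cfg$noise$file)
  } else {
    synthetic_sigma(cfg$noise$level, q, config_beam(cfg))
  }
}
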