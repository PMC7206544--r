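# Shot-noise model. The per-curve noise level sigma(q) is taken from a
# reference neat-solvent measurement and rescaled by the square root of the
# photon count ratio; averaged difference-curve noise is Gaussian with the
# 1/sqrt(I) law. Quantum (shot) noise is the only component modelled, which
# makes the estimate an upper bound when the reference already contains
# systematic noise.

#' Beamline photon-accounting parameters
#'
#' @param f X-ray pulse repetition rate (Hz), > 0.
#' @param D Detector exposure time per scattering curve (s), > 0. For
#'   shot-by-shot XFEL acquisition `D = 1/f` (one pulse per curve).
#' @param n Photons per pulse, > 0.
#' @param t Nominal accumulation time (s), > 0.
#' @param d Duty cycle: fraction of the nominal time actually acquiring,
#'   in (0, 1].
#' @return An object of class `beam_parameters`.
#' @examples
#' beam_parameters(f = 30, D = 1 / 30, n = 1e12, t = 36)
#' @export
beam_parameters <- function(f, D, n, t = 1, d = 1) {
  vals <- c(f = f, D = D, n = n, t = t)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("f, D, n and t must be positive")
  if (!is.finite(d) || d <= 0 || d > 1) stop("duty cycle d must lie in (0, 1]")
  structure(list(f = f, D = D, n = n, t = t, d = d),
            class = "beam_parameters")
}

#' Packaged facility beam presets
#'
#' Three representative acquisition setups: an integrating synchrotron
#' beamline (f = 1 kHz, D = 1.5 s, n = 5e8), a low-repetition XFEL recorded
#' shot-by-shot (f = 30 Hz, n = 1e12 per pulse, D = 1/f), and a
#' high-repetition XFEL (f = 1 MHz, n = 3e10, D = 1/f).
#'
#' @param name `"synchrotron"`, `"xfel_low_rep"` or `"xfel_high_rep"`.
#' @param t,d Accumulation time (s) and duty cycle passed through.
#' @return A `beam_parameters` object.
#' @export
facility_beam <- function(name = c("synchrotron", "xfel_low_rep",
                                   "xfel_high_rep"), t = 36, d = 1) {
  switch(match.arg(name),
         synchrotron   = beam_parameters(f = 1000, D = 1.5,    n = 5e8,  t = t, d = d),
         xfel_low_rep  = beam_parameters(f = 30,   D = 1 / 30, n = 1e12, t = t, d = d),
         xfel_high_rep = beam_parameters(f = 1e6,  D = 1e-6,   n = 3e10, t = t, d = d))
}

#' Incident photons per scattering curve
#' @param beam A [beam_parameters()] object.
#' @return N = f * D * n.
#' @export
photons_per_curve <- function(beam) {
  stopifnot(inherits(beam, "beam_parameters"))
  beam$f * beam$D * beam$n
}

#' Reference solvent noise curve
#'
#' @param sigma A `scattering_curve` whose intensities hold the per-point
#'   standard deviation sigma_solvent(q) of repeated neat-solvent difference
#'   curves (>= 0).
#' @param beam The [beam_parameters()] of the reference acquisition.
#' @return An object of class `noise_reference`.
#' @export
noise_reference <- function(sigma, beam) {
  stopifnot(inherits(sigma, "scattering_curve"),
            inherits(beam, "beam_parameters"))
  if (any(sigma$intensity < 0)) stop("sigma must be >= 0 everywhere")
  structure(list(sigma = sigma, beam = beam), class = "noise_reference")
}

#' Synthetic reference noise curve
#'
#' A smooth, strictly positive sigma(q) stand-in for a measured neat-solvent
#' noise reference: a solvent-like hump profile (or a flat level) scaled to
#' `level`. Useful for planning when no measured reference is at hand.
#'
#' @param level Overall noise scale (e.u.), > 0.
#' @param q Momentum-transfer grid.
#' @param beam [beam_parameters()] attached as the acquisition parameters of
#'   the synthetic reference.
#' @param shape `"solvent_like"` (broad humps around the solvent peak) or
#'   `"flat"`.
#' @return A `noise_reference`.
#' @export
synthetic_sigma <- function(level, q, beam, shape = c("solvent_like", "flat")) {
  shape <- match.arg(shape)
  if (!is.numeric(level) || level <= 0) stop("level must be > 0")
  prof <- switch(shape,
                 flat = rep(1, length(q)),
                 solvent_like = 0.55 + exp(-((q - 1.4) / 0.7)^2) +
                   0.35 * exp(-((q - 4.5) / 2.2)^2))
  noise_reference(scattering_curve(q, level * prof,
                                   normalization = "per_solvent_molecule"),
                  beam)
}

#' Load a reference noise curve from a two-column text file
#'
#' Expects `q sigma` rows with a `#` header carrying the acquisition
#' parameters as `# f: <Hz>`, `# D: <s>`, `# n: <photons>` lines (parsed,
#' not decorative).
#'
#' @param path File path.
#' @return A `noise_reference`.
#' @export
read_sigma_reference <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_par <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(hit))
      stop("sigma reference ", path, " lacks required header '# ", key, ": ...'")
    as.numeric(sub(".*:\\s*", "", hit[1]))
  }
  curve <- load_curve(path, normalization = "per_solvent_molecule")
  noise_reference(curve,
                  beam_parameters(f = get_par("f"), D = get_par("D"),
                                  n = get_par("n")))
}

#' Write a reference noise curve with its acquisition header
#' @param ref A `noise_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sigma_reference <- function(ref, path) {
  write_curve(ref$sigma, path,
              header = list(kind = "sigma_solvent", units = "e.u.",
                            f = ref$beam$f, D = ref$beam$D, n = ref$beam$n))
}

#' Scale a reference noise curve to a target beam
#'
#' Shot-noise scaling: the per-curve standard deviation is proportional to
#' the square root of the incident photons per curve, so
#' \deqn{\sigma_{target}(q) = \sigma_{ref}(q)
#'   \sqrt{N_{target} / N_{ref}}.}
#'
#' @param ref A [noise_reference()].
#' @param target_beam [beam_parameters()] of the planned experiment.
#' @return A `scattering_curve` holding sigma_target(q).
#' @export
scale_sigma <- function(ref, target_beam) {
  stopifnot(inherits(ref, "noise_reference"))
  n_ref <- photons_per_curve(ref$beam)
  if (n_ref <= 0) stop("reference photon count is zero")
  fac <- sqrt(photons_per_curve(target_beam) / n_ref)
  scattering_curve(ref$sigma$q, fac * ref$sigma$intensity,
                   normalization = ref$sigma$normalization)
}

#' Number of difference curves in an accumulation
#'
#' One difference curve consumes a laser-on/laser-off pulse pair, so
#' `I = floor(f * t * d / 2)`. With t = 36 s at full duty cycle this gives
#' 540 curves at 30 Hz and 1.8e7 at 1 MHz.
#'
#' @param beam A [beam_parameters()] object.
#' @return Integer count I; a warning is raised when I = 0 (no averaging
#'   possible).
#' @export
n_difference_curves <- function(beam) {
  stopifnot(inherits(beam, "beam_parameters"))
  I <- floor(beam$f * beam$t * beam$d / 2)
  if (I < 1) warning("accumulation yields no complete on/off pulse pair (I = 0)")
  I
}

#' Averaged Gaussian noise realization
#'
#' Per q-point the mean of `I` independent draws from
#' `Normal(0, sigma_target(q))`. For large `I` the draw-average is sampled
#' through its exact distribution `Normal(0, sigma_target(q)/sqrt(I))`
#' (identical in law; the literal average is used while `I * length(q)`
#' stays below 2e5 draws). Reproducible for a fixed seed.
#'
#' @param sigma_target A `scattering_curve` of per-curve standard
#'   deviations.
#' @param I Number of averaged difference curves, >= 1.
#' @param seed Integer RNG seed (required: every stochastic run is seeded).
#' @return A `scattering_curve` holding the averaged noise realization,
#'   with `sigma = sigma_target/sqrt(I)` attached.
#' @export
generate_noise <- function(sigma_target, I, seed) {
  stopifnot(inherits(sigma_target, "scattering_curve"))
  if (!is.numeric(I) || I < 1) stop("I must be >= 1")
  if (missing(seed) || is.null(seed)) stop("a seed is required for noise generation")
  I <- floor(I)
  nq <- length(sigma_target$q)
  sd_mean <- sigma_target$intensity / sqrt(I)
  set.seed(seed)
  noise <- if (I * nq <= 2e5) {
    rowMeans(matrix(stats::rnorm(nq * I, mean = 0, sd = sigma_target$intensity),
                    nrow = nq))
  } else {
    stats::rnorm(nq, mean = 0, sd = sd_mean)
  }
  scattering_curve(sigma_target$q, noise, sigma = sd_mean,
                   normalization = sigma_target$normalization)
}
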