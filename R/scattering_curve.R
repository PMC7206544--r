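# ScatteringCurve: the common currency between modules. A q-grid (1/Angstrom)
# with intensities in electron units (e.u.), an optional per-point standard
# deviation, and a normalization tag recording whether values are per solute
# molecule or scaled to one solvent molecule.

#' Default momentum-transfer grid
#'
#' 0.3 to 8.0 1/Angstrom at 0.01 spacing, covering the q-range displayed in
#' typical TRXL difference-curve analyses.
#'
#' @param q_min,q_max,dq Grid limits and spacing (1/Angstrom).
#' @return Numeric vector of q values.
#' @export
default_q_grid <- function(q_min = 0.3, q_max = 8.0, dq = 0.01) {
  seq(q_min, q_max, by = dq)
}

#' Construct a scattering curve
#'
#' @param q Strictly increasing non-negative grid (1/Angstrom).
#' @param intensity Intensity values in electron units, aligned with `q`.
#' @param sigma Optional per-point standard deviation (>= 0).
#' @param normalization `"per_solute_molecule"` or `"per_solvent_molecule"`.
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL,
                             normalization = c("per_solute_molecule",
                                               "per_solvent_molecule")) {
  normalization <- match.arg(normalization)
  q <- as.double(q); intensity <- as.double(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (!is.null(sigma)) {
    sigma <- as.double(sigma)
    if (length(sigma) != length(q)) stop("sigma not aligned with q")
    if (any(!is.finite(sigma)) || any(sigma < 0)) stop("sigma must be >= 0")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 normalization = normalization),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat("scattering_curve:", length(x$q), "points, q in [",
      format(min(x$q)), ",", format(max(x$q)), "] 1/A,",
      x$normalization, if (!is.null(x$sigma)) "(with sigma)", "\n")
  cat("  intensity range [", format(min(x$intensity)), ",",
      format(max(x$intensity)), "] e.u.\n")
  invisible(x)
}

#' @export
plot.scattering_curve <- function(x, weight_q = TRUE, ...) {
  y <- if (weight_q) x$q * x$intensity else x$intensity
  graphics::plot(x$q, y, type = "l",
                 xlab = "q (1/Angstrom)",
                 ylab = if (weight_q) "q dS(q) (e.u.)" else "dS(q) (e.u.)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$q) == length(b$q) && max(abs(a$q - b$q)) <= tol
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("scattering curves are on different q-grids")
  invisible(TRUE)
}

# curve arithmetic on a shared grid (sigma is dropped; it is re-attached
# explicitly by the simulation assembly)
curve_lincomb <- function(curves, weights, normalization) {
  stopifnot(length(curves) == length(weights), length(curves) >= 1)
  for (i in seq_along(curves)[-1]) check_same_grid(curves[[1]], curves[[i]])
  v <- rep(0, length(curves[[1]]$q))
  for (i in seq_along(curves)) v <- v + weights[i] * curves[[i]]$intensity
  scattering_curve(curves[[1]]$q, v, normalization = normalization)
}
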