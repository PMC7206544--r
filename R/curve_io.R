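# Curve file I/O: 2-3 column whitespace text (q, value[, sigma]) with '#'
# header lines of the form "# key: value" recording units, normalization
# and generation parameters. Values are written with full double precision
# (%.17g) so a written curve re-reads to the identical numbers.

#' Write a scattering curve to a text file
#'
#' @param curve A `scattering_curve`.
#' @param path Output path.
#' @param header Named list of extra `# key: value` header entries.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, header = list()) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- c(list(format = "q[1/A] intensity[e.u.]",
                normalization = curve$normalization),
           header)
  if (!is.null(curve$sigma)) hdr$format <- "q[1/A] intensity[e.u.] sigma[e.u.]"
  lines <- sprintf("# %s: %s", names(hdr),
                   vapply(hdr, function(x) paste(format(x), collapse = " "),
                          character(1)))
  num <- function(x) sprintf("%.17g", x)
  body <- if (is.null(curve$sigma)) {
    paste(num(curve$q), num(curve$intensity))
  } else {
    paste(num(curve$q), num(curve$intensity), num(curve$sigma))
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a scattering curve from a text file
#'
#' Accepts two or three whitespace-delimited numeric columns
#' (q, intensity[, sigma]); `#` lines are comments. The normalization tag is
#' recovered from a `# normalization: ...` header when present.
#'
#' @param path File path.
#' @param normalization Fallback normalization tag when the file header has
#'   none.
#' @return A `scattering_curve`.
#' @export
load_curve <- function(path, normalization = "per_solute_molecule") {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  tagline <- grep("^#\\s*normalization\\s*:", hdr, value = TRUE)
  if (length(tagline)) normalization <- trimws(sub(".*:", "", tagline[1]))
  tab <- tryCatch(utils::read.table(text = lines, comment.char = "#"),
                  error = function(e) stop("curve parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (ncol(tab) < 2) stop("curve file ", path, " needs >= 2 numeric columns")
  scattering_curve(tab[[1]], tab[[2]],
                   sigma = if (ncol(tab) >= 3) tab[[3]] else NULL,
                   normalization = normalization)
}
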