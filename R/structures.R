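# Molecular species: element lists + Cartesian coordinates (Angstrom),
# standard XYZ file I/O, and the geometric descriptors used by the cage
# approximation (unweighted centroid and RMS molecular radius).

#' Construct a molecular structure
#'
#' @param elements Character vector of element symbols (length k >= 1).
#' @param coords Numeric k x 3 matrix of Cartesian coordinates in Angstrom.
#' @param name Optional species name.
#' @return An object of class `molecular_structure`.
#' @examples
#' i2 <- molecular_structure(c("I", "I"),
#'                           rbind(c(0, 0, 0), c(2.666, 0, 0)), "I2")
#' molecular_radius(i2)
#' @export
molecular_structure <- function(elements, coords, name = "") {
  coords <- as.matrix(coords)
  if (is.vector(coords)) coords <- matrix(coords, nrow = 1)
  if (length(elements) < 1) stop("structure must contain at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3)
    stop("coords must be a ", length(elements), " x 3 matrix")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  check_element(elements)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(list(name = as.character(name),
                 elements = as.character(elements),
                 coords = coords),
            class = "molecular_structure")
}

#' @export
print.molecular_structure <- function(x, ...) {
  cat("molecular_structure", if (nzchar(x$name)) sQuote(x$name) else "",
      "-", length(x$elements), "atoms:",
      paste(names(table(x$elements)), table(x$elements),
            sep = "x", collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s A `molecular_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(s) length(s$elements)

#' Read a structure from an XYZ file
#'
#' Standard XYZ layout: atom count line, free-text comment line, then one
#' `element x y z` row per atom (whitespace-delimited, Angstrom).
#'
#' @param path Path to an XYZ file.
#' @param name Species name; defaults to the file's base name.
#' @return A `molecular_structure`. The comment line is kept in the
#'   `comment` element but carries no semantics.
#' @export
read_xyz <- function(path, name = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("XYZ parse error in ", path, ": fewer than 2 lines")
  k <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(k) || k < 1)
    stop("XYZ parse error in ", path, " line 1: bad atom count ", sQuote(lines[1]))
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < k)
    stop("XYZ parse error in ", path, ": count line declares ", k,
         " atoms but only ", length(body), " atom rows found")
  elements <- character(k)
  coords <- matrix(NA_real_, k, 3)
  for (i in seq_len(k)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("XYZ parse error in ", path, " line ", i + 2, ": expected 'element x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz)))
      stop("XYZ parse error in ", path, " line ", i + 2, ": non-numeric coordinate")
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  s <- molecular_structure(elements, coords,
                           name = if (is.null(name)) sub("\\.xyz$", "", basename(path)) else name)
  s$comment <- lines[2]
  s
}

#' Write a structure to an XYZ file
#'
#' @param s A `molecular_structure`.
#' @param path Output path.
#' @param comment Comment line content.
#' @param digits Coordinate decimals (default 6).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(s, path, comment = s$name, digits = 6) {
  fmt <- paste0("%-2s %", digits + 6, ".", digits, "f %", digits + 6, ".",
                digits, "f %", digits + 6, ".", digits, "f")
  rows <- sprintf(fmt, s$elements, s$coords[, 1], s$coords[, 2], s$coords[, 3])
  writeLines(c(as.character(n_atoms(s)), comment, rows), path)
  invisible(path)
}

#' Unweighted centroid of a structure
#'
#' The plain mean of the atomic positions. Atomic masses are deliberately
#' ignored: the cage approximation characterizes the spatial extent of the
#' atom distribution, not the mass distribution.
#'
#' @param s A `molecular_structure`.
#' @return Numeric length-3 vector (Angstrom).
#' @export
centroid <- function(s) colMeans(s$coords)

#' Molecular radius (unweighted RMS radius)
#'
#' Root-mean-square distance of the atoms from the unweighted centroid:
#' \deqn{R_s = \sqrt{\frac{1}{k}\sum_{i=1}^{k} |r_i - c_s|^2}.}
#' The form parallels the radius of gyration but without mass weighting.
#' `R_s` sets the width of the linear ramp of the hard-sphere
#' pair-distribution function (see [hard_sphere_gr()]).
#'
#' @param s A `molecular_structure`.
#' @return Radius in Angstrom; 0 for a single atom.
#' @export
molecular_radius <- function(s) {
  d2 <- sweep(s$coords, 2, centroid(s))^2
  sqrt(mean(rowSums(d2)))
}
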