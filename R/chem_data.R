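# Element-wise constants: Cromer-Mann form factors and van der Waals radii.
# Both tables live as documented plain-text files under inst/extdata and are
# cached on first access.

.trxl_cache <- new.env(parent = emptyenv())

trxl_data_file <- function(name) {
  path <- system.file("extdata", name, package = "trxlsim")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}

cromer_mann_table <- function() {
  if (is.null(.trxl_cache$cm)) {
    tab <- utils::read.table(trxl_data_file("cromer_mann.tsv"),
                             header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    rownames(tab) <- tab$element
    .trxl_cache$cm <- tab
  }
  .trxl_cache$cm
}

vdw_table <- function() {
  if (is.null(.trxl_cache$vdw)) {
    tab <- utils::read.table(trxl_data_file("vdw_radii.tsv"),
                             header = TRUE, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    rownames(tab) <- tab$element
    .trxl_cache$vdw <- tab
  }
  .trxl_cache$vdw
}

#' Elements with packaged scattering constants
#'
#' @return Character vector of supported element symbols.
#' @export
supported_elements <- function() cromer_mann_table()$element

check_element <- function(element) {
  bad <- setdiff(unique(element), supported_elements())
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(supported_elements(), collapse = ", "), ")",
         call. = FALSE)
  invisible(element)
}

#' Atomic number of an element
#'
#' @param element Element symbol (e.g. `"C"`).
#' @return Integer atomic number Z.
#' @export
atomic_number <- function(element) {
  check_element(element)
  cromer_mann_table()[element, "Z"]
}

#' Atomic X-ray form factor f(q)
#'
#' Evaluates the analytic Cromer-Mann 4-Gaussian parameterization
#' \deqn{f(q) = \sum_{i=1}^{4} a_i \exp(-b_i s^2) + c, \quad s = q/4\pi,}
#' in electron units. At `q = 0` the form factor equals the atomic number
#' to within the fit accuracy of the tabulated coefficients (< 0.1 e).
#'
#' @param element Element symbol.
#' @param q Numeric vector of momentum-transfer values (1/Angstrom), >= 0.
#' @return Numeric vector of form-factor values aligned with `q`.
#' @examples
#' form_factor("C", 0)         # ~ 6
#' form_factor("I", c(0, 1, 2))
#' @export
form_factor <- function(element, q) {
  stopifnot(length(element) == 1)
  check_element(element)
  if (any(!is.finite(q)) || any(q < 0)) stop("q values must be finite and >= 0")
  row <- cromer_mann_table()[element, ]
  s2 <- (q / (4 * pi))^2
  f <- rep(row$c, length(q))
  for (i in 1:4) f <- f + row[[paste0("a", i)]] * exp(-row[[paste0("b", i)]] * s2)
  f
}

#' Van der Waals radius of an element
#'
#' @param element Element symbol.
#' @return Radius in Angstrom.
#' @export
vdw_radius <- function(element) {
  check_element(element)
  vdw_table()[element, "radius"]
}

#' Hard-sphere contact distance of an element pair
#'
#' The sum of the two van der Waals radii; this is the inner knot of the
#' trapezoidal hard-sphere pair-distribution function used by the cage term.
#'
#' @param element_i,element_j Element symbols; order does not matter.
#' @return Contact distance V_ij in Angstrom.
#' @examples
#' combined_vdw("C", "I")  # 1.70 + 1.98
#' @export
combined_vdw <- function(element_i, element_j) {
  vdw_radius(element_i) + vdw_radius(element_j)
}
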