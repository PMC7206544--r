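# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the Debye oracle is a literal pair-sum double loop,
# the cage oracle is adaptive numerical quadrature of the transform
# integrand, and kinetics are cross-checked by ODE integration.

# literal Debye double loop over all atom pairs (including self terms)
brute_force_debye <- function(s, q) {
  k <- length(s$elements)
  f <- lapply(s$elements, function(el) form_factor(el, q))
  total <- numeric(length(q))
  for (m in seq_len(k)) for (n in seq_len(k)) {
    r <- sqrt(sum((s$coords[m, ] - s$coords[n, ])^2))
    kern <- if (r == 0) rep(1, length(q)) else sin(q * r) / (q * r)
    total <- total + f[[m]] * f[[n]] * kern
  }
  total
}

# adaptive quadrature of int 4 pi r^2 (g - 1) sinc(qr) dr, one q at a time,
# split at the g(r) knots so the integrand is smooth on each panel
quadrature_excess_transform <- function(pd, q) {
  rmax <- max(pd$r)
  knots <- sort(unique(c(0, pd$r)))
  vapply(q, function(qv) {
    f <- function(r) {
      g <- eval_gr(pd, r)
      out <- 4 * pi * r^2 * (g - 1)
      s <- ifelse(qv * r < 1e-12, 1, sin(qv * r) / (qv * r))
      out * s
    }
    total <- 0
    for (i in seq_len(length(knots) - 1)) {
      if (knots[i + 1] <= knots[i]) next
      total <- total + stats::integrate(f, knots[i], knots[i + 1],
                                        rel.tol = 1e-12, abs.tol = 1e-12,
                                        subdivisions = 500L)$value
    }
    total
  }, numeric(1))
}

# random rigid-body transform (rotation + translation) of a structure
random_rigid_transform <- function(s) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shift <- stats::rnorm(3, sd = 5)
  molecular_structure(s$elements,
                      sweep(s$coords %*% t(R), 2, -shift), s$name)
}

# small demo system reused by assembly tests: iodoform photolysis in
# cyclohexane on a coarse grid (fast)
demo_system <- function() {
  scheme <- chi3_kinetic_scheme()
  trxl_system(
    reactant = chi3_structure(),
    species = list(isomer = chi2i_structure(),
                   radical = list(chi2_structure(), iodine_structure()),
                   ground = NULL),
    scheme = scheme,
    solvent = packaged_solvent("cyclohexane", q = demo_q()),
    c_solu = 0.002, excitation = 0.3, pump_wavelength_nm = 267)
}

demo_q <- function() default_q_grid(0.3, 8.0, 0.05)
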