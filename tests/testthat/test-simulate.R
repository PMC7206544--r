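test_that("populations match the closed-form single decay", {
  sp <- c("A", "B")
  rates <- matrix(c(0, 2e6, 0, 0), 2, 2, byrow = TRUE,
                  dimnames = list(sp, sp))
  sch <- kinetic_scheme(sp, rates, initial = c(1, 0))
  t1 <- 1 / 2e6
  p <- populations_at(sch, t1)
  expect_equal(p[["A"]], exp(-1), tolerance = 1e-12)
  expect_equal(p[["B"]], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("populations match brute-force ODE integration on a chain", {
  skip_if_not_installed("deSolve")
  sp <- c("A", "B", "C")
  rates <- matrix(0, 3, 3, dimnames = list(sp, sp))
  rates["A", "B"] <- 3.1e7; rates["B", "C"] <- 4.7e5
  rates["A", "C"] <- 1.2e6  # parallel branch
  sch <- kinetic_scheme(sp, rates, initial = c(0.9, 0.1, 0))
  A <- t(rates); diag(A) <- -rowSums(rates)
  rhs <- function(t, y, parms) list(as.vector(A %*% y))
  times <- c(0, 1e-8, 1e-7, 1e-6, 1e-5)
  sol <- deSolve::ode(y = c(0.9, 0.1, 0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-12, atol = 1e-14)
  for (i in seq_along(times)) {
    p <- populations_at(sch, times[i])
    expect_equal(unname(p), unname(sol[i, 2:4]), tolerance = 1e-10)
    expect_lt(abs(sum(p) - 1), 1e-10)
  }
})

test_that("negative delays leave all population in the ground state", {
  p <- populations_at(chi3_kinetic_scheme(), -3e-9)
  expect_true(all(p == 0))
})

test_that("t = 0+ populations reproduce the excitation branching", {
  p <- populations_at(chi3_kinetic_scheme(), 0)
  expect_equal(p[["isomer"]], 0.4)
  expect_equal(p[["radical"]], 0.6)
})

test_that("population is conserved across delays", {
  sch <- chi3_kinetic_scheme()
  for (t in c(0, 1e-10, 3e-8, 1e-6, 1e-4)) {
    expect_lt(abs(sum(populations_at(sch, t)) - sum(sch$initial)), 1e-10)
  }
  expect_error(kinetic_scheme(c("A", "B"),
                              matrix(c(0, -1, 0, 0), 2, 2), c(1, 0)),
               ">= 0")
})

test_that("the noise-free assembly equals the sum of its components", {
  sys <- demo_system()
  q <- demo_q()
  beam <- facility_beam("xfel_low_rep")
  ref <- synthetic_sigma(0.03, q, beam)
  clean <- simulate_difference(sys, 1e-10, beam, ref, q = q, noise = FALSE)
  comp <- attr(clean, "components")
  expect_lt(max(abs(clean$intensity - (comp$solute$intensity +
                                         comp$cage$intensity +
                                         comp$solvent$intensity))), 1e-12)
  # all population in the (recovered) reactant, no thermal state -> zero
  sys0 <- demo_system(); sys0$excitation <- 0
  zero <- simulate_difference(sys0, 1e-10, beam, ref, q = q, noise = FALSE)
  expect_lt(max(abs(zero$intensity)), 1e-9)
})

test_that("noise-on residual std matches sigma_target/sqrt(I)", {
  sys <- demo_system()
  q <- default_q_grid(0.3, 8.0, 0.01)
  beam <- facility_beam("xfel_low_rep")
  ref <- synthetic_sigma(0.03, q, beam, shape = "flat")
  clean <- simulate_difference(sys, 1e-10, beam, ref, q = q, noise = FALSE)
  noisy <- simulate_difference(sys, 1e-10, beam, ref, q = q, seed = 3)
  resid <- noisy$intensity - clean$intensity
  expected_sd <- 0.03 / sqrt(540)
  expect_lt(abs(stats::sd(resid) - expected_sd) / expected_sd, 0.10)
  again <- simulate_difference(sys, 1e-10, beam, ref, q = q, seed = 3)
  expect_identical(noisy$intensity, again$intensity)
})

test_that("series allocation follows the delay-count noise trade-off", {
  sys <- demo_system()
  q <- demo_q()
  beam <- facility_beam("synchrotron")
  ref <- synthetic_sigma(0.03, q, beam)
  mk <- function(M) simulation_plan(seq(1e-10, 1e-6, length.out = M),
                                    total_time = 24 * 3600, beam = beam,
                                    noise_ref = ref, duty_cycle = 0.7,
                                    seed = 11)
  s100 <- simulate_series(mk(100), sys, q = q)
  s4000 <- simulate_series(mk(4000), sys, q = q)
  r100 <- plan_report(s100); r4000 <- plan_report(s4000)
  expect_identical(nrow(r100), 100L)
  # per-delay noise std grows ~ sqrt(40) when delays go 100 -> 4000
  expect_equal(r4000$sigma_bar[1] / r100$sigma_bar[1], sqrt(40),
               tolerance = 0.01)
  # identical signal -> SNR ratio is the inverse
  expect_equal(r100$snr[1] / r4000$snr[1], sqrt(40), tolerance = 0.01)
})

test_that("reference delays are noise-only and doubling time helps by sqrt(2)", {
  sys <- demo_system()
  q <- demo_q()
  beam <- facility_beam("synchrotron")
  ref <- synthetic_sigma(0.03, q, beam)
  plan <- simulation_plan(c(-3e-9, 1e-10), total_time = 7200, beam = beam,
                          noise_ref = ref, duty_cycle = 0.7, seed = 2)
  ser <- simulate_series(plan, sys, q = q)
  neg <- ser$curves[[1]]
  comp <- attr(neg, "components")
  expect_true(all(comp$solute$intensity == 0))
  expect_true(all(comp$solvent$intensity == 0))
  expect_lt(max(abs(neg$intensity)), 10 * max(neg$sigma))
  plan2 <- simulation_plan(c(-3e-9, 1e-10), total_time = 14400, beam = beam,
                           noise_ref = ref, duty_cycle = 0.7, seed = 2)
  ser2 <- simulate_series(plan2, sys, q = q)
  expect_equal(plan_report(ser)$sigma_bar[1] / plan_report(ser2)$sigma_bar[1],
               sqrt(2), tolerance = 1e-6)
})

test_that("the planning table reports one row per delay with SNR sentinel", {
  sys <- demo_system()
  q <- demo_q()
  beam <- facility_beam("synchrotron")
  ref <- synthetic_sigma(0.03, q, beam)
  plan <- simulation_plan(1e-10, total_time = 3600, beam = beam,
                          noise_ref = ref, seed = 1)
  rep_off <- plan_report(simulate_series(plan, sys, q = q, noise = FALSE))
  expect_identical(nrow(rep_off), 1L)
  expect_true(is.infinite(rep_off$snr[1]))
})
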