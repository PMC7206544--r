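test_that("photon accounting multiplies out and doubles with exposure", {
  expect_equal(photons_per_curve(beam_parameters(30, 1, 1e12)), 3e13)
  expect_equal(photons_per_curve(beam_parameters(1000, 1.5, 5e8)), 7.5e11)
  b <- beam_parameters(100, 2, 1e9)
  b2 <- beam_parameters(100, 4, 1e9)
  expect_equal(photons_per_curve(b2), 2 * photons_per_curve(b))
  expect_error(beam_parameters(-1, 1, 1), "positive")
  expect_error(beam_parameters(30, 1, 1e12, d = 1.3), "duty")
})

test_that("sigma scaling follows the square-root photon-count law", {
  q <- demo_q()
  ref <- synthetic_sigma(0.05, q, beam_parameters(30, 1 / 30, 1e12))
  same <- scale_sigma(ref, beam_parameters(30, 1 / 30, 1e12))
  expect_equal(same$intensity, ref$sigma$intensity, tolerance = 1e-14)
  quad <- scale_sigma(ref, beam_parameters(30, 4 / 30, 1e12))
  expect_equal(quad$intensity, 2 * ref$sigma$intensity, tolerance = 1e-14)
  # low-rep XFEL (1e12 photons/curve) to high-rep XFEL (3e10 photons/curve)
  hi <- scale_sigma(ref, facility_beam("xfel_high_rep"))
  expect_equal(hi$intensity / ref$sigma$intensity,
               rep(sqrt(0.03), length(q)), tolerance = 1e-12)
})

test_that("sigma scaling composes transitively", {
  q <- demo_q()
  a <- beam_parameters(30, 1 / 30, 1e12)
  b <- beam_parameters(1000, 1.5, 5e8)
  c_ <- beam_parameters(1e6, 1e-6, 3e10)
  ref_a <- synthetic_sigma(0.04, q, a)
  via_b <- scale_sigma(noise_reference(scale_sigma(ref_a, b), b), c_)
  direct <- scale_sigma(ref_a, c_)
  expect_equal(via_b$intensity, direct$intensity, tolerance = 1e-12)
})

test_that("difference-curve counts reproduce the pulse-pair arithmetic", {
  expect_identical(n_difference_curves(beam_parameters(30, 1 / 30, 1e12,
                                                       t = 36, d = 1)), 540)
  expect_equal(n_difference_curves(beam_parameters(1e6, 1e-6, 3e10,
                                                   t = 36, d = 1)), 1.8e7)
  expect_warning(n_difference_curves(beam_parameters(30, 1, 1e12, t = 0.01)),
                 "pulse pair")
})

test_that("generated noise is seeded, zero for zero sigma, and 1/sqrt(I)", {
  q <- seq(0.3, 2.29, by = 0.01)  # 200 points
  zero <- scattering_curve(q, rep(0, length(q)))
  expect_true(all(generate_noise(zero, 50, seed = 1)$intensity == 0))
  unit <- scattering_curve(q, rep(1, length(q)))
  a <- generate_noise(unit, 100, seed = 42)
  b <- generate_noise(unit, 100, seed = 42)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity,
                         generate_noise(unit, 100, seed = 43)$intensity))
  m <- generate_noise(unit, 1e4, seed = 7)
  expect_lt(abs(stats::sd(m$intensity) - 0.01) / 0.01, 0.05)
  expect_equal(m$sigma, rep(1 / sqrt(1e4), length(q)))
  expect_error(generate_noise(unit, 0, seed = 1), "I must be")
  expect_error(generate_noise(unit, 10), "seed")
})

test_that("averaged-noise amplitude decays with log-log slope -1/2", {
  q <- default_q_grid(0.3, 8.0, 0.0077)   # 1001 points
  unit <- scattering_curve(q, rep(1, length(q)))
  I_values <- c(1e2, 1e3, 1e4)
  stds <- vapply(seq_along(I_values), function(i)
    stats::sd(generate_noise(unit, I_values[i], seed = 100 + i)$intensity),
    numeric(1))
  slope <- stats::coef(stats::lm(log(stds) ~ log(I_values)))[[2]]
  expect_lt(abs(slope - (-0.5)), 0.05)
})

test_that("synthetic references are positive, homogeneous, and file-stable", {
  q <- demo_q()
  beam <- facility_beam("synchrotron")
  flat <- synthetic_sigma(0.2, q, beam, shape = "flat")
  expect_true(all(flat$sigma$intensity == 0.2))
  ref <- synthetic_sigma(0.05, q, beam)
  expect_true(all(ref$sigma$intensity > 0))
  ref3 <- synthetic_sigma(0.15, q, beam)
  expect_equal(ref3$sigma$intensity, 3 * ref$sigma$intensity,
               tolerance = 1e-14)
  path <- withr::local_tempfile(fileext = ".txt")
  write_sigma_reference(ref, path)
  back <- read_sigma_reference(path)
  expect_equal(back$sigma$intensity, ref$sigma$intensity)
  expect_equal(back$beam$f, beam$f)
  expect_equal(back$beam$n, beam$n)
})
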