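test_that("single atoms and homonuclear diatomics match closed forms", {
  q <- default_q_grid()
  c1 <- molecular_structure("C", matrix(0, 1, 3))
  expect_equal(debye_intensity(c1, q)$intensity, form_factor("C", q)^2)
  expect_lt(abs(debye_intensity(c1, 0)$intensity - 36), 0.1 * 12 + 0.01)

  r <- 2.666
  i2 <- molecular_structure(c("I", "I"), rbind(c(0, 0, 0), c(r, 0, 0)))
  f <- form_factor("I", q)
  closed <- 2 * f^2 * (1 + sin(q * r) / (q * r))
  got <- debye_intensity(i2, q)$intensity
  expect_lt(max(abs(got - closed) / abs(closed)), 1e-10)
})

test_that("Debye intensity equals the brute-force pair sum on fixtures", {
  q <- demo_q()
  for (s in list(chi3_structure(), chi2i_structure(), cyclohexane_structure(),
                 azobenzene_structure("trans"))) {
    got <- debye_intensity(s, q)$intensity
    want <- brute_force_debye(s, q)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
})

test_that("Debye intensity is invariant under rigid motion and S(0) = (sum Z)^2", {
  set.seed(5)
  q <- demo_q()
  s <- chi2i_structure()
  base <- debye_intensity(s, q)$intensity
  for (i in 1:3) {
    moved <- debye_intensity(random_rigid_transform(s), q)$intensity
    expect_lt(max(abs(moved - base)) / max(base), 1e-9)
  }
  z_tot <- sum(vapply(s$elements, atomic_number, numeric(1)))
  expect_equal(debye_intensity(s, 0)$intensity, z_tot^2,
               tolerance = 1e-3)  # limited by form-factor fit accuracy
})

test_that("solute difference vanishes for null reactions", {
  q <- demo_q()
  chi3 <- chi3_structure()
  ch_zero <- reaction_channel(chi3, list(reaction_product(chi2i_structure(),
                                                          fraction = 1)),
                              r_str = 0)
  expect_true(all(solute_difference(ch_zero, 0.002, 9.25, q)$intensity == 0))
  ch_id <- reaction_channel(chi3, list(reaction_product(chi3, fraction = 1)),
                            r_str = 0.3)
  expect_true(all(abs(solute_difference(ch_id, 0.002, 9.25, q)$intensity) < 1e-12))
})

test_that("solute difference is linear in r_str and additive over channels", {
  q <- demo_q()
  chi3 <- chi3_structure()
  iso <- reaction_product(chi2i_structure(), fraction = 1)
  rad <- reaction_product(chi2_structure(), iodine_structure(), fraction = 1)
  both <- reaction_channel(chi3, list(
    reaction_product(chi2i_structure(), fraction = 0.4),
    reaction_product(chi2_structure(), iodine_structure(), fraction = 0.6)),
    r_str = 0.3)
  d_iso <- solute_difference(reaction_channel(chi3, list(iso), 0.3),
                             0.002, 9.25, q)$intensity
  d_rad <- solute_difference(reaction_channel(chi3, list(rad), 0.3),
                             0.002, 9.25, q)$intensity
  d_both <- solute_difference(both, 0.002, 9.25, q)$intensity
  expect_equal(d_both, 0.4 * d_iso + 0.6 * d_rad, tolerance = 1e-12)

  half <- reaction_channel(chi3, list(iso), r_str = 0.15)
  full <- reaction_channel(chi3, list(iso), r_str = 0.3)
  expect_equal(2 * solute_difference(half, 0.002, 9.25, q)$intensity,
               solute_difference(full, 0.002, 9.25, q)$intensity,
               tolerance = 1e-12)
})

test_that("the q -> 0 difference follows the direct S(0) evaluation", {
  qlow <- c(1e-6, 0.01)
  chi3 <- chi3_structure()
  ch <- reaction_channel(chi3, list(
    reaction_product(chi2_structure(), iodine_structure(), fraction = 1)),
    r_str = 0.25)
  got <- solute_difference(ch, 0.002, 9.25, qlow)$intensity[1]
  s_r <- debye_intensity(chi3, qlow)$intensity[1]
  s_p <- debye_intensity(chi2_structure(), qlow)$intensity[1] +
    debye_intensity(iodine_structure(), qlow)$intensity[1]
  expect_equal(got, (0.002 / 9.25) * 0.25 * (s_p - s_r), tolerance = 1e-12)
})

test_that("invalid channels and concentrations are rejected", {
  chi3 <- chi3_structure()
  expect_error(reaction_channel(chi3, list(
    reaction_product(chi2i_structure(), fraction = 0.5)), 0.3), "sum to 1")
  expect_error(reaction_channel(chi3, list(
    reaction_product(chi3, fraction = 1)), 1.2), "r_str")
  ch <- reaction_channel(chi3, list(reaction_product(chi3, fraction = 1)), 0.5)
  expect_error(solute_difference(ch, -1, 9.25, demo_q()), "positive")
})
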