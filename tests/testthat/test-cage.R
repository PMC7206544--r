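test_that("the hard-sphere trapezoid takes its defining values", {
  pd <- hard_sphere_gr(3.5, 2.0)
  expect_equal(eval_gr(pd, 3.0), 0)
  expect_equal(eval_gr(pd, 5.5), 1)
  expect_equal(eval_gr(pd, 4.5), 0.5)
  expect_equal(eval_gr(pd, 10), 1)
  # continuity at both knots
  eps <- 1e-9
  expect_lt(abs(eval_gr(pd, 3.5 + eps) - eval_gr(pd, 3.5 - eps)), 1e-6)
  expect_lt(abs(eval_gr(pd, 5.5 + eps) - eval_gr(pd, 5.5 - eps)), 1e-6)
  # degenerate trapezoid (single atom solute) is a step
  st <- hard_sphere_gr(3.5, 0)
  expect_equal(eval_gr(st, 3.49), 0)
  expect_equal(eval_gr(st, 3.51), 1)
})

test_that("bulk solvent (g == 1 everywhere) gives an exactly zero cage term", {
  q <- demo_q()
  flat <- pair_distribution(c(0, 10), c(1, 1), "C", "C")
  comp <- solvent_composition(c(C = 6, H = 12), mass_density = 0.779,
                              molar_mass = 84.16)
  pdfs <- list()
  for (ei in c("C", "H", "I")) for (ej in c("C", "H"))
    pdfs <- c(pdfs, list(pair_distribution(c(0, 10), c(1, 1), ei, ej)))
  cg <- cage_intensity(chi3_structure(), comp, q, pdfs = pdfs)
  expect_true(all(cg$intensity == 0))
})

test_that("the analytic transform matches adaptive quadrature", {
  q <- c(demo_q(), 0.31, 1.005, 7.99)
  pd <- hard_sphere_gr(combined_vdw("I", "C"),
                       molecular_radius(chi3_structure()), "I", "C")
  analytic <- trxlsim:::excess_sine_transform(pd, q)
  numeric <- quadrature_excess_transform(pd, q)
  expect_lt(max(abs(analytic - numeric)) / max(abs(numeric)), 1e-6)
})

test_that("cage intensity is linear in solvent density and atom counts", {
  q <- demo_q()
  s <- chi3_structure()
  base <- solvent_composition(c(C = 6, H = 12), number_density = 0.005549)
  double <- solvent_composition(c(C = 6, H = 12), number_density = 2 * 0.005549)
  c1 <- cage_intensity(s, base, q)$intensity
  c2 <- cage_intensity(s, double, q)$intensity
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("compact support makes the result independent of grid extension", {
  q <- demo_q()
  v <- combined_vdw("I", "C"); rs <- molecular_radius(chi3_structure())
  pd <- hard_sphere_gr(v, rs, "I", "C")
  extended <- pair_distribution(c(pd$r, 2 * max(pd$r)), c(pd$g, 1), "I", "C")
  expect_equal(trxlsim:::excess_sine_transform(pd, q),
               trxlsim:::excess_sine_transform(extended, q),
               tolerance = 1e-12)
})

test_that("a file RDF encoding the trapezoid reproduces the analytic path", {
  q <- demo_q()
  v <- combined_vdw("C", "C"); rs <- molecular_radius(chi3_structure())
  pd <- hard_sphere_gr(v, rs, "C", "C")
  path <- withr::local_tempfile(fileext = ".txt")
  r <- sort(unique(c(seq(0, v + rs + 1, by = 0.002), pd$r)))
  writeLines(c("# trapezoid encoded on a fine grid",
               paste(sprintf("%.10f", r), sprintf("%.10f", eval_gr(pd, r)))),
             path)
  loaded <- load_rdf(path, "C", "C")
  expect_equal(trxlsim:::excess_sine_transform(loaded, q),
               trxlsim:::excess_sine_transform(pd, q),
               tolerance = 1e-6)
})

test_that("RDF parsing rejects bad files and flat files give zero", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), p)
  expect_error(load_rdf(p), "parse error")
  writeLines(c("1 1", "0.5 1"), p)
  expect_error(load_rdf(p), "monotone")
  writeLines(c("0 1", "1 -0.2"), p)
  expect_error(load_rdf(p), "negative")
  writeLines(c("0 1", "5 1", "10 1"), p)
  flat <- load_rdf(p, "C", "C")
  expect_true(all(trxlsim:::excess_sine_transform(flat, demo_q()) == 0))
})

test_that("a missing pair distribution is reported by pair name", {
  comp <- solvent_composition(c(C = 6, H = 12), number_density = 0.005549)
  pdfs <- list(hard_sphere_gr(3.4, 1.7, "C", "C"))
  expect_error(cage_intensity(chi3_structure(), comp, demo_q(), pdfs = pdfs),
               "\\(C, H\\)|\\(H, C\\)")
})

test_that("cage difference vanishes for null reactions and assembles linearly", {
  q <- demo_q()
  chi3 <- chi3_structure()
  comp <- solvent_composition(c(C = 6, H = 12), mass_density = 0.779,
                              molar_mass = 84.16)
  ch0 <- reaction_channel(chi3, list(reaction_product(chi2i_structure(),
                                                      fraction = 1)), 0)
  expect_true(all(cage_difference(ch0, comp, 0.002, 9.25, q)$intensity == 0))
  ch_id <- reaction_channel(chi3, list(reaction_product(chi3, fraction = 1)), 0.3)
  expect_lt(max(abs(cage_difference(ch_id, comp, 0.002, 9.25, q)$intensity)), 1e-14)

  ch <- reaction_channel(chi3, list(
    reaction_product(chi2i_structure(), fraction = 0.4),
    reaction_product(chi2_structure(), iodine_structure(), fraction = 0.6)),
    r_str = 0.3)
  got <- cage_difference(ch, comp, 0.002, 9.25, q)$intensity
  # reassemble by hand from per-species cage intensities
  s_r <- cage_intensity(chi3, comp, q)$intensity
  s_iso <- cage_intensity(chi2i_structure(), comp, q)$intensity
  s_rad <- cage_intensity(list(chi2_structure(), iodine_structure()),
                          comp, q)$intensity
  want <- (0.002 / 9.25) * 0.3 * (0.4 * s_iso + 0.6 * s_rad - s_r)
  expect_equal(got, want, tolerance = 1e-12)
})
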