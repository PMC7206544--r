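# Offline fixture generator: writes every input the simulator consumes as
# small plain-text files (XYZ structures, synthetic sigma references for
# three facility presets, synthetic solvent differential curves, a demo RDF,
# and ready-to-run YAML configs), so a full run never needs a download.

fixture_structures <- function() {
  list(chi3 = chi3_structure(), chi2i = chi2i_structure(),
       chi2 = chi2_structure(), iodine = iodine_structure(),
       cyclohexane = cyclohexane_structure(),
       ab_trans = azobenzene_structure("trans"),
       ab_cis = azobenzene_structure("cis"),
       br2ab_trans = dibromoazobenzene_structure("trans"),
       br2ab_cis = dibromoazobenzene_structure("cis"))
}

#' Generate the packaged fixture file set
#'
#' Writes (deterministically; reruns with the same seed are identical):
#' XYZ toy structures for the iodoform and azobenzene examples, synthetic
#' reference noise curves for three facility presets with their acquisition
#' headers, synthetic solvent differential curves, a trapezoidal demo RDF,
#' and three ready-to-run configs (single-delay demo, synchrotron
#' time-delay series, heavy-atom/facility comparison).
#'
#' @param out_dir Writable output directory (created if absent).
#' @param seed Integer seed recorded in the generated configs.
#' @return Character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create fixture directory ", out_dir)
  for (d in c("xyz", "sigma", "solvent", "rdf"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  written <- character(0)
  add <- function(p) { written <<- c(written, p); p }

  for (nm in names(fixture_structures()))
    write_xyz(fixture_structures()[[nm]],
              add(file.path(out_dir, "xyz", paste0(nm, ".xyz"))),
              comment = paste(nm, "synthetic fixture geometry"))

  # facility sigma references: shot-noise-consistent levels (sigma ~ sqrt(N))
  # anchored at 0.03 e.u. for the synchrotron preset
  q <- default_q_grid()
  base_n <- photons_per_curve(facility_beam("synchrotron"))
  for (fac in c("synchrotron", "xfel_low_rep", "xfel_high_rep")) {
    beam <- facility_beam(fac)
    level <- 0.03 * sqrt(photons_per_curve(beam) / base_n)
    ref <- synthetic_sigma(level, q, beam)
    write_sigma_reference(ref, add(file.path(out_dir, "sigma",
                                             paste0(fac, ".txt"))))
  }

  for (sv in c("cyclohexane", "acetonitrile")) {
    mod <- packaged_solvent(sv, q)
    write_curve(mod$dsdt, add(file.path(out_dir, "solvent",
                                        paste0(sv, "_dsdt.txt"))),
                header = list(kind = "dS_dT_rho (synthetic)", solvent = sv,
                              units = "e.u. per solvent molecule per K"))
    write_curve(mod$dsdrho, add(file.path(out_dir, "solvent",
                                          paste0(sv, "_dsdrho.txt"))),
                header = list(kind = "dS_drho_T (synthetic)", solvent = sv,
                              units = "e.u. per solvent molecule per (g/mL)"))
  }

  # demo RDF: the C..C hard-sphere trapezoid for CHI3 in cyclohexane
  pd <- hard_sphere_gr(combined_vdw("C", "C"),
                       molecular_radius(chi3_structure()), "C", "C")
  r <- seq(0, max(pd$r) + 1, by = 0.05)
  writeLines(c("# synthetic trapezoidal RDF fixture (r[A], g)",
               paste(sprintf("%.6f", r), sprintf("%.10f", eval_gr(pd, r)))),
             add(file.path(out_dir, "rdf", "cc_trapezoid.txt")))

  writeLines(demo_config_yaml(seed), add(file.path(out_dir, "demo_chi3.yaml")))
  writeLines(series_config_yaml(seed), add(file.path(out_dir, "series_chi3.yaml")))
  writeLines(ab_config_yaml(seed), add(file.path(out_dir, "ab_xfel.yaml")))
  invisible(written)
}

chi3_config_core <- function() {
  c("reactant: xyz/chi3.xyz",
    "species:",
    "  isomer:",
    "    structures: [xyz/chi2i.xyz]",
    "  radical:",
    "    structures: [xyz/chi2.xyz, xyz/iodine.xyz]",
    "  ground: reactant",
    "kinetics:",
    "  initial: {isomer: 0.4, radical: 0.6, ground: 0.0}",
    "  rates:",
    "    - {from: isomer, to: ground, k: 1.1494e+6}",
    "    - {from: radical, to: ground, k: 2.0e+4}",
    "solvent: cyclohexane",
    "solute:",
    "  concentration: 0.002",
    "  excitation: 0.3",
    "  r_heat: 0.0",
    "  pump_wavelength: 267")
}

demo_config_yaml <- function(seed) {
  c("title: iodoform photolysis in cyclohexane, single delay (demo)",
    chi3_config_core(),
    "beam: {f: 30, D: 0.03333333333333333, \"n\": 1.0e+12, t: 36, d: 1.0}",
    "noise: {source: synthetic, level: 0.0346}",
    "delay: 1.0e-10",
    "q_grid: {min: 0.3, max: 8.0, step: 0.01}",
    paste0("seed: ", seed))
}

series_config_yaml <- function(seed) {
  c("title: iodoform photolysis, synchrotron time-delay series",
    chi3_config_core(),
    "beam: {f: 1000, D: 1.5, \"n\": 5.0e+8}",
    "noise: {source: synthetic, level: 0.03}",
    "delays: [-3.0e-9, 1.0e-10, 3.0e-8, 1.0e-6]",
    "total_time: 86400",
    "duty_cycle: 0.7",
    "q_grid: {min: 0.3, max: 8.0, step: 0.01}",
    paste0("seed: ", seed))
}

ab_config_yaml <- function(seed) {
  c("title: azobenzene cis->trans photoisomerization at a high-rep XFEL",
    "reactant: xyz/ab_cis.xyz",
    "species:",
    "  trans:",
    "    structures: [xyz/ab_trans.xyz]",
    "kinetics:",
    "  initial: {trans: 1.0}",
    "  rates: []",
    "solvent: cyclohexane",
    "solute:",
    "  concentration: 0.05",
    "  excitation: 0.1",
    "  r_heat: 0.5",
    "  pump_wavelength: 355",
    "beam: {f: 1.0e+6, D: 1.0e-6, \"n\": 3.0e+10, t: 36, d: 1.0}",
    "noise: {source: synthetic, level: 0.006}",
    "delay: 1.0e-10",
    "q_grid: {min: 0.3, max: 8.0, step: 0.01}",
    paste0("seed: ", seed))
}
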