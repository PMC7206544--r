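---
title: "Simulating signal and noise for time-resolved X-ray solution scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating signal and noise for time-resolved X-ray solution scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxlsim)
```

## The problem

Time-resolved X-ray solution scattering (TRXL, also called TRXSS or
liquidography) probes structural dynamics of a photoreaction in solution:
an optical pump pulse triggers the reaction, an X-ray pulse probes it after
a controlled delay, and the observable is the laser-on minus laser-off
difference scattering curve $\Delta S(q)$. The solute structural signal is
small against the solvent background, so whether a proposed experiment is
feasible — at a given beamline, solute, solvent and accumulation time —
is a quantitative question that should be answered before beam time is
requested. `trxlsim` answers it by simulating the four components of the
difference signal,

$$\Delta S_{sim}(q) = \Delta S_{solute}(q) + \Delta S_{cage}(q)
  + \Delta S_{solvent}(q) + \Delta S_{noise}(q),$$

and assembling them into per-delay curves with realistic signal-to-noise.

## The four terms

### Solute-only term

For randomly oriented molecules the scattering intensity of a chemical
species is given by the Debye equation over all atom pairs,

$$S_k(q) = \sum_m \sum_n f_m(q)\, f_n(q)\,
  \frac{\sin(q\,r_{nm})}{q\,r_{nm}},$$

with Cromer-Mann analytic form factors $f(q)$ (International Tables
4-Gaussian convention, packaged as plain-text coefficients; $f(0) = Z$
within the fit accuracy of about 0.1 e). The self ($m = n$) terms are
included; they cancel in differences between species with identical atom
inventories (isomerizations) but not in dissociations, which is the correct
behaviour for difference signals between channels. The solute-only
difference for a reaction channel with excitation ratio $r_{str}$ and
product branching fractions $\phi_p$ is

$$\Delta S_{solute}(q) = \frac{c_{solu}}{c_{solv}}\, r_{str}
  \left[\sum_p \phi_p S_p(q) - S_r(q)\right],$$

scaled to one mole of solvent molecules, the convention in which difference
curves are conventionally displayed. A dissociation product (e.g. a radical
pair) is represented as a list of fragments whose intensities add without
cross terms — the fragments are assumed uncorrelated once separated.

### Cage term

The solute-solvent cross term is the sine Fourier transform of the
pair-distribution functions $g_{ij}(r)$ between solute element $i$ and
solvent element $j$:

$$S_{cage}(q) = \sum_i \sum_j f_i(q) f_j(q)\, N_i\, n_j
  \int 4\pi r^2 \left[g_{ij}(r) - 1\right]
  \frac{\sin(qr)}{qr}\, dr,$$

where $N_i$ counts atoms of type $i$ in the solute and $n_j$ is the bulk
number density of solvent atoms of type $j$ (molecule number density times
atoms per molecule — this removes any simulation-box dependence and puts
the result on a per-solute-molecule scale). Instead of running molecular
dynamics, each $g_{ij}$ is approximated by a trapezoid: zero below the van
der Waals contact $V_{ij}$ (Bondi radii), one beyond $V_{ij} + R_s$, and a
linear ramp in between, where $R_s$ is the unweighted RMS radius of the
solute,

$$R_s = \left(\tfrac{1}{k}\sum_i |r_i - c_s|^2\right)^{1/2},$$

the analogue of the radius of gyration with atomic masses ignored — the
cage is shaped by where atoms are, not by how heavy they are. The same
reasoning fixes the centre $c_s$ as the unweighted centroid.

**Numerical choice.** Because the trapezoid (and any file RDF, which is
linearly interpolated) is piecewise linear, the transform integral is
evaluated in closed form on each linear segment using the elementary
antiderivatives of $r\sin(qr)$ and $r^2\sin(qr)$, with a series limit for
$q \to 0$. This is exact — no quadrature step size exists to tune — and the
compact support of $g - 1$ makes windowing unnecessary. The test suite
verifies the closed form against adaptive numerical quadrature to better
than $10^{-6}$ relative. Users with MD-derived RDFs can load them with
`load_rdf()` and they travel the identical code path.

The hard-sphere cage is a deliberately coarse model: it reproduces the
overall amplitude and trend of MD-derived cage terms above roughly
1 A$^{-1}$, which is sufficient for feasibility estimates, but not the fine
oscillations from real solvation-shell structure.

### Solvent heating term

Excited solute molecules that do not enter a structural channel return the
photon energy to the solvent as heat. Assuming complete, loss-free transfer
(an upper bound, chosen so the solvent signal is never underestimated), the
heat per mole of solvent is

$$Q_{max} = \frac{hc}{\lambda} N_A\, r_{heat}\, \frac{c_{excited}}{c_{solv}},$$

giving the isochoric temperature-rise limit $\Delta T_{max} = Q_{max}/C_v$
and the isobaric density-change limit
$\Delta\rho_{max} = -\alpha_p (Q_{max}/C_p)\, \rho_0$. The time dependence
is the standard fast approximation: $\Delta T$ holds at $\Delta T_{max}$ up
to 10 ns, then decreases linearly (in $t$, not $\log t$) to zero by 3 us,
while $\Delta\rho$ rises linearly from zero to $\Delta\rho_{max}$ over the
same window; both are zero before the pump. The solvent signal is then the
bilinear contraction

$$\Delta S_{solvent}(q) = \Delta T \left(\frac{\delta S}{\delta T}\right)_\rho
  + \Delta\rho \left(\frac{\delta S}{\delta\rho}\right)_T.$$

**Units.** $\Delta\rho$ is carried in g/mL and the packaged
$(\delta S/\delta\rho)_T$ curves are defined per unit g/mL change, which
keeps the contraction unit-consistent with the $\rho_0$ factor in
$\Delta\rho_{max}$.

**Synthetic differentials.** The packaged solvents (cyclohexane,
acetonitrile, methanol, ethanol) carry literature thermophysical constants
but *synthetic* differential curves — smooth damped oscillations with
realistic amplitude and extent. They make the heating term exercise every
code path offline; they do not reproduce any measured solvent response.
Quantitative work should load measured differentials from two-column text
files.

### Noise term

Shot (quantum) noise dominates a typical TRXL measurement, so the noise
model is anchored on a reference neat-solvent noise curve
$\sigma_{solvent}(q)$ — the per-point standard deviation of repeated
difference curves — together with the acquisition parameters of that
reference (repetition rate $f$, exposure $D$, photons per pulse $n$).
Since the variance of a photon-counting measurement is proportional to the
incident photons per curve $N = f D n$,

$$\sigma_{target}(q) = \sigma_{ref}(q) \sqrt{N_{target}/N_{ref}}.$$

A measured reference inevitably contains systematic noise too, so treating
it as pure shot noise overestimates the target noise: the estimate is a
worst-case upper bound, which is the conservative direction for
feasibility planning. Inter-bin noise correlations (from e.g. jet-thickness
fluctuations) are deliberately not modelled.

One accumulation of nominal length $t$ at duty cycle $d$ yields
$I = \lfloor f t d / 2 \rfloor$ difference curves — each curve consumes a
laser-on/laser-off pulse pair. The averaged noise at each q-point is the
mean of $I$ independent draws from $\mathcal{N}(0, \sigma_{target}(q))$;
for large $I$ the average is sampled through its exact law
$\mathcal{N}(0, \sigma_{target}(q)/\sqrt{I})$ (the literal draw-average is
used below $2\times10^5$ total draws), which is what makes megahertz-class
scenarios with $I = 1.8\times10^7$ tractable. Every stochastic operation
takes an explicit seed.

## Kinetics and series assembly

Transient populations evolve through a general linear first-order network,
solved with the matrix exponential of the generator (cross-checked in the
tests against independent ODE integration at $10^{-10}$ tolerance); the
generator's columns sum to zero so total population is conserved to
machine precision. Negative delays put all population in the unexcited
ground state, producing noise-only reference curves.

A measurement plan divides the total beam time equally among the $M$
delays (the default allocation), so the per-delay curve count is
$I_{delay} = \lfloor f\, (t_{total} d / M) / 2 \rfloor$ and per-delay noise
grows as $\sqrt{M}$ — the trade-off between the number of delays and data
quality that the planning table makes explicit. The per-delay SNR figure
reported by `plan_report()` is peak $|\Delta S|$ over the median per-point
noise std, a package convention chosen for robustness rather than a
standard of the field.

## Worked demonstration systems

The packaged fixtures mirror two canonical planning scenarios:

- **Iodoform photolysis in cyclohexane** — CHI$_3$ branching 40:60 into
  the iso-CHI$_2$I–I isomer and the CHI$_2$ + I radical pair at early
  delays, with illustrative relaxation constants (870 ns, 50 us). The
  geometries are constructed from standard bond lengths and angles.
- **Azobenzene photoisomerization** — cis/trans azobenzene and its
  4,4'-dibromo analogue built by replacing exactly the two para hydrogens
  with bromine, isolating the heavy-atom-labelling gain in scattering power
  at otherwise identical geometry; compared across a low-repetition XFEL
  (30 Hz, $10^{12}$ photons per pulse) and a high-repetition one (1 MHz,
  $3\times10^{10}$), where the photon-budget ratio alone sets a
  $\sqrt{0.03} \approx 0.173$ noise scaling per curve and the repetition
  rate multiplies the number of curves by $6\times10^5$.

All fixture inputs (XYZ geometries, synthetic noise references with
facility presets, synthetic solvent differentials, demo configs) are
written by `make_fixtures()`, deterministically, so the full pipeline runs
offline.

```{r demo}
fx <- file.path(tempdir(), "fixtures")
invisible(make_fixtures(fx, seed = 1))
cfg <- load_config(file.path(fx, "demo_chi3.yaml"))
system <- build_system(cfg)
curve <- simulate_difference(system, cfg$delay, config_beam(cfg),
                             config_noise_reference(cfg),
                             q = config_q_grid(cfg), seed = 1)
comp <- attr(curve, "components")
round(c(solute = max(abs(comp$solute$intensity)),
        cage = max(abs(comp$cage$intensity)),
        noise_sd = stats::sd(comp$noise$intensity)), 5)
```

```{r plot, fig.width = 6, fig.height = 4}
plot(curve, main = "Iodoform photolysis, 100 ps, 540 curves averaged")
lines(comp$solute$q, comp$solute$q * comp$solute$intensity, col = 2)
legend("topright", c("simulated", "solute-only"), col = c(1, 2), lty = 1)
```

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| q-grid | 1/A | 0.3–8.0, step 0.01 | covers the usual displayed range of difference curves |
| excitation ratio | – | config | fraction of solute promoted by the pump |
| `r_heat` | – | $1 - \sum$ initial populations | excited molecules not in a structural channel heat the solvent |
| duty cycle $d$ | – | 1 | fraction of nominal beam time actually acquiring |
| thermal crossover | s | 10 ns / 3 us | fast approximation of the isochoric-to-isobaric transition |
| noise level (synthetic ref) | e.u. | 0.03 at the synchrotron preset | anchors facility presets consistently via $\sqrt{N}$ |

The synthetic reference noise level of 0.03 e.u. per difference curve was
chosen once as a realistic order of magnitude for a per-solvent-molecule
difference curve; the facility presets derive their levels from it through
the $\sqrt{N}$ law so that cross-facility comparisons depend only on photon
accounting, not on independent level choices.

## Degenerate inputs and numerical corners

- `sinc` is evaluated with a series guard below $qr = 10^{-8}$.
- A single-atom solute has $R_s = 0$: the trapezoid degenerates to a step
  function, handled by zero-length-segment skipping in the transform.
- $q \to 0$ in the cage transform switches to the analytic polynomial
  limit below $q = 10^{-8}$.
- An accumulation too short for one pulse pair ($I = 0$) warns rather than
  fails, and series allocation reports it per delay.
- Curve files are written with `%.17g` so a re-read reproduces the exact
  doubles; identical config and seed give byte-identical outputs.

## What the tests do and do not show

The suite verifies internal correctness: Debye sums against a literal
pair-sum oracle, the cage transform against adaptive quadrature, kinetics
against ODE integration, the noise law against its Monte-Carlo slope, and
end-to-end determinism. Because the solvent differentials and noise
references are synthetic, passing tests demonstrate correct machinery and
scaling laws — not agreement with any measured difference curve. Feeding
measured reference curves in through the documented file formats is what
turns the output into a quantitative prediction for a real beamline.

## Known limitations

- The hard-sphere cage misses real solvation-shell oscillations; treat the
  cage term as an amplitude estimate, best above about 1 A$^{-1}$.
- Only shot noise is modelled; systematic noise enters solely through the
  measured reference, as an overestimate folded into $\sigma_{ref}$.
- The thermal crossover is a fixed two-knot approximation; systems with
  slow vibrational cooling or acoustic ringing are outside it.
- Excited-state electronic structure is ignored: ground-state form factors
  are used for all species.
- Problem sizes in the examples (coarse 0.05 A$^{-1}$ grids in tests,
  4-delay demo series) were chosen to keep the demonstrations quick;
  production grids at 0.01 A$^{-1}$ and thousands of delays run in
  seconds.
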