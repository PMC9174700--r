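---
title: "The oxygen-dose-histogram formalism for FLASH sparing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oxygen-dose-histogram formalism for FLASH sparing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashodh)
```

## The problem

Pulsed irradiation at ultra-high dose rates (tens of Gy per second and
above) spares normal tissue relative to conventional delivery — the FLASH
effect. A leading physical explanation is transient radiolytic oxygen
depletion: part of the dose is deposited after the local oxygen has been
consumed, and hypoxic deposition produces fewer chemically fixed (hence
fewer lethal) DNA lesions. `flashodh` quantifies this without a full
time-resolved mechanistic simulation by abstracting delivery into an
**oxygen dose histogram (ODH)**: the delivered dose binned by the
instantaneous partial oxygen pressure at which it was deposited. The area
under the ODH is the total dose, positional and temporal detail is
deliberately discarded, and — crucially — ODHs are additive across pulses,
which is what makes multi-pulse treatments, partial depletion and partial
re-oxygenation tractable.

## The damage-response model

Oxygen fixation is modelled as a saturable ligand–receptor process
competing with thiol-mediated chemical repair. For a mono-energetic beam
the lesion yield per Gy collapses to the rational form

$$M(p) = \frac{c_1\,p + c_2}{p + c_3},$$

with \(p\) the pO2 in Torr. \(c_2/c_3\) is the fully hypoxic damage floor,
\(c_1\) the well-oxygenated asymptote, and \(c_3\) the half-saturation
scale. The shipped default, `default_response_params()`, is the fitted
2 MeV electron set \((c_1, c_2, c_3) = (8.334,\ 15.99,\ 5.67)\) in lesions
per cell per Gbp per Gy; because the oxygen effect is nearly flat across
therapeutic electron and photon energies, this single-energy set serves
photon and electron beams generally. Energy-resolved work uses
`damage_coefficients()` tables \(a(y), b(y)\) with piecewise-linear
interpolation and no extrapolation (no functional form for the energy
dependence is assumed), and `spectrum_weighted_response()` for
poly-energetic beams.

A note on units: in the saturation form the ratio \(q_1 = K_D/M_T\) is
treated as carrying the concentration scale while the response output is a
dimensionless relative factor; units are pinned down only at the level of
the rational form above, whose coefficients are defined for curve fitting
rather than physical interpretation. All oxygen levels are Torr
(1 Torr ≈ 1 mmHg; 100 % O2 = 760 Torr, so atmospheric 20 % ≈ 152 Torr).

## Depletion models

Two depletion kinetics are provided.

* **Linear** (`linear_depletion()`): \(p(d) = \max(p_0 - R\,d,\ 0)\), with
  the rate \(R\) in Torr/Gy. Conventional-dose-rate measurements put \(R\)
  between about 0.21 and 0.42 Torr/Gy (both quoted bounds, 0.21 and 0.22,
  are accepted as configuration values — neither is hard-coded); cell
  experiments under ultra-high dose rates are best reproduced with far
  steeper effective rates around 15 Torr/Gy. Both are shipped as
  `depletion_rate_presets()` and the rate is always an explicit argument.
  The model is stated in the literature in a self-referential shorthand;
  this package implements the textual description — a constant Torr/Gy
  depletion rate, clamped at zero.
* **Second-order** (`ling_depletion()`): oxygen binds radiation-induced
  species pairwise, \(\dot x = -\lambda x (x + GD - p_0)\), giving a
  closed-form time course with a possible long-time residual
  \(\max(p_0 - GD, 0)\) — depletion can be incomplete. Evaluation is
  branch-stabilised so the exponential always decays, and within a relative
  tolerance of `1e-9` of the singular point \(GD = p_0\) the analytic
  equal-concentration limit \(p_0/(1+\lambda p_0 t)\) is used to avoid 0/0
  cancellation. The time course is mapped to the dose domain assuming a
  constant in-pulse dose rate (rectangular pulses), sampled at 401 points
  by default and checked for monotonicity.

## Histogram construction and algebra

`odh_from_trajectory()` integrates the dose deposited in each pO2 bin
exactly over the piecewise-linear trajectory segments. Bins are
left-closed, right-open with the lowest edge at exactly 0 (fully hypoxic
dose sits in the first bin), default width 0.1 Torr, and the automatic
top edge lies strictly above the starting pO2.

Each bin also stores the exact dose-weighted mean pO2 of the dose it holds.
Downstream damage evaluation uses this representative rather than the bin
midpoint: for dose spread across a bin the two agree to second order, but
for dose concentrated at a single level (no depletion, or the hypoxic
remainder) the weighted mean is exact where the midpoint would bias the
sparing factor slightly above 1. This choice keeps two structural
guarantees at any bin width: a constant-oxygen delivery has sparing factor
exactly 1, and the factor never exceeds 1 for non-increasing trajectories.

`odh_add()` rebins to the union of the edge grids with exact
mass-preserving reassignment (dose uniform within a source bin); bins that
are not split keep their exact moments, split bins fall back to the uniform
assumption. `odh_scale()` multiplies doses (and moments) — the histogram of
\(n\) identical pulses under full re-oxygenation. `compose_train()` builds
multi-pulse histograms: full re-oxygenation scales the single-pulse ODH;
`partial(f)` starts pulse \(i+1\) at \(p_\text{end} + f\,(p_0 -
p_\text{end})\); `none` (`f = 0`) chains the trajectory, which for the
linear model reproduces exactly the ODH of one long pulse.

## Sparing factor and derived quantities

`total_damage()` converts an ODH to lesions per cell per Gbp;
`sparing_factor()` is \(F = M_D / M_{D_0}\), the ratio against the same
dose at the constant initial oxygenation. \(F \le 1\); smaller means more
sparing. For the linear model the exact closed-form integral

$$M_D = \frac{1}{R}\Big[c_1\,(p_0 - p_\text{end}) - (c_1 c_3 - c_2)
\ln\frac{p_0 + c_3}{p_\text{end} + c_3}\Big] +
\big(D - d_\text{hyp}\big)_+ \frac{c_2}{c_3}$$

is implemented alongside the binned path (`linear_damage()`,
`sparing_factor_linear()`) and doubles as the internal oracle: at 0.01-Torr
bins the binned value agrees with adaptive quadrature of the response along
the trajectory to better than 0.1 %, and the closed form agrees with the
quadrature to 1e-9.

Three framings of the same quantity appear in the field; the package
reports the ratio \(F\) as primary, `relative_sparing = 1 - F` in the sweep
tables, and the inverse \(1/F\) in the dose-rate-sweep pipeline where a
behavioural response is expected to increase with sparing.

Measured survival under a spared delivery is corrected by rescaling the
killed fraction, \(SF_\text{corr} = 1 - (1 - SF_\text{meas})\,F\)
(`correct_survival()`).

`crossover_dose()` locates the dose where the sparing curves of two
oxygenation levels change order. At small doses the less oxygenated tissue
is spared more; asymptotically the ordering reverses because
\(F \to M(0)/M(p_0)\). With the default response and either conventional
rate the 2-vs-20-Torr crossover does **not** fall near 10 Gy (it is
~76 Gy at 0.42 Torr/Gy and ~2.1 Gy at 15 Torr/Gy); the parameters behind
the published ~10 Gy figure are unstated, so the crossover is treated as a
scenario-dependent output and deliberately not calibrated to it. Absence of
a crossover is reported as a tagged `NA`, not an error.

## Exact rank statistics

The pre-clinical recreation rests on a small-sample Spearman correlation,
so `spearman_null_distribution()` computes the exact permutation null of
\(\sum d^2\) for \(3 \le n \le 10\) by subset dynamic programming —
mathematically identical to enumerating all \(n!\) permutations, but
\(O(2^n n \cdot d_\text{max})\), about 0.1 s at \(n = 10\). A naive
factorial enumeration is kept in the test suite as the independent oracle
up to \(n = 7\). A two-sided level \(\alpha\) maps to a one-sided
\(\alpha/2\) tail, matching published critical-value tables: at \(n = 10\),
\(\alpha = 0.01\) the smallest attainable \(\rho\) with tail probability
\(\le 0.005\) is \(\rho_c = 0.794\) (at \(\sum d^2 = 34\)); at
\(\alpha = 0.05\), 0.648. Unattainable levels (e.g. \(n = 3\),
\(\alpha = 0.01\), where the best one-sided tail is 1/6) are flagged with
the minimum achievable level rather than silently reported. Ties take
average ranks while the null remains the tie-free distribution — a
documented approximation.

## Experiment pipelines

`town_pipeline()` (cell cultures, 1.2 µs pulses, doses 0.5–45 Gy,
atmospheric 152 Torr, effective rate 15.0 Torr/Gy): single-pulse records
get the single-pulse sparing factor at their dose; double-pulse records
compose two half-dose ODHs with full re-oxygenation (the 2.5 ms gap showed
a minimal two-pulse effect, so full recovery is the documented default;
`partial(f)` exists but is uncalibrated) and correct the measured survival.
By ODH additivity the double-pulse sparing equals the single-pulse factor
at half the dose.

`recognition_pipeline()` (whole-brain dose-rate sweep, 10 Gy at 100 Hz,
20 Torr healthy-tissue oxygenation): dose per pulse is the mean rate
divided by the repetition frequency; under full re-oxygenation the train's
sparing equals the single-pulse factor at that per-pulse dose — the
pulse-count invariance that makes the conversion well-posed (verified to
1e-12 for 1–100 pulses). The single-pulse arm delivers the full 10 Gy in
one 1.8 µs pulse, following the published labelling convention, rather
than as a 1000 Gy/s train. Both quoted effective rates (15.0 and 15.5
Torr/Gy) ship as presets; 15.0 is the default. The published correlation
value itself (ρ = 0.881) depends on behavioural response data not
reproduced here, so the pipeline asserts structure (monotonicity, perfect
concordance under a noiseless link, exact critical value) rather than that
number.

## Voxel engine

`voxel_sparing_map()` applies the formalism per voxel over co-registered
dose and pO2 grids: each voxel's dose is split over the template's pulses
with full re-oxygenation and its sparing and damage computed from its own
oxygenation. The default closed-form path is fully vectorised (a 64³
phantom takes well under a second); the `odh` method routes every distinct
(dose, pO2) pair through the same histogram code as the scalar API and
matches it to 1e-12. Per-voxel energy spectra are reduced to the single
effective energy justified by the flat electron/photon response; a
spectrum hook exists via `spectrum_weighted_response()` but is not wired
into the voxel path by default. Zero-dose voxels report sparing 1 and
damage 0 by convention. I/O covers NIfTI volumes and long-format CSV;
there is deliberately no dose calculation, beam transport or DICOM-RT
machinery here.

## Synthetic data

The generators are pure functions of their configuration including the
seed, and cover both FLASH-present (high dose-per-pulse) and FLASH-absent
regimes:

* `gen_response_table()` — saturation-shaped damage tables with additive
  Gaussian noise, emulating Monte Carlo damage-simulation output.
* `gen_town_survival()` — single-pulse survival from the linear-quadratic
  model on effective dose \(D \cdot F(D)\) (LQ defaults α = 0.3 /Gy,
  β = 0.03 /Gy² — a generic mammalian-cell convention for round-trip
  testability, not a modelling claim), with double-pulse records derived by
  inverting the survival correction so the pipeline provably restores the
  single-pulse curve. The inversion is only defined while
  \(SF_1 \ge 1 - F_2\); with the default radiosensitivity this bounds the
  usable dose range near 9 Gy, so higher doses in the default 0.5–45 Gy
  span are dropped with a message and recorded in an attribute.
* `gen_recognition_sweep()` — the ten-arm dose-rate design with responses
  linked linearly to the computed inverse sparing plus Gaussian noise.
* `gen_phantom()` — two-region (core/shell) dose and oxygen volumes.

What passing tests on these fixtures shows is that the machinery is
self-consistent — conservation, additivity, invariances, round trips and
agreement with independent oracles (adaptive quadrature, Runge–Kutta
integration, brute-force enumeration). It does not validate the biology:
real survival curves are not exactly LQ, real behavioural responses are
not a linear function of inverse sparing, and real oxygen kinetics are
neither exactly linear nor exactly second-order.

## Numerical choices, at a glance

* Default bin width 0.1 Torr; 0.01 Torr for oracle-grade comparisons.
* Bin representative: exact dose-weighted mean pO2 (midpoint fallback).
* Singular-case switch for the second-order solution at relative 1e-9.
* Fit initialisation from the saturation shape (`c1` ← max yield, `c3` ←
  pO2 at half range, `c2` ← `c3` × min yield), all-positive bounds,
  Levenberg–Marquardt refinement; constant-yield tables raise a classed
  fit error (the flat solution leaves `c3` unidentifiable). With 30-point
  tables at 1 % relative noise the sampling error of `c2`/`c3` is ~2 %
  (Fisher bound), so recovery at 5 % is asserted over a fixed ten-seed
  panel (≥ 9/10 within 5 %, all within 12 %) rather than per single seed.
* Crossover search by sign-change bracketing and `uniroot` to 1e-6 Gy.
* Test problem sizes: trajectories of 2–401 breakpoints, histograms up to
  ~15 000 bins, 100-pulse trains, 12³ phantoms, 100-seed noise panels —
  the full suite runs in seconds.

## Known limitations

* No radical-chemistry radiolysis modelling, no spatial oxygen diffusion,
  no biological repair or immune kinetics — by design, the formalism
  isolates the oxygen-fixation pathway.
* The effective depletion rate under ultra-high dose rates is an empirical
  fitting quantity, orders of magnitude above conventional measurements;
  results should be read as conditional on it.
* The exact Spearman machinery stops at n = 10 (its intended use case);
  no asymptotic approximation is provided.
* Ion beams (α, carbon) violate the single-energy simplification; the
  energy-tabulated interface is the extension point, but no LET-dependent
  coefficient tables are bundled.
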