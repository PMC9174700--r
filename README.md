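# flashodh

Quantifying the tissue-sparing (FLASH) effect of pulsed ultra-high dose
rate radiotherapy with **oxygen dose histograms (ODH)**.

At ultra-high dose rates (≳ 40 Gy/s), radiolytic oxygen depletion can
outpace re-oxygenation, so part of the dose is deposited under transient
hypoxia, where fewer DNA lesions are chemically fixed. `flashodh` turns
that idea into a computable pipeline for radiotherapy physicists and
radiobiologists who need a planning-compatible estimate of the effect —
without a mechanistic time-resolved simulation.

The core abstraction is the ODH: the delivered dose binned by the
instantaneous pO2 at which it was deposited. Its area is the total dose
and it is **additive across pulses**. Dose at each oxygen level converts
to complex-lesion yield through the oxygen-fixation response

    M(p) = (c1 p + c2) / (p + c3),   (c1, c2, c3) = (8.334, 15.99, 5.67)

(lesions / cell / Gbp / Gy, p in Torr; the fitted 2 MeV electron set,
valid across therapeutic photon/electron energies). The FLASH sparing
factor is

    F = M_D / M_D0  ≤ 1,

the damage under the ODH relative to the same dose at constant initial
oxygenation; smaller F means more sparing. Oxygen depletion during
delivery is modelled as linear in dose (constant Torr/Gy rate) or as
second-order binding kinetics with a closed-form time course and possible
residual oxygen.

The package provides the damage-response model and its fitting, both
depletion models, ODH construction/algebra over pulse trains, sparing and
survival correction, exact small-sample Spearman rank statistics, the two
bundled experiment-recreation pipelines (single/double-pulse cell survival;
dose-rate sweep vs behavioural response), a voxel engine for 3D dose/pO2
grids (NIfTI or CSV), and seeded synthetic-data generators.

## Worked example

A single 3.4 µs pulse delivering 15 Gy to tissue at 20 Torr, with linear
depletion at the conventional upper-bound rate 0.42 Torr/Gy:

```r
library(flashodh)

model <- linear_depletion(o2_0 = 20, rate = 0.42)
h <- odh_from_trajectory(linear_trajectory(model, total_dose = 15))
sparing_result(h, o2_0 = 20)
#> FLASH sparing: F = 0.9748 (M_D = 104, M_D0 = 106.7 lesions/cell/Gbp; 15 Gy at o2_0 = 20 Torr)
```

Only 2.5 % sparing: at conventional depletion rates and healthy-tissue
oxygenation, 15 Gy barely dents the oxygen pool. With the steep effective
rate (15 Torr/Gy) that reproduces ultra-high dose rate cell experiments,
the same delivery at atmospheric oxygenation (152 Torr) gives
`sparing_factor_linear(152, 15, 15)` = 0.748 — a 25 % damage reduction.

Correcting measured double-pulse cell survival (10 Gy split over two
1.2 µs pulses, full re-oxygenation in the gap):

```r
rec <- data.frame(dose_gy = c(10, 10), sf_meas = c(0.20, 0.15),
                  n_pulses = c(1L, 2L))
town_pipeline(rec)
#>   dose_gy sf_meas n_pulses sparing_factor   sf_corr
#> 1      10    0.20        1      0.9469228 0.2000000
#> 2      10    0.15        2      0.9912912 0.1574025
```

The double-pulse delivery depletes less per pulse (F = 0.991 vs 0.947), so
its killed fraction is rescaled by its own sparing factor.

Exact small-sample rank statistics for a ten-arm dose-rate sweep:

```r
spearman_critical_value(n = 10, alpha = 0.01)
#> Exact Spearman critical value: rho_c = 0.794 (n = 10, two-sided alpha = 0.01, tail p = 0.00439)
```

A thin command-line front end ships in `inst/scripts/flashodh`
(subcommands `odh`, `sparing`, `sweep`, `spearman`, `town`, `recognition`,
`simulate`).

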