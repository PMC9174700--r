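Package: flashodh
Title: Oxygen Dose Histograms for FLASH Sparing in Pulsed Ultra-High Dose
    Rate Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tissue-sparing (FLASH) effects of pulsed ultra-high
    dose rate irradiation through the oxygen dose histogram (ODH) formalism.
    Provides the oxygen-fixation damage-response model mapping partial oxygen
    pressure to complex DNA-lesion yield, linear (Whillans-Rauth) and
    second-order (Ling) radiolytic oxygen depletion trajectories, construction
    and algebra of oxygen dose histograms over pulse trains, sparing-factor
    and survival-correction computation, exact small-sample Spearman rank
    statistics, voxelised application over 3D dose and oxygen grids, and
    seeded synthetic-data generators for cell-survival and dose-rate-sweep
    experiment recreations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
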