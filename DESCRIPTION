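Package: rsmet
Title: Recurrent-Selection Gain and Drought-Tolerance Analysis for Wheat Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for evaluating recurrent-selection programmes in
    cereal field trials run under paired moisture regimes (restricted irrigation
    versus rainfed). Estimates variance components and broad-sense heritability
    from a balanced genotype x treatment x year random model via expected mean
    squares, computes genetic advance and genetic gain from the breeder's
    equation, derives six yield-based drought-tolerance indices (TOL, MPI, GMP,
    MRP, REI, STI) with per-index entry rankings, and compares selected
    populations against base populations and checks with Welch t-tests,
    Dunnett many-to-one tests, trait correlations on adjusted means, and
    progeny BLUPs. Includes a synthetic multi-environment-trial generator with
    specified variance components and a truncation-selection response
    simulator, so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mvtnorm,
    lme4,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
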