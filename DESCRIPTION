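Package: resilipig
Title: Resilience Phenotypes from Daily Feed Intake in Grow-Finish Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives disease-resilience phenotypes from longitudinal daily
    feed-intake and feeder-duration records of grow-finish pigs under a
    natural disease challenge: within-animal root-mean-square deviation of
    intake and feeder duration about their age trends (RMSE_FI, RMSE_DUR)
    and the proportion of off-feed days classified by a population-level
    5 percent quantile regression on age (QR_FI, QR_DUR). Includes record
    cleaning (intake cap, rolling-average imputation), LOESS growth curves
    and phase average daily gain, production traits (ADFI, FCR, residual
    feed intake, carcass traits, lean yield), pedigree, genomic and blended
    relationship matrices, restricted-maximum-likelihood animal models for
    heritability and genetic correlation, and a stochastic disease-challenge
    cohort simulator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
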