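Package: gyrogait
Title: Shank-Gyroscope Step Detection, Step-Length Estimation and Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Open", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Real-time gait-event detection from shank-mounted gyroscopes for
    soccer-style movement monitoring. Implements a causal toe-off / mid-swing /
    initial-contact peak state machine on the sagittal-plane (pitch) angular
    velocity, per-step angular-displacement integration with drift reset, and a
    chord-model step-length estimate d = 2 L sin(theta/2). Ships a labelled
    synthetic-session generator (per-pace waveforms, sync jumps, two-device
    variants) standing in for non-shareable field data, plus the full
    method-comparison suite used to validate such devices: MAE/RMSE/MAPE, Lin's
    concordance correlation coefficient, repeated-measures Bland-Altman limits
    of agreement via mixed models, the total deviation index, the coefficient
    of individual agreement, variance-component models, and inter-unit
    reliability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
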