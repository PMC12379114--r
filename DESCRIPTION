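Package: hnds
Title: Healthy Nordic Diet Score and Depressive Symptom Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores adherence to a healthy Nordic diet from 4-day mean
    dietary intakes (a nine-component, 0-25 point quartile-based index
    adapted from the Baltic Sea Diet Score), scores the 18-item Human
    Population Laboratory (HPL) depression scale, and analyses their
    cross-sectional association with Quade's non-parametric rank ANCOVA
    across score quartiles and covariate-adjusted quantile regression.
    Includes a calibrated synthetic-cohort generator emulating a
    middle-aged male population so the full pipeline is testable without
    access to the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), emmeans, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
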