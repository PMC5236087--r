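Package: cnspk
Title: Multi-Compartmental CNS Distribution Pharmacokinetics and
    Rat-to-Human Translation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Physiologically informed compartmental modelling of drug
    distribution across plasma, brain extracellular/intracellular fluid and
    cerebrospinal fluid compartments. Simulates concentration-time profiles
    for arbitrary infusion regimens, corrects microdialysis data for in-vivo
    probe recovery, fits naive-pooled extended least squares models with
    transporter-inhibition covariates, computes simulation-based 95%
    prediction intervals and SMAPE validation metrics, and translates a rat
    model to humans by system-parameter replacement and allometric scaling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
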