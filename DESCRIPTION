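Package: fibrostage
Title: Stepwise Non-Invasive Staging of Liver Fibrosis and Cirrhosis in NAFLD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the stepwise non-invasive diagnosis of advanced liver
    fibrosis and cirrhosis in non-alcoholic fatty liver disease (NAFLD).
    Implements the four-group classifications built from the elastography-based
    Agile3+/Agile4 scores and from the specialized blood tests FibroMeterV3G and
    CirrhoMeterV3G, the sequential study algorithm that combines them into four
    diagnoses (F0-2, Biopsy, F34, F4), joint risk-prediction charts for cirrhosis
    and advanced fibrosis on composite elastography/blood axes, and the
    evaluation statistics used to validate such algorithms (midrank AUROC with
    DeLong confidence intervals and paired comparison, operating
    characteristics, calibration tables, accuracy reports). A seeded synthetic
    cohort generator, deterministically calibrated by binormal inversion to
    published stage prevalences, score quartiles and AUROCs, lets the whole
    pipeline run at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
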