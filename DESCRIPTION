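Package: femi
Title: Subnational Women's Empowerment Scores from Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds subnational (admin-1) women's empowerment estimates from
    DHS-style survey microdata. Codes respondent answers into six empowerment
    domain scores (intimate partner violence attitudes, family planning,
    reproductive healthcare, employment, education, decision-making), adjusts
    Education and Employment for gender inequality, imputes missing
    region-level domain scores with random forests, harmonizes scores reported
    on historical region schemes onto current admin-1 boundaries, extrapolates
    to reference years by direct reassignment, linear trends or random-forest
    prediction, and combines the domains into the Female Empowerment Index
    (FEMI) with population-weighted summary statistics. Includes a synthetic
    survey generator with known latent scores so the whole pipeline is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
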