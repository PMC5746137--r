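Package: he4ren
Title: Renal Adjustment of Serum HE4 and Prediction of Deep Myometrial
    Invasion in Endometrial Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adjusts serum HE4 (human epididymis protein 4) concentrations
    for reduced glomerular filtration via a piecewise log-linear model of
    ln(HE4) against CKD-EPI eGFR with a fixed knot at 90 ml/min/1.73 m2
    (the HE4ren transform), and uses the adjusted biomarker together with
    age, histological grade and CA125 in logistic-regression models that
    predict deep myometrial invasion (>= 50% of the uterine wall) in
    endometrial cancer. Includes backward-elimination model development,
    a coefficient-times-ten points system with a simplified weighted
    low/high-risk classifier, ROC/AUC evaluation with cut-off
    optimisation, seeded synthetic cohort generators for end-to-end
    testing, and cohort CSV input/output with schema validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
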