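Package: dilipattern
Title: Dynamic ALT/TB Evolution Patterns and Acute Liver Failure Prediction in Drug-Induced Liver Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies longitudinal alanine aminotransferase (ALT) and total
    bilirubin (TB) trajectories of drug-induced liver injury (DILI) patients
    into four dynamic evolution patterns (ALT-mono-peak, TB-mono-peak,
    double-overlap-peak, double-separate-peak), evaluates the
    double-separate-peak (DSP) pattern and classical single-time-point
    prognostic rules (Hy's law, new Hy's law, Robles-Diaz) as predictors of
    acute liver failure, and fits an optimized logistic model combining DSP
    membership with INR and ALP at onset.  Includes self-contained logistic
    regression with forward likelihood-ratio selection, ROC/AUROC analysis
    with DeLong confidence intervals and paired comparisons, Brier scores,
    bootstrap internal validation, and a synthetic-cohort simulator so the
    full analysis is reproducible without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
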