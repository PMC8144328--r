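Package: mrlung
Title: Mendelian Randomization of BMI Effects on Lung Function with
    Instrumented Age Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage least squares Mendelian randomization of body mass
    index (BMI) effects on spirometric lung function in a longitudinal
    cohort, in which both the exposure (log BMI) and its interaction with
    age are instrumented by a weighted BMI allele score and its product
    with age. Provides weighted allele-score construction with an
    SNP-exclusion cascade (imputation quality, phenotype exclusion lists,
    greedy LD pruning), predictive and long-term cross-sectional analysis
    frames built from repeated surveys, an estimation core (OLS, 2SLS with
    multiple instrumented terms, first-stage F diagnostics, delta-method
    derived effects, AIC comparison), instrument-assumption checks
    including one-sample MR-Egger regression, an instrumented/residual
    BMI decomposition, inverse-probability weighting for attrition,
    age-tertile stratification, sensitivity analyses, and a synthetic
    cohort generator with known causal ground truth for calibration and
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
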