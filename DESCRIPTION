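Package: trialmr
Title: Treatment-Response Biomarker Signatures and Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds treatment-response biomarker signatures from small
    randomized trials by penalized logistic regression with leave-one-out
    cross-validation, permutation inference and fold-stability summaries;
    selects genetic instruments for a signature via a quality-controlled
    association scan with linkage-disequilibrium clumping and cis-region
    filtering; estimates the causal effect of the signature on binary
    disease outcomes with one-sample and two-sample Mendelian
    randomization (inverse-variance weighting, weighted median, weighted
    mode, MR-Egger, MR-PRESSO, bi-directional analyses); and screens
    candidate mediating biomarkers by direction-consistency rules. A
    synthetic-data module generates randomized trials, genotype cohorts
    in Hardy-Weinberg equilibrium with block linkage disequilibrium, and
    paired non-overlapping summary statistics with known ground truth, so
    the whole inference chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
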