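Package: sarcoscore
Title: Candidate-Gene Association Testing and Genetic Risk Scores for
    Sarcopenia Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for small case-control genetic-association studies of
    sarcopenia in older adults: EWGSOP phenotype classification from
    bioimpedance-derived skeletal muscle mass, Hardy-Weinberg equilibrium
    quality control, genotype/allele/dominant/recessive association
    statistics with Woolf confidence intervals, covariate-adjusted binary
    logistic regression with Nagelkerke pseudo-R2, an unweighted additive
    genetic risk score with ROC/AUC and Youden-index cutoff selection, a
    genetic power calculator parameterized by genotype relative risks, and
    a synthetic-cohort simulator so every analysis stage is testable
    without individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
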