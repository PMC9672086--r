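Package: bedmot
Title: Motivation and Sentiment Analysis for Online Binge-Eating-Disorder Treatment Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative arm of a mixed-methods analysis of
    patient motivation in guided internet-based treatment for binge eating
    disorder. Provides hybrid lexicon- and rule-based sentiment polarity
    scoring of free-text motivation statements (negation, modifier and
    exclamation rules; sum, mean and partitioned signed geometric-mean
    pooling), scoring of the study instruments (BED-Q, MDI, VAS, completion
    rate), an ordered-alternatives inference chain (signed Jonckheere-Terpstra
    trend test with tie-corrected variance and permutation option,
    Brown-Forsythe homoscedasticity test, tie-aware Kendall tau-b with
    bootstrap confidence intervals, and a dual minimal-practical-effect-size
    significance rule), mixed pre/post ANOVA, a seeded synthetic cohort
    generator emulating the study's statistical structure, and an end-to-end
    pipeline producing the study's table shapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
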