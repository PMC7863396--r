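Package: dietmetab
Title: Diet-Group Metabolomics and Micronutrient Status Analysis for Pediatric Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible analysis pipeline for small diet-group cohort
    studies (omnivore, vegetarian, vegan children): covariate-adjusted
    permutation tests with the probabilistic index as test statistic,
    Benjamini-Hochberg multiple-testing correction, Welch tests and
    Behrens-Fisher confidence intervals, GSEA-style metabolite-set
    enrichment of untargeted flow-injection TOF-MS profiles, accurate-mass
    putative annotation with isotopologue-correlation support, log2 fold
    changes against the omnivore mean, Ward hierarchical clustering of
    participants, LMS growth-reference z-scores, and rule-based
    micronutrient status classification. Ships a synthetic-cohort
    generator so every stage is testable without participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
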