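Package: ivfqol
Title: Binocular Integrated Visual Field Subfields and Vision-Related
    Quality of Life in Advanced Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking damage in subfields of the central
    binocular integrated visual field (IVF) to vision-related quality of
    life (VRQoL) in advanced glaucoma.  Builds Humphrey 10-2 and 24-2
    test-point grids, integrates per-eye total-deviation fields into a
    binocular IVF under the best-location model (per-point maximum),
    summarises damage as subfield mean total deviations, scores a 30-item
    three-category VRQoL questionnaire with a rating-scale Rasch model
    (item easiness parameters and raw-score-to-ability person indices),
    and identifies the subfields driving each daily-task ability with a
    regression random forest and permutation variable importance tested
    against an empirical permutation null.  Includes eligibility
    filtering, a Spearman/Bonferroni correlation screen, ANOVA with
    Scheffe contrasts, paired hemifield tests, and a seeded synthetic
    cohort generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
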