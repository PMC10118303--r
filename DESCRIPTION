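Package: phenostrat
Title: Behavioral Stratification of Automated Home-Cage Discrimination and
    Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for automated home-cage (hole-poke)
    discrimination and reversal-learning sessions in mice. Implements the
    moving-window success criterion with entries- and hours-to-criterion,
    cumulative and hourly learning indices, initial learning rate and
    cognitive-flexibility measures, extinction curves, young-reference
    confidence-interval cutoffs for stratifying aged cohorts into
    cognitively intact and impaired subgroups, criterion-attainment
    survival tables with log-rank and Gehan-Wilcoxon comparisons, and a
    behavior-augmented principal-component embedding. A synthetic cohort
    simulator emulates group-dependent learning, perseveration, and
    circadian entry dynamics so every stage of the pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
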