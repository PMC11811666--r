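Package: phenosleep
Title: Digital Phenotyping of Insomnia Severity from Wearable and
    Self-Report Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive objective sleep, activity, and circadian
    features from wearable-style data streams (epoch heart rate,
    cumulative steps, nightly sleep-stage records), score nine
    self-report instruments with their published severity cutoffs,
    apply time-of-day weighting to ecological momentary assessment
    (EMA) logs, and run a four-group insomnia-severity comparison
    workflow (normality-gated Kruskal-Wallis with Bonferroni-corrected
    pairwise Wilcoxon rank-sum tests, ANOVA with Tukey HSD, chi-square
    for categoricals). Includes a synthetic-cohort generator that
    reproduces the statistical structure of a 4-week digital
    phenotyping study: group-invariant objective sleep, severity-graded
    psychological scales, and a circadian heart-rate rhythm, so the
    full subjective-objective discrepancy analysis can be exercised
    end to end without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
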