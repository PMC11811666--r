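#!/usr/bin/env Rscript

# Step 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 250 participants split
# 63/106/69/12 across the four ISI severity bands, 28 days of 5-minute
# heart rate and cumulative steps, nightly sleep-stage records drawn from
# one group-invariant distribution, item-level responses for all nine
# questionnaires, and a daily EMA log. Streams are written as plain CSVs
# under scratch/cohort/ (large) with the generator truth sidecar; small
# summaries go to results/.

suppressPackageStartupMessages(library(phenosleep))
suppressPackageStartupMessages(library(dplyr))

cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = 1)
cat("Generating cohort:", cfg$n_participants, "participants,",
    cfg$study_days, "days...\n")
cohort <- generate_cohort(cfg)
write_cohort(cohort, cohort_dir)

counts <- table(cohort$truth$group)[c("no_insomnia", "mild", "moderate",
                                      "severe")]
cat("Group sizes:", paste(names(counts), counts, sep = "=",
                          collapse = ", "), "\n")
cat("Heart-rate epochs per participant:",
    length(cohort$heart_rate[[1]]$values), "\n")
cat("EMA entries:", nrow(cohort$ema), "| sleep nights:",
    nrow(cohort$sleep), "\n")

readr::write_csv(
  tibble::tibble(group = names(counts), n = as.integer(counts),
                 pct = round(100 * as.integer(counts) / sum(counts), 1)),
  "results/01_group_sizes.csv"
)
cat("Cohort written to", cohort_dir, "\n")
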