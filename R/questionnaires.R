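#' Self-report instrument registry
#'
#' Item counts, per-item rating ranges, and total-score ranges for the nine
#' instruments used in the study workflow. BRIAN carries 21 items but only the
#' 18 circadian-category items are scored; the 3 chronotype items are
#' descriptive and excluded from the total (hence the 18-72 range).
#'
#' @return A tibble with one row per instrument: `instrument`, `n_items`,
#'   `n_scored` (items entering the total), `item_min`, `item_max`,
#'   `total_min`, `total_max`.
#' @export
instrument_info <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- tibble::tribble(
        ~instrument, ~n_items, ~n_scored, ~item_min, ~item_max,
        "ISI",        7L,  7L, 0L,  4L,
        "IRLS",      10L, 10L, 0L,  4L,
        "DBAS",      16L, 16L, 0L, 10L,
        "STAI_S",    20L, 20L, 1L,  4L,
        "PHQ9",       9L,  9L, 0L,  3L,
        "GAD7",       7L,  7L, 0L,  3L,
        "AUDIT_C",    3L,  3L, 0L,  4L,
        "SOS_Q",     28L, 28L, 1L,  4L,
        "BRIAN",     21L, 18L, 1L,  4L
      ) |>
        dplyr::mutate(
          total_min = .data$n_scored * .data$item_min,
          total_max = .data$n_scored * .data$item_max
        )
    }
    cache
  }
})

instrument_row <- function(instrument) {
  info <- instrument_info()
  row <- info[info$instrument == instrument, ]
  if (nrow(row) != 1L) {
    stop("unknown instrument: ", instrument, call. = FALSE)
  }
  row
}

#' Score a self-report instrument
#'
#' All nine instruments are scored as plain sums of their item ratings; no
#' reverse-scored items are applied. For BRIAN only the first 18 (category)
#' items enter the total.
#'
#' @param instrument Instrument code, one of
#'   `r paste(instrument_info()$instrument, collapse = ", ")`.
#' @param items Integer vector of item ratings, in instrument order.
#' @return The integer total score.
#' @examples
#' score_scale("ISI", rep(4, 7))      # 28
#' score_scale("BRIAN", rep(1, 21))   # 18
#' @export
score_scale <- function(instrument, items) {
  row <- instrument_row(instrument)
  if (length(items) != row$n_items) {
    stop(sprintf(
      "%s expects %d items, got %d", instrument, row$n_items, length(items)
    ), call. = FALSE)
  }
  if (anyNA(items)) {
    stop(instrument, ": missing rating at item ",
         which(is.na(items))[1], call. = FALSE)
  }
  bad <- which(items < row$item_min | items > row$item_max |
                 items != round(items))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: rating out of range [%d, %d] at item %d (value %s)",
      instrument, row$item_min, row$item_max, bad[1], items[bad[1]]
    ), call. = FALSE)
  }
  as.integer(sum(items[seq_len(row$n_scored)]))
}

check_total <- function(total, lo, hi, what) {
  if (anyNA(total) || any(total < lo | total > hi)) {
    stop(sprintf("%s total must lie in [%d, %d]", what, lo, hi),
         call. = FALSE)
  }
  invisible(total)
}

#' Insomnia severity bands from the ISI total
#'
#' Bands: 0-7 no clinically significant insomnia, 8-14 mild, 15-21 moderate,
#' 22-28 severe.
#'
#' @param total ISI total score(s) in 0-28.
#' @return Factor with levels `no_insomnia`, `mild`, `moderate`, `severe`.
#' @export
classify_isi <- function(total) {
  check_total(total, 0, 28, "ISI")
  cut(total, breaks = c(-1, 7, 14, 21, 28),
      labels = c("no_insomnia", "mild", "moderate", "severe"))
}

#' Restless legs syndrome severity bands from the IRLS total
#'
#' Bands: 0-10 mild, 11-20 moderate, 21-30 severe, 31-40 most severe.
#'
#' @param total IRLS total score(s) in 0-40.
#' @return Factor with levels `mild`, `moderate`, `severe`, `most_severe`.
#' @export
classify_irls <- function(total) {
  check_total(total, 0, 40, "IRLS")
  cut(total, breaks = c(-1, 10, 20, 30, 40),
      labels = c("mild", "moderate", "severe", "most_severe"))
}

#' Depression severity bands from the PHQ-9 total
#'
#' Bands: 0-4 normal, 5-9 mild, 10-19 moderate, 20-27 severe.
#'
#' @param total PHQ-9 total score(s) in 0-27.
#' @return Factor with levels `normal`, `mild`, `moderate`, `severe`.
#' @export
classify_phq9 <- function(total) {
  check_total(total, 0, 27, "PHQ-9")
  cut(total, breaks = c(-1, 4, 9, 19, 27),
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Anxiety severity bands from the GAD-7 total
#'
#' Bands: 0-4 normal, 5-9 mild, 10-14 moderate, 15-21 severe.
#'
#' @param total GAD-7 total score(s) in 0-21.
#' @return Factor with levels `normal`, `mild`, `moderate`, `severe`.
#' @export
classify_gad7 <- function(total) {
  check_total(total, 0, 21, "GAD-7")
  cut(total, breaks = c(-1, 4, 9, 14, 21),
      labels = c("normal", "mild", "moderate", "severe"))
}

#' Hazardous-drinking flag from the AUDIT-C total
#'
#' Sex-specific cutoffs: hazardous at a total of 4 or more for men, 3 or more
#' for women.
#'
#' @param total AUDIT-C total score(s) in 0-12.
#' @param sex `"male"` or `"female"`, recycled against `total`.
#' @return Factor with levels `nonhazardous`, `hazardous`.
#' @export
classify_auditc <- function(total, sex) {
  check_total(total, 0, 12, "AUDIT-C")
  if (anyNA(sex) || !all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  cutoff <- ifelse(sex == "male", 4, 3)
  factor(ifelse(total >= cutoff, "hazardous", "nonhazardous"),
         levels = c("nonhazardous", "hazardous"))
}

#' Smartphone-overuse risk from the SOS-Q total
#'
#' Scores strictly greater than 49 indicate high risk; 49 itself is assigned
#' to low risk (the cutoff sentence is strict).
#'
#' @param total SOS-Q total score(s) in 28-112.
#' @return Factor with levels `low_risk`, `high_risk`.
#' @export
classify_sosq <- function(total) {
  check_total(total, 28, 112, "SOS-Q")
  factor(ifelse(total > 49, "high_risk", "low_risk"),
         levels = c("low_risk", "high_risk"))
}

#' Screening eligibility from the first ISI administration
#'
#' The screening rule is distinct from the four-band analysis grouping:
#' the insomnia arm requires an ISI total strictly greater than 15 plus
#' insomnia symptoms on at least 3 days per week; the no-insomnia arm an ISI
#' total strictly below 8 plus symptoms on fewer than 3 days per week.
#' Totals of 8-15, mismatched symptom frequency, or an exclusion flag render
#' a candidate ineligible.
#'
#' @param isi_total Screening ISI total(s) in 0-28.
#' @param weekly_symptom_days Self-reported insomnia-symptom days per week
#'   (0-7), recycled.
#' @param excluded Logical exclusion flag(s) (psychiatric/sleep-disorder
#'   exclusion criteria), recycled. Default `FALSE`.
#' @return Factor with levels `insomnia_arm`, `no_insomnia_arm`, `ineligible`.
#' @export
screen_eligibility <- function(isi_total, weekly_symptom_days,
                               excluded = FALSE) {
  check_total(isi_total, 0, 28, "ISI")
  n <- max(length(isi_total), length(weekly_symptom_days), length(excluded))
  isi_total <- rep_len(isi_total, n)
  weekly_symptom_days <- rep_len(weekly_symptom_days, n)
  excluded <- rep_len(excluded, n)
  out <- rep("ineligible", n)
  out[!excluded & isi_total > 15 & weekly_symptom_days >= 3] <- "insomnia_arm"
  out[!excluded & isi_total < 8 & weekly_symptom_days < 3] <- "no_insomnia_arm"
  factor(out, levels = c("insomnia_arm", "no_insomnia_arm", "ineligible"))
}

#' Score and categorize all questionnaires of a cohort
#'
#' Takes item-level responses (one row per participant x instrument x item)
#' and returns one row per participant x instrument with the total score and,
#' where the instrument defines one, its severity/risk category.
#'
#' @param responses Tibble with columns `participant_id`, `instrument`,
#'   `item_index`, `rating`, `sex`.
#' @return Tibble with columns `participant_id`, `instrument`, `total`,
#'   `category` (NA for instruments without a categorization).
#' @export
score_cohort_questionnaires <- function(responses) {
  required <- c("participant_id", "instrument", "item_index", "rating", "sex")
  missing <- setdiff(required, names(responses))
  if (length(missing) > 0) {
    stop("responses is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  info <- instrument_info()
  df <- dplyr::inner_join(responses, info, by = "instrument")
  if (nrow(df) < nrow(responses)) {
    stop("unknown instrument: ",
         paste(setdiff(unique(responses$instrument), info$instrument),
               collapse = ", "), call. = FALSE)
  }
  bad <- which(is.na(df$rating) | df$rating < df$item_min |
                 df$rating > df$item_max | df$rating != round(df$rating))
  if (length(bad) > 0) {
    b <- df[bad[1], ]
    stop(sprintf(
      "%s (%s): rating out of range [%d, %d] at item %d",
      b$instrument, b$participant_id, b$item_min, b$item_max, b$item_index
    ), call. = FALSE)
  }
  counts <- df |>
    dplyr::count(.data$participant_id, .data$instrument, .data$n_items)
  off <- counts[counts$n != counts$n_items, ]
  if (nrow(off) > 0) {
    stop(sprintf("%s (%s): expected %d items, got %d", off$instrument[1],
                 off$participant_id[1], off$n_items[1], off$n[1]),
         call. = FALSE)
  }
  scored <- df |>
    dplyr::filter(.data$item_index <= .data$n_scored) |>
    dplyr::group_by(.data$participant_id, .data$instrument) |>
    dplyr::summarise(
      total = as.integer(sum(.data$rating)),
      sex = .data$sex[1],
      .groups = "drop"
    )
  scored$category <- NA_character_
  idx <- scored$instrument == "ISI"
  scored$category[idx] <- as.character(classify_isi(scored$total[idx]))
  idx <- scored$instrument == "IRLS"
  scored$category[idx] <- as.character(classify_irls(scored$total[idx]))
  idx <- scored$instrument == "PHQ9"
  scored$category[idx] <- as.character(classify_phq9(scored$total[idx]))
  idx <- scored$instrument == "GAD7"
  scored$category[idx] <- as.character(classify_gad7(scored$total[idx]))
  idx <- scored$instrument == "AUDIT_C"
  scored$category[idx] <- as.character(
    classify_auditc(scored$total[idx], scored$sex[idx])
  )
  idx <- scored$instrument == "SOS_Q"
  scored$category[idx] <- as.character(classify_sosq(scored$total[idx]))
  scored[, c("participant_id", "instrument", "total", "category")]
}
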