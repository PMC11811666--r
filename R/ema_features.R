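#' Time-of-day weight table for EMA variables
#'
#' Daily EMA events are weighted by when they occurred. Caffeine, naps, and
#' stress carry weights 1 / 1.5 / 2 for morning / afternoon / before bedtime.
#' Alcohol carries 1.5 / 1 / 2: morning drinking is weighted above afternoon
#' drinking, and drinking before bedtime highest.
#'
#' @return Tibble with columns `kind`, `slot`, `weight`.
#' @export
ema_weights <- function() {
  tibble::tibble(
    kind = rep(c("caffeine", "alcohol", "nap", "stress"), each = 3),
    slot = rep(c("morning", "afternoon", "before_bedtime"), times = 4),
    weight = c(
      1, 1.5, 2,   # caffeine
      1.5, 1, 2,   # alcohol
      1, 1.5, 2,   # nap
      1, 1.5, 2    # stress
    )
  )
}

ema_kinds <- c("caffeine", "alcohol", "nap", "stress")
ema_slots <- c("morning", "afternoon", "before_bedtime")
nap_categories <- c("<1h", "1-2h", "2-3h", ">3h")
stress_levels <- c("mild", "moderate", "severe")

#' Encode a nap-duration category as a number
#'
#' Categories are half-open hour intervals: under an hour scores 0.5, 1-2 h
#' scores 1, 2-3 h scores 2, over 3 h scores 3.
#'
#' @param category Character vector of categories among
#'   `"<1h"`, `"1-2h"`, `"2-3h"`, `">3h"`.
#' @return Numeric encoding.
#' @export
encode_nap <- function(category) {
  idx <- match(category, nap_categories)
  if (anyNA(idx)) {
    stop("unknown nap category: ",
         paste(unique(category[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  c(0.5, 1, 2, 3)[idx]
}

#' Encode a stress intensity as a number
#'
#' mild = 1, moderate = 2, severe = 3.
#'
#' @param intensity Character vector among `"mild"`, `"moderate"`, `"severe"`.
#' @return Numeric encoding.
#' @export
encode_stress <- function(intensity) {
  idx <- match(intensity, stress_levels)
  if (anyNA(idx)) {
    stop("unknown stress intensity: ",
         paste(unique(intensity[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  c(1, 2, 3)[idx]
}

#' Time-of-day-weighted value of one EMA entry
#'
#' For caffeine and alcohol the reported intake amount is multiplied by the
#' slot weight; for naps and stress the categorical report is first encoded
#' (see [encode_nap()], [encode_stress()]) and then weighted.
#'
#' @param kind Entry kind(s): `"caffeine"`, `"alcohol"`, `"nap"`, `"stress"`.
#' @param slot Time-of-day slot(s): `"morning"`, `"afternoon"`,
#'   `"before_bedtime"`.
#' @param magnitude Nonnegative intake amount for caffeine/alcohol; ignored
#'   for nap/stress.
#' @param category Nap-duration or stress-intensity category for nap/stress;
#'   ignored for caffeine/alcohol.
#' @param weights Weight table, by default [ema_weights()].
#' @return Numeric weighted value(s).
#' @examples
#' weighted_ema_value("caffeine", "afternoon", magnitude = 2)       # 3
#' weighted_ema_value("stress", "before_bedtime", category = "severe") # 6
#' @export
weighted_ema_value <- function(kind, slot, magnitude = NULL, category = NULL,
                               weights = ema_weights()) {
  n <- max(length(kind), length(slot),
           length(magnitude), length(category))
  kind <- rep_len(kind, n)
  slot <- rep_len(slot, n)
  if (!all(kind %in% ema_kinds)) {
    stop("unknown EMA kind", call. = FALSE)
  }
  if (!all(slot %in% ema_slots)) {
    stop("unknown EMA slot", call. = FALSE)
  }
  w <- weights$weight[match(paste(kind, slot),
                            paste(weights$kind, weights$slot))]
  base <- numeric(n)
  quant <- kind %in% c("caffeine", "alcohol")
  if (any(quant)) {
    if (is.null(magnitude)) {
      stop("magnitude required for caffeine/alcohol entries", call. = FALSE)
    }
    magnitude <- rep_len(magnitude, n)
    if (anyNA(magnitude[quant]) || any(magnitude[quant] < 0)) {
      stop("magnitude must be nonnegative", call. = FALSE)
    }
    base[quant] <- magnitude[quant]
  }
  if (any(kind == "nap")) {
    category <- rep_len(category, n)
    base[kind == "nap"] <- encode_nap(category[kind == "nap"])
  }
  if (any(kind == "stress")) {
    category <- rep_len(category, n)
    base[kind == "stress"] <- encode_stress(category[kind == "stress"])
  }
  base * w
}

#' Aggregate one participant's EMA log into per-kind variables
#'
#' Each entry is weighted by time of day, entries are summed within days, and
#' days are combined over the study period. Days with no entry contribute 0.
#' The participant-level statistic is the sum over the period by default
#' (a period aggregate matches the scale of the reported cohort medians);
#' `statistic = "mean_per_day"` divides by `study_days`.
#'
#' @param entries Tibble with columns `participant_id`, `date`, `kind`,
#'   `slot`, and `magnitude` (caffeine/alcohol) and/or `category`
#'   (nap/stress). May be empty.
#' @param study_days Number of study days (denominator for
#'   `"mean_per_day"`).
#' @param statistic `"sum"` (default) or `"mean_per_day"`.
#' @param weights Weight table, by default [ema_weights()].
#' @return Named numeric vector with elements `caffeine`, `alcohol`, `nap`,
#'   `stress`.
#' @export
aggregate_ema_participant <- function(entries, study_days,
                                      statistic = c("sum", "mean_per_day"),
                                      weights = ema_weights()) {
  statistic <- match.arg(statistic)
  out <- stats::setNames(numeric(4), ema_kinds)
  if (nrow(entries) > 0) {
    if (length(unique(entries$participant_id)) > 1) {
      stop("entries span multiple participants", call. = FALSE)
    }
    if (!"magnitude" %in% names(entries)) entries$magnitude <- NA_real_
    if (!"category" %in% names(entries)) entries$category <- NA_character_
    wv <- weighted_ema_value(entries$kind, entries$slot,
                             magnitude = entries$magnitude,
                             category = entries$category,
                             weights = weights)
    sums <- tapply(wv, factor(entries$kind, levels = ema_kinds), sum)
    sums[is.na(sums)] <- 0
    out[] <- sums
  }
  if (statistic == "mean_per_day") {
    if (study_days <= 0) stop("study_days must be positive", call. = FALSE)
    out <- out / study_days
  }
  out
}

#' EMA feature table for a cohort
#'
#' Applies [aggregate_ema_participant()] to every participant in an EMA log.
#'
#' @param ema Tibble of EMA entries for any number of participants.
#' @param participant_ids Participants to report (so participants with an
#'   empty log still get a zero row). Defaults to the ids present in `ema`.
#' @inheritParams aggregate_ema_participant
#' @return Tibble with columns `participant_id`, `caffeine`, `alcohol`,
#'   `nap`, `stress`.
#' @export
ema_features <- function(ema, study_days,
                         participant_ids = unique(ema$participant_id),
                         statistic = c("sum", "mean_per_day"),
                         weights = ema_weights()) {
  statistic <- match.arg(statistic)
  base <- tidyr::expand_grid(participant_id = participant_ids,
                             kind = ema_kinds)
  if (nrow(ema) > 0) {
    if (!"magnitude" %in% names(ema)) ema$magnitude <- NA_real_
    if (!"category" %in% names(ema)) ema$category <- NA_character_
    wv <- weighted_ema_value(ema$kind, ema$slot,
                             magnitude = ema$magnitude,
                             category = ema$category, weights = weights)
    sums <- tibble::tibble(participant_id = ema$participant_id,
                           kind = ema$kind, wv = wv) |>
      dplyr::group_by(.data$participant_id, .data$kind) |>
      dplyr::summarise(value = sum(.data$wv), .groups = "drop")
    base <- dplyr::left_join(base, sums,
                             by = c("participant_id", "kind"))
  } else {
    base$value <- 0
  }
  base$value[is.na(base$value)] <- 0
  if (statistic == "mean_per_day") {
    if (study_days <= 0) stop("study_days must be positive", call. = FALSE)
    base$value <- base$value / study_days
  }
  tidyr::pivot_wider(base, names_from = "kind", values_from = "value")
}
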