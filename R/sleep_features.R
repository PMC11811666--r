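#' Total sleep time of a night
#'
#' Total sleep time (TST) is the night's total inactive time minus its total
#' awake time, in minutes.
#'
#' @param total_inactive_min Total inactive minutes (time in bed as estimated
#'   by the device).
#' @param total_awake_min Total awake minutes within the inactive period.
#' @return TST in minutes (vectorized).
#' @export
total_sleep_time <- function(total_inactive_min, total_awake_min) {
  if (any(total_inactive_min < 0) || any(total_awake_min < 0)) {
    stop("durations must be nonnegative", call. = FALSE)
  }
  if (any(total_awake_min > total_inactive_min)) {
    stop("total_awake_min exceeds total_inactive_min", call. = FALSE)
  }
  total_inactive_min - total_awake_min
}

#' Sleep quality as a percentage
#'
#' Computed from total sleep time and total awake time as
#' `100 * tst / (tst + awake)` — the slept share of the inactive period.
#' This is the only formula consistent with being "calculated from TST and
#' total awake time", being a percentage, and landing on the 80-85% scale of
#' typical wearable data; it equals sleep efficiency over the inactive
#' period.
#'
#' @param tst Total sleep time, minutes.
#' @param awake Total awake time, minutes.
#' @return Sleep quality in percent, within \[0, 100\] (vectorized).
#' @export
sleep_quality <- function(tst, awake) {
  if (any(tst < 0) || any(awake < 0)) {
    stop("durations must be nonnegative", call. = FALSE)
  }
  if (any(tst + awake == 0)) {
    stop("sleep quality undefined when tst + awake = 0", call. = FALSE)
  }
  100 * tst / (tst + awake)
}

#' Wake-ups per week
#'
#' Scales the total number of nightly wake-ups to a weekly rate:
#' `sum(n_wakeups) * 7 / n_nights`.
#'
#' @param n_wakeups Integer vector, one count per recorded night.
#' @return Wake-ups per week.
#' @export
wakeups_per_week <- function(n_wakeups) {
  if (length(n_wakeups) == 0) {
    stop("at least one night required", call. = FALSE)
  }
  sum(n_wakeups) * 7 / length(n_wakeups)
}

validate_sleep_nights <- function(nights) {
  required <- c("participant_id", "date", "total_inactive_min",
                "total_awake_min", "rem_min", "light_min", "deep_min",
                "n_wakeups")
  missing <- setdiff(required, names(nights))
  if (length(missing) > 0) {
    stop("sleep records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dur <- c("total_inactive_min", "total_awake_min", "rem_min", "light_min",
           "deep_min")
  if (any(as.matrix(nights[dur]) < 0) || any(nights$n_wakeups < 0)) {
    stop("sleep durations and wake-up counts must be nonnegative",
         call. = FALSE)
  }
  if (any(nights$total_awake_min > nights$total_inactive_min)) {
    stop("total_awake_min exceeds total_inactive_min", call. = FALSE)
  }
  tst <- nights$total_inactive_min - nights$total_awake_min
  if (any(nights$rem_min + nights$light_min + nights$deep_min > tst + 1e-9)) {
    stop("staged sleep exceeds total sleep time", call. = FALSE)
  }
  invisible(nights)
}

#' Participant-level sleep summary over the study period
#'
#' Per-night parameters are averaged arithmetically over recorded nights
#' (nights with zero inactive time are dropped as device non-wear and the
#' divisor is the number of remaining nights). Sleep quality is computed from
#' the mean TST and mean awake time by default (`quality = "aggregate"`);
#' `quality = "nightly_mean"` instead averages the nightly percentages.
#'
#' @param nights Tibble of nightly records with columns `participant_id`,
#'   `date`, `total_inactive_min`, `total_awake_min`, `rem_min`, `light_min`,
#'   `deep_min`, `n_wakeups`.
#' @param quality How the sleep-quality percentage is formed; see above.
#' @return One-row tibble per participant: mean `tst_min`, `awake_min`,
#'   `rem_min`, `light_min`, `deep_min`, `wakeups_per_week`,
#'   `sleep_quality_pct`, `n_nights`, `n_dropped` (non-wear nights).
#' @export
summarize_sleep <- function(nights, quality = c("aggregate", "nightly_mean")) {
  quality <- match.arg(quality)
  validate_sleep_nights(nights)
  if (nrow(nights) == 0) stop("no nights provided", call. = FALSE)
  dropped <- nights |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_dropped = sum(.data$total_inactive_min == 0),
                     .groups = "drop")
  kept <- nights[nights$total_inactive_min > 0, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop("every night has zero inactive time (device non-wear)",
         call. = FALSE)
  }
  out <- kept |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      tst_min = mean(.data$total_inactive_min - .data$total_awake_min),
      awake_min = mean(.data$total_awake_min),
      rem_min = mean(.data$rem_min),
      light_min = mean(.data$light_min),
      deep_min = mean(.data$deep_min),
      wakeups_per_week = wakeups_per_week(.data$n_wakeups),
      nightly_quality = mean(sleep_quality(
        .data$total_inactive_min - .data$total_awake_min,
        .data$total_awake_min
      )),
      n_nights = dplyr::n(),
      .groups = "drop"
    )
  out$sleep_quality_pct <- if (quality == "aggregate") {
    sleep_quality(out$tst_min, out$awake_min)
  } else {
    out$nightly_quality
  }
  out |>
    dplyr::left_join(dropped, by = "participant_id") |>
    dplyr::select("participant_id", "tst_min", "awake_min", "rem_min",
                  "light_min", "deep_min", "wakeups_per_week",
                  "sleep_quality_pct", "n_nights", "n_dropped")
}
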