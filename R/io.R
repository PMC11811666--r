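cohort_schemas <- list(
  participants = c("participant_id", "sex", "age", "bmi"),
  heart_rate = c("participant_id", "timestamp", "bpm"),
  steps = c("participant_id", "timestamp", "steps_cumulative"),
  sleep = c("participant_id", "date", "total_inactive_min",
            "total_awake_min", "rem_min", "light_min", "deep_min",
            "n_wakeups"),
  ema = c("participant_id", "date", "kind", "slot", "magnitude", "category"),
  questionnaires = c("participant_id", "instrument", "item_index", "rating",
                     "sex")
)

check_columns <- function(df, stream) {
  required <- cohort_schemas[[stream]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s.csv is missing column(s): %s", stream,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

series_to_long <- function(series_list, value_col) {
  purrr::map_dfr(series_list, function(s) {
    tibble::tibble(
      participant_id = s$participant_id,
      timestamp = s$start + (seq_along(s$values) - 1) * s$epoch_minutes * 60,
      value = s$values
    )
  }) |>
    dplyr::rename(!!value_col := "value")
}

long_to_series <- function(df, value_col) {
  df <- df[order(df$participant_id, df$timestamp), ]
  out <- lapply(split(df, df$participant_id), function(d) {
    if (nrow(d) < 2) {
      stop("epoch series needs at least 2 timestamps to infer the epoch",
           call. = FALSE)
    }
    epoch <- as.numeric(difftime(d$timestamp[2], d$timestamp[1],
                                 units = "mins"))
    epoch_series(d[[value_col]], d$timestamp[1], epoch,
                 d$participant_id[1])
  })
  out
}

#' Write a cohort to plain CSV files plus a truth sidecar
#'
#' One CSV per stream (`participants.csv`, `heart_rate.csv`, `steps.csv`,
#' `sleep.csv`, `ema.csv`, `questionnaires.csv`; only generated streams are
#' written) with ISO-8601 timestamps, and the generator truth as
#' `truth.json`. The truth sidecar exists for generator diagnostics only and
#' is never read back by [read_cohort()].
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"))
  if (!is.null(cohort$heart_rate)) {
    readr::write_csv(series_to_long(cohort$heart_rate, "bpm"),
                     file.path(dir, "heart_rate.csv"))
  }
  if (!is.null(cohort$steps)) {
    readr::write_csv(series_to_long(cohort$steps, "steps_cumulative"),
                     file.path(dir, "steps.csv"))
  }
  if (!is.null(cohort$sleep)) {
    readr::write_csv(cohort$sleep, file.path(dir, "sleep.csv"))
  }
  if (!is.null(cohort$ema)) {
    readr::write_csv(cohort$ema, file.path(dir, "ema.csv"))
  }
  if (!is.null(cohort$questionnaires)) {
    readr::write_csv(cohort$questionnaires,
                     file.path(dir, "questionnaires.csv"))
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a cohort back from CSV files
#'
#' Validates each file's schema (the error names the first missing column)
#' and reconstructs the heart-rate and step streams as [epoch_series()]
#' objects. The `truth.json` sidecar is deliberately not read; use
#' [read_truth()] in generator-recovery contexts only.
#'
#' @param dir Directory written by [write_cohort()].
#' @param streams Streams to read (present files among the defaults).
#' @return A list shaped like [generate_cohort()]'s value, without `truth`.
#' @export
read_cohort <- function(dir,
                        streams = c("heart_rate", "steps", "sleep",
                                    "questionnaires", "ema")) {
  out <- list()
  out$participants <- check_columns(
    readr::read_csv(file.path(dir, "participants.csv"),
                    show_col_types = FALSE),
    "participants"
  )
  for (stream in streams) {
    path <- file.path(dir, paste0(stream, ".csv"))
    if (!file.exists(path)) next
    df <- check_columns(readr::read_csv(path, show_col_types = FALSE),
                        stream)
    out[[stream]] <- switch(
      stream,
      heart_rate = long_to_series(df, "bpm"),
      steps = long_to_series(df, "steps_cumulative"),
      df
    )
  }
  out
}

#' Read the generator truth sidecar
#'
#' @param dir Directory written by [write_cohort()].
#' @return Tibble of per-participant truth (group, circadian parameters).
#' @export
read_truth <- function(dir) {
  tibble::as_tibble(jsonlite::read_json(file.path(dir, "truth.json"),
                                        simplifyVector = TRUE))
}
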