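#' Construct an epoch series
#'
#' A light container for uniformly sampled physiological streams (heart rate
#' in bpm, step increments, cumulative steps). Missing epochs are encoded as
#' `NA` in `values`.
#'
#' @param values Numeric samples, one per epoch; `NA` marks a missing epoch.
#' @param start POSIXct (or ISO-8601 string) timestamp of the first epoch.
#' @param epoch_minutes Epoch length in minutes; must divide 1440.
#' @param participant_id Optional participant identifier carried along.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(values, start, epoch_minutes,
                         participant_id = NA_character_) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (is.character(start) || inherits(start, "Date")) {
    start <- as.POSIXct(start, tz = "UTC")
  }
  if (!inherits(start, "POSIXct")) {
    stop("start must be a POSIXct timestamp", call. = FALSE)
  }
  if (length(epoch_minutes) != 1 || epoch_minutes <= 0 ||
      1440 %% epoch_minutes != 0) {
    stop("epoch_minutes must be a positive divisor of 1440", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), start = start,
         epoch_minutes = as.integer(epoch_minutes),
         participant_id = participant_id),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %d epochs of %d min from %s (%.1f%% missing)\n",
    length(x$values), x$epoch_minutes,
    format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

# Hours since midnight of the series' first calendar day, one per epoch.
epoch_hours <- function(series) {
  midnight <- as.POSIXct(format(series$start, "%Y-%m-%d", tz = "UTC"),
                         tz = "UTC")
  h0 <- as.numeric(difftime(series$start, midnight, units = "hours"))
  h0 + (seq_along(series$values) - 1) * series$epoch_minutes / 60
}

# Calendar date of each epoch.
epoch_dates <- function(series) {
  as.Date(series$start, tz = "UTC") + floor(epoch_hours(series) / 24)
}

#' Difference a cumulative series into per-epoch increments
#'
#' Cumulative streams (step counts, walking distance) reset to zero at
#' midnight. The first observed epoch of each calendar day is treated as its
#' own increment from zero; later increments are differences from the last
#' observed value within the same day, so that within-day increments
#' telescope back to the day's final cumulative value. Missing epochs stay
#' missing. A within-day decrease beyond `tolerance` is a data error; small
#' negative differences within tolerance are clamped to zero.
#'
#' @param series An [epoch_series()] of cumulative values.
#' @param tolerance Largest tolerated within-day decrease.
#' @return An [epoch_series()] of nonnegative per-epoch increments.
#' @export
difference_cumulative <- function(series, tolerance = 1e-8) {
  stopifnot(inherits(series, "epoch_series"))
  vals <- series$values
  inc <- rep(NA_real_, length(vals))
  obs <- which(!is.na(vals))
  if (length(obs) > 0) {
    day <- epoch_dates(series)[obs]
    prev_val <- c(NA_real_, vals[obs[-length(obs)]])
    same_day <- c(FALSE, day[-1] == day[-length(day)])
    d <- ifelse(same_day, vals[obs] - prev_val, vals[obs])
    bad <- which(d < -tolerance)
    if (length(bad) > 0) {
      stop(sprintf(
        "cumulative series decreases within a day at epoch %d (by %.6g)",
        obs[bad[1]], -d[bad[1]]
      ), call. = FALSE)
    }
    inc[obs] <- pmax(d, 0)
  }
  epoch_series(inc, series$start, series$epoch_minutes,
               series$participant_id)
}

#' Fit a single-component cosinor model
#'
#' Least-squares fit of `y(t) = M + beta*cos(2*pi*t/tau) +
#' gamma*sin(2*pi*t/tau)` by the linearized (cos/sin basis) regression, which
#' is exact for this model. MESOR is the rhythm-adjusted mean `M`; amplitude
#' is `sqrt(beta^2 + gamma^2)` (peak minus MESOR); acrophase is the fitted
#' peak time in hours past midnight, in `[0, 24)`; goodness of fit is the
#' coefficient of determination against the mean-only model, in `[0, 1]`.
#'
#' A zero-variance series returns amplitude 0 and goodness of fit 0 by
#' convention (acrophase undefined, `NA`).
#'
#' @param series An [epoch_series()].
#' @param period_hours Rhythm period, default 24.
#' @return An object of class `cosinor_fit`: a list with `mesor`,
#'   `amplitude`, `acrophase` (hours past midnight in `[0, 24)`),
#'   `acrophase_signed` (same angle mapped to `(-12, 12]`), `gof`, `n_used`,
#'   and `window_start`.
#' @export
cosinor_fit <- function(series, period_hours = 24) {
  stopifnot(inherits(series, "epoch_series"))
  t_h <- epoch_hours(series)
  ok <- !is.na(series$values)
  if (sum(ok) < 3) {
    stop("cosinor fit needs at least 3 non-missing samples", call. = FALSE)
  }
  t_h <- t_h[ok]
  y <- series$values[ok]
  if (diff(range(t_h)) < 0.9 * period_hours) {
    stop("cosinor fit needs samples spanning at least one period",
         call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12) {
    fit <- list(mesor = mean(y), amplitude = 0, acrophase = NA_real_,
                acrophase_signed = NA_real_, gof = 0, n_used = length(y),
                window_start = series$start)
    class(fit) <- "cosinor_fit"
    return(fit)
  }
  omega <- 2 * pi / period_hours
  X <- cbind(1, cos(omega * t_h), sin(omega * t_h))
  coef <- qr.coef(qr(X), y)
  resid <- y - X %*% coef
  beta <- coef[2]
  gamma <- coef[3]
  amplitude <- sqrt(beta^2 + gamma^2)
  acrophase <- (atan2(gamma, beta) / omega) %% period_hours
  gof <- max(0, min(1, 1 - sum(resid^2) / tss))
  fit <- list(
    mesor = unname(coef[1]),
    amplitude = unname(amplitude),
    acrophase = unname(acrophase),
    acrophase_signed = unname(((acrophase + period_hours / 2) %%
                                 period_hours) - period_hours / 2),
    gof = gof,
    n_used = length(y),
    window_start = series$start
  )
  class(fit) <- "cosinor_fit"
  fit
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> MESOR %.3f, amplitude %.3f, acrophase %.2f h, R^2 %.3f (n=%d)\n",
    x$mesor, x$amplitude, x$acrophase, x$gof, x$n_used
  ))
  invisible(x)
}

# Circular mean of clock-hour angles on a given period; NA-dropped.
circular_mean_hours <- function(hours, period = 24) {
  hours <- hours[!is.na(hours)]
  if (length(hours) == 0) return(NA_real_)
  theta <- 2 * pi * hours / period
  (atan2(mean(sin(theta)), mean(cos(theta))) * period / (2 * pi)) %% period
}

#' Sliding-window cosinor analysis
#'
#' Fits the cosinor model in windows of `window_days` days advanced by
#' `step_days` (the main parameters are generated in a 2-day window by
#' default) and averages the parameters across windows: MESOR, amplitude,
#' and goodness of fit arithmetically, acrophase by circular (vector) mean so
#' the 0/24 wrap does not distort the average. Windows with less than
#' `min_coverage` non-missing data are skipped and counted.
#'
#' @param series An [epoch_series()].
#' @param window_days Window length in days (default 2).
#' @param step_days Window step in days (default 1).
#' @param period_hours Rhythm period, default 24.
#' @param min_coverage Minimum non-missing fraction for a window to be fit.
#' @return List with `fits` (tibble of per-window parameters) and `summary`
#'   (list: `mesor`, `amplitude`, `acrophase`, `acrophase_signed`, `gof`,
#'   `n_windows`, `n_skipped`).
#' @export
sliding_cosinor <- function(series, window_days = 2, step_days = 1,
                            period_hours = 24, min_coverage = 0.5) {
  stopifnot(inherits(series, "epoch_series"))
  epd <- 1440L %/% series$epoch_minutes
  n_days <- ceiling(length(series$values) / epd)
  if (n_days < window_days) {
    stop("series must span at least window_days days", call. = FALSE)
  }
  starts <- seq(0, n_days - window_days, by = step_days)
  fits <- vector("list", length(starts))
  skipped <- 0L
  for (i in seq_along(starts)) {
    idx <- (starts[i] * epd + 1):min((starts[i] + window_days) * epd,
                                     length(series$values))
    vals <- series$values[idx]
    if (mean(!is.na(vals)) < min_coverage) {
      skipped <- skipped + 1L
      next
    }
    win <- epoch_series(vals,
                        series$start + starts[i] * 86400,
                        series$epoch_minutes, series$participant_id)
    f <- cosinor_fit(win, period_hours = period_hours)
    fits[[i]] <- tibble::tibble(
      window_start = f$window_start, mesor = f$mesor,
      amplitude = f$amplitude, acrophase = f$acrophase, gof = f$gof
    )
  }
  fits <- dplyr::bind_rows(fits)
  if (nrow(fits) == 0) {
    stop("no window had sufficient coverage for a cosinor fit",
         call. = FALSE)
  }
  acro <- circular_mean_hours(fits$acrophase, period_hours)
  list(
    fits = fits,
    summary = list(
      mesor = mean(fits$mesor),
      amplitude = mean(fits$amplitude),
      acrophase = acro,
      acrophase_signed = if (is.na(acro)) NA_real_ else {
        ((acro + period_hours / 2) %% period_hours) - period_hours / 2
      },
      gof = mean(fits$gof),
      n_windows = nrow(fits),
      n_skipped = skipped
    )
  )
}

#' Bin an epoch series into fixed clock-aligned bins
#'
#' Bins are aligned to midnight of the first calendar day. A bin's mean is
#' `NA` when less than `min_coverage` of its expected epochs are observed.
#'
#' @param series An [epoch_series()].
#' @param bin_minutes Bin width in minutes; must be a multiple of the epoch
#'   length and divide 1440.
#' @param min_coverage Minimum observed fraction for a bin mean to be kept.
#' @return Tibble with `bin_index` (0-based from midnight of day 1),
#'   `bin_of_day` (0-based within the day), and `bin_mean`.
#' @export
bin_series <- function(series, bin_minutes = 60, min_coverage = 0.5) {
  stopifnot(inherits(series, "epoch_series"))
  if (bin_minutes %% series$epoch_minutes != 0 || 1440 %% bin_minutes != 0) {
    stop("bin_minutes must be a multiple of epoch_minutes dividing 1440",
         call. = FALSE)
  }
  per_bin <- bin_minutes %/% series$epoch_minutes
  bins_per_day <- 1440L %/% bin_minutes
  bin_index <- floor(epoch_hours(series) / (bin_minutes / 60))
  agg <- tibble::tibble(bin_index = bin_index, value = series$values) |>
    dplyr::group_by(.data$bin_index) |>
    dplyr::summarise(
      n_obs = sum(!is.na(.data$value)),
      bin_mean = mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  agg$bin_mean[agg$n_obs < min_coverage * per_bin] <- NA_real_
  agg$bin_mean[agg$n_obs == 0] <- NA_real_
  tibble::tibble(
    bin_index = as.integer(agg$bin_index),
    bin_of_day = as.integer(agg$bin_index %% bins_per_day),
    bin_mean = agg$bin_mean
  )
}

#' Intradaily variability (IV)
#'
#' The normalized mean squared successive difference of binned (hourly by
#' default) values: `IV = n * sum(diff(x)^2) / ((n-1) * sum((x - mean)^2))`.
#' High values indicate a fragmented rhythm; white noise gives IV near 2; a
#' smooth 24-h rhythm gives IV near 0. With missing bins, successive
#' differences are taken only across adjacent observed bins and the same
#' mean-square normalization applies.
#'
#' @param series An [epoch_series()].
#' @param bin_minutes Bin width, default 60.
#' @param min_coverage Minimum per-bin coverage, see [bin_series()].
#' @return IV (nonnegative scalar), or `NA` with a warning when the binned
#'   series has zero variance or fewer than 2 usable bins.
#' @export
intradaily_variability <- function(series, bin_minutes = 60,
                                   min_coverage = 0.5) {
  b <- bin_series(series, bin_minutes, min_coverage)
  x <- b$bin_mean
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) {
    warning("fewer than 2 usable bins; IV undefined")
    return(NA_real_)
  }
  xb <- mean(x[ok])
  denom <- sum((x[ok] - xb)^2) / n
  adj <- which(ok[-1] & ok[-length(ok)] &
                 diff(b$bin_index) == 1)
  if (length(adj) == 0) {
    warning("no adjacent observed bins; IV undefined")
    return(NA_real_)
  }
  d <- x[adj + 1] - x[adj]
  if (denom < 1e-300) {
    warning("zero variance; IV undefined")
    return(NA_real_)
  }
  (sum(d^2) / length(d)) / denom
}

#' Interdaily stability (IS)
#'
#' The variance of the average 24-hour profile relative to the total
#' variance of the binned series:
#' `IS = n * sum((xbar_h - xbar)^2) / (p * sum((x_i - xbar)^2))`,
#' with `p` bins per day (24 hourly bins by default). IS is 1 for a
#' perfectly repeating daily pattern and near 0 for noise.
#'
#' @inheritParams intradaily_variability
#' @return IS in `[0, 1]` for complete balanced data, or `NA` with a warning
#'   when undefined.
#' @export
interdaily_stability <- function(series, bin_minutes = 60,
                                 min_coverage = 0.5) {
  b <- bin_series(series, bin_minutes, min_coverage)
  x <- b$bin_mean[!is.na(b$bin_mean)]
  hod <- b$bin_of_day[!is.na(b$bin_mean)]
  n <- length(x)
  if (n < 2) {
    warning("fewer than 2 usable bins; IS undefined")
    return(NA_real_)
  }
  xb <- mean(x)
  ss_tot <- sum((x - xb)^2)
  if (ss_tot < 1e-300) {
    warning("zero variance; IS undefined")
    return(NA_real_)
  }
  profile <- tapply(x, hod, mean)
  p <- length(profile)
  n * sum((profile - xb)^2) / (p * ss_tot)
}

# Moving average over a fixed epoch window; NA-aware. Returns NA where the
# observed fraction falls below min_coverage. Positions with any part of the
# window beyond the series end are excluded (no partial trailing windows).
# Windowed sums come from stats::filter (per-window summation), not cumsum
# differencing, so results agree with naive per-window means to full
# precision.
moving_average <- function(values, width, min_coverage = 0.5) {
  n <- length(values)
  if (n < width) return(numeric(0))
  v <- values
  v[is.na(v)] <- 0
  obs <- as.numeric(!is.na(values))
  idx <- seq_len(n - width + 1)
  sums <- stats::filter(v, rep(1, width), sides = 1)[idx + width - 1]
  counts <- stats::filter(obs, rep(1, width), sides = 1)[idx + width - 1]
  out <- as.numeric(sums / counts)
  out[counts < min_coverage * width] <- NA_real_
  out
}

#' Least-active 5-hour and most-active 10-hour levels (L5, M10)
#'
#' Moving averages on the series' own epoch grid: L5 is the minimum of the
#' 5-hour moving average, M10 the maximum of the 10-hour moving average.
#' Incomplete trailing windows are excluded. Returns the window onset times
#' as hours past midnight of day 1.
#'
#' @param series An [epoch_series()] (activity increments for rest-activity
#'   use).
#' @param l_hours L window length in hours (default 5).
#' @param m_hours M window length in hours (default 10).
#' @param min_coverage Minimum observed fraction within a window.
#' @return List with `l5`, `m10`, `l5_onset_hours`, `m10_onset_hours`.
#' @export
l5_m10 <- function(series, l_hours = 5, m_hours = 10, min_coverage = 0.5) {
  stopifnot(inherits(series, "epoch_series"))
  w5 <- as.integer(l_hours * 60 / series$epoch_minutes)
  w10 <- as.integer(m_hours * 60 / series$epoch_minutes)
  if (length(series$values) < w10) {
    stop("series too short for the 10-hour window", call. = FALSE)
  }
  ma5 <- moving_average(series$values, w5, min_coverage)
  ma10 <- moving_average(series$values, w10, min_coverage)
  if (all(is.na(ma5)) || all(is.na(ma10))) {
    stop("insufficient coverage for L5/M10", call. = FALSE)
  }
  hours <- epoch_hours(series)
  i5 <- which.min(ma5)
  i10 <- which.max(ma10)
  list(
    l5 = ma5[i5], m10 = ma10[i10],
    l5_onset_hours = hours[i5], m10_onset_hours = hours[i10]
  )
}

#' Stratified daily aggregates
#'
#' Computes each calendar day's maximum, minimum, and mean, and averages
#' them by weekday/weekend and by daytime (08:00-18:00 by default) versus
#' night (18:00-08:00, crossing midnight and attributed to the evening's
#' date).
#'
#' @param series An [epoch_series()].
#' @param day_start,day_end Daytime block boundaries in hours (default 8
#'   and 18); night is the complement.
#' @return Tibble with one row per stratum (`weekday`, `weekend`, `daytime`,
#'   `night`): `mean_daily_max`, `mean_daily_min`, `mean_daily_mean`,
#'   `n_days`.
#' @export
stratified_aggregates <- function(series, day_start = 8, day_end = 18) {
  stopifnot(inherits(series, "epoch_series"))
  hours <- epoch_hours(series)
  hod <- hours %% 24
  date <- epoch_dates(series)
  vals <- series$values
  daily <- function(dates_vec, keep) {
    tibble::tibble(date = dates_vec[keep], value = vals[keep]) |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::group_by(.data$date) |>
      dplyr::summarise(
        day_max = max(.data$value), day_min = min(.data$value),
        day_mean = mean(.data$value), .groups = "drop"
      )
  }
  summarize_block <- function(tbl, stratum) {
    if (nrow(tbl) == 0) {
      return(tibble::tibble(
        stratum = stratum, mean_daily_max = NA_real_,
        mean_daily_min = NA_real_, mean_daily_mean = NA_real_, n_days = 0L
      ))
    }
    tibble::tibble(
      stratum = stratum,
      mean_daily_max = mean(tbl$day_max),
      mean_daily_min = mean(tbl$day_min),
      mean_daily_mean = mean(tbl$day_mean),
      n_days = nrow(tbl)
    )
  }
  all_daily <- daily(date, rep(TRUE, length(vals)))
  is_weekend <- format(all_daily$date, "%u") %in% c("6", "7")
  # night epochs before day_start belong to the previous evening's date
  night_date <- date
  night_date[hod < day_start] <- date[hod < day_start] - 1
  in_day <- hod >= day_start & hod < day_end
  dplyr::bind_rows(
    summarize_block(all_daily[!is_weekend, ], "weekday"),
    summarize_block(all_daily[is_weekend, ], "weekend"),
    summarize_block(daily(date, in_day), "daytime"),
    summarize_block(daily(night_date, !in_day), "night")
  )
}

#' Circadian feature row for one participant
#'
#' Combines the sliding 2-day cosinor on heart rate, the cosinor on
#' differenced step increments, and the nonparametric rest-activity metrics
#' (IV, IS, L5, M10, computed on step increments) into one feature row.
#'
#' @param hr An [epoch_series()] of heart rate (bpm).
#' @param steps_cumulative An [epoch_series()] of cumulative step counts.
#' @param window_days Cosinor window length in days (default 2).
#' @param step_days Cosinor window step in days (default 1).
#' @return One-row tibble with `hr_mesor`, `hr_amplitude`, `hr_acrophase`,
#'   `hr_gof`, `steps_mesor`, `steps_amplitude`, `steps_acrophase`,
#'   `steps_gof`, `iv`, `is_`, `l5`, `m10`.
#' @export
circadian_participant_features <- function(hr, steps_cumulative,
                                           window_days = 2, step_days = 1) {
  inc <- difference_cumulative(steps_cumulative)
  hr_fit <- sliding_cosinor(hr, window_days, step_days)$summary
  st_fit <- sliding_cosinor(inc, window_days, step_days)$summary
  lm <- l5_m10(inc)
  tibble::tibble(
    participant_id = hr$participant_id,
    hr_mesor = hr_fit$mesor, hr_amplitude = hr_fit$amplitude,
    hr_acrophase = hr_fit$acrophase, hr_gof = hr_fit$gof,
    steps_mesor = st_fit$mesor, steps_amplitude = st_fit$amplitude,
    steps_acrophase = st_fit$acrophase, steps_gof = st_fit$gof,
    iv = intradaily_variability(inc),
    is_ = interdaily_stability(inc),
    l5 = lm$l5, m10 = lm$m10
  )
}
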