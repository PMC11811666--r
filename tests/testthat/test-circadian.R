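test_that("cumulative differencing telescopes and handles day resets", {
  s <- epoch_series(c(0, 10, 25, 25), "2023-03-06", 360)
  expect_equal(difference_cumulative(s)$values, c(0, 10, 15, 0))
  # two days: increments per day sum to the day's final cumulative value
  two <- epoch_series(c(0, 2000, 5000, 5000, 0, 1000, 2500, 3000),
                      "2023-03-06", 360)
  inc <- difference_cumulative(two)$values
  expect_equal(sum(inc[1:4]), 5000)
  expect_equal(sum(inc[5:8]), 3000)
  # constant series differentiates to zero
  expect_equal(difference_cumulative(
    epoch_series(rep(7, 8), "2023-03-06", 360))$values,
    c(7, rep(0, 3), 7, rep(0, 3)))  # day-boundary resets re-count the level
  # a within-day decrease is an error naming the epoch
  bad <- epoch_series(c(0, 10, 8, 20), "2023-03-06", 360)
  expect_error(difference_cumulative(bad), "epoch 3")
  # missing epochs: the gap increment lands on the next observed epoch
  gap <- epoch_series(c(0, 10, NA, 30), "2023-03-06", 360)
  expect_equal(difference_cumulative(gap)$values, c(0, 10, NA, 20))
})

test_that("differencing inverts per-day accumulation of increments", {
  set.seed(31)
  for (rep in 1:5) {
    inc <- round(stats::rexp(4 * 48, 1 / 30))
    day <- rep(1:4, each = 48)
    cum <- stats::ave(inc, day, FUN = cumsum)
    s <- epoch_series(cum, "2023-03-06", 30)
    expect_equal(difference_cumulative(s)$values, inc)
  }
})

test_that("cosinor recovers its own model exactly", {
  s <- make_cosine_series(mesor = 75, amplitude = 10, acrophase = 15,
                          days = 2, epoch_minutes = 5)
  f <- cosinor_fit(s)
  expect_equal(f$mesor, 75, tolerance = 1e-6)
  expect_equal(f$amplitude, 10, tolerance = 1e-6)
  expect_equal(f$acrophase, 15, tolerance = 1e-6)
  expect_equal(f$gof, 1, tolerance = 1e-6)
  # value checks at the peak and trough-side hours
  idx15 <- which.min(abs(epoch_hours(s) - 15))
  idx3 <- which.min(abs(epoch_hours(s) - 3))
  expect_equal(s$values[idx15], 85)
  expect_equal(s$values[idx3], 65)
  # wrap-around acrophase near midnight stays in [0, 24)
  f2 <- cosinor_fit(make_cosine_series(acrophase = 23.5))
  expect_equal(f2$acrophase, 23.5, tolerance = 1e-6)
  expect_equal(f2$acrophase_signed, -0.5, tolerance = 1e-6)
  # constant series: amplitude 0, gof 0 by convention
  fc <- cosinor_fit(epoch_series(rep(70, 576), "2023-03-06", 5))
  expect_equal(fc$mesor, 70)
  expect_equal(fc$amplitude, 0)
  expect_equal(fc$gof, 0)
  # insufficient data errors
  expect_error(cosinor_fit(epoch_series(c(1, 2), "2023-03-06", 5)),
               "3 non-missing")
  expect_error(cosinor_fit(epoch_series(rnorm(36), "2023-03-06", 5)),
               "spanning")
})

test_that("goodness of fit degrades as noise grows", {
  set.seed(77)
  gof_at <- function(sd) {
    mean(replicate(8, cosinor_fit(make_cosine_series(days = 4,
                                                     noise_sd = sd))$gof))
  }
  g <- vapply(c(0, 3, 8, 20), gof_at, numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("sliding cosinor windows average to the stationary fit", {
  s <- make_cosine_series(days = 28)
  sl <- sliding_cosinor(s, window_days = 2, step_days = 1)
  expect_equal(nrow(sl$fits), 27)
  expect_equal(sl$summary$mesor, 75, tolerance = 1e-6)
  expect_equal(sl$summary$amplitude, 10, tolerance = 1e-6)
  expect_equal(sl$summary$acrophase, 15, tolerance = 1e-6)
  expect_equal(sl$summary$gof, 1, tolerance = 1e-6)
  expect_true(all(abs(sl$fits$acrophase - 15) < 1e-6))
  expect_error(sliding_cosinor(make_cosine_series(days = 1)),
               "window_days")
})

test_that("acrophase averaging is circular and tracks a slow drift", {
  # acrophase drifting +0.2 h/day: the average should sit mid-study
  days <- 28
  epoch <- 5
  n <- days * 1440 / epoch
  t_h <- (seq_len(n) - 1) * epoch / 60
  drift <- 0.2 / 24
  y <- 75 + 10 * cos(2 * pi * (t_h - (15 + drift * t_h)) / 24)
  s <- epoch_series(y, "2023-03-06", epoch)
  sl <- sliding_cosinor(s)
  expect_equal(sl$summary$acrophase, 15 + 0.2 * days / 2, tolerance = 0.1)
  # brute-force check: circular mean of the per-window acrophases
  theta <- 2 * pi * sl$fits$acrophase / 24
  brute <- (atan2(mean(sin(theta)), mean(cos(theta))) * 24 / (2 * pi)) %% 24
  expect_equal(sl$summary$acrophase, brute, tolerance = 1e-12)
  # circularity matters: acrophases straddling midnight average near 0, not 12
  wrap <- c(23.6, 0.4)
  theta_w <- 2 * pi * wrap / 24
  m <- (atan2(mean(sin(theta_w)), mean(cos(theta_w))) * 24 / (2 * pi)) %% 24
  expect_equal(m, 0, tolerance = 1e-9)
})

test_that("IV and IS match the double-loop oracles to 1e-12", {
  set.seed(123)
  for (n_bins in c(24, 48, 120, 200)) {
    x <- 50 + 20 * cos(2 * pi * (seq_len(n_bins) - 1) / 24) +
      rnorm(n_bins, 0, 10)
    s <- epoch_series(x, "2023-03-06", 60)
    expect_equal(intradaily_variability(s), oracle_iv(x), tolerance = 1e-12)
    expect_equal(interdaily_stability(s), oracle_is(x, 24),
                 tolerance = 1e-12)
  }
})

test_that("IV hits its closed-form, white-noise, and fragmented regimes", {
  # smooth 24-h cosine on hourly bins: 2*(1 - cos(pi/12)) * n/(n-1)
  n_bins <- 72
  x <- 75 + 10 * cos(2 * pi * (seq_len(n_bins) - 1) / 24)
  s <- epoch_series(x, "2023-03-06", 60)
  # (the non-cyclic successive-difference sum leaves a small boundary term)
  expect_equal(intradaily_variability(s),
               2 * (1 - cos(pi / 12)) * n_bins / (n_bins - 1),
               tolerance = 1e-3)
  expect_equal(intradaily_variability(s), 0.068, tolerance = 0.05)
  # i.i.d. noise: IV near 2 (n = 2400 bins; 3 SE by simulation is ~0.12)
  set.seed(99)
  noise <- epoch_series(rnorm(2400), "2023-03-06", 60)
  expect_equal(intradaily_variability(noise), 2, tolerance = 0.12)
  # alternating high/low bins exceed the white-noise value
  alt <- epoch_series(rep(c(0, 100), 12), "2023-03-06", 60)
  expect_gt(intradaily_variability(alt), 2)
  expect_equal(intradaily_variability(alt), oracle_iv(rep(c(0, 100), 12)),
               tolerance = 1e-12)
  # zero variance flagged
  expect_warning(
    iv0 <- intradaily_variability(epoch_series(rep(5, 48), "2023-03-06", 60)),
    "zero variance")
  expect_true(is.na(iv0))
})

test_that("IS spans its limiting regimes", {
  # identical repeating daily profile: IS = 1 exactly
  profile <- c(rep(10, 8), rep(80, 10), rep(30, 6))
  s <- epoch_series(rep(profile, 7), "2023-03-06", 60)
  expect_equal(interdaily_stability(s), 1, tolerance = 1e-12)
  # i.i.d. noise over many days: IS near 1/n_days, far below 1
  set.seed(7)
  noise <- epoch_series(rnorm(24 * 100), "2023-03-06", 60)
  expect_lt(interdaily_stability(noise), 0.1)
  # repeating profile with one disturbed day: strictly between 0 and 1
  disturbed <- rep(profile, 7)
  disturbed[25:48] <- rev(profile)
  s2 <- epoch_series(disturbed, "2023-03-06", 60)
  is2 <- interdaily_stability(s2)
  expect_gt(is2, 0)
  expect_lt(is2, 1)
})

test_that("L5/M10 match brute-force enumeration of window positions", {
  set.seed(55)
  x <- pmax(0, 30 + 25 * cos(2 * pi * ((seq_len(576) - 1) / 12 - 14) / 24) +
              rnorm(576, 0, 8))
  s <- epoch_series(x, "2023-03-06", 5)
  lm <- l5_m10(s)
  ma5 <- oracle_moving_means(x, 60)
  ma10 <- oracle_moving_means(x, 120)
  expect_equal(lm$l5, min(ma5), tolerance = 1e-12)
  expect_equal(lm$m10, max(ma10), tolerance = 1e-12)
  hours <- (seq_len(576) - 1) / 12
  expect_equal(lm$l5_onset_hours, hours[which.min(ma5)])
  expect_equal(lm$m10_onset_hours, hours[which.max(ma10)])
  # constant series: L5 = M10 = c
  cs <- epoch_series(rep(42, 300), "2023-03-06", 5)
  lc <- l5_m10(cs)
  expect_equal(lc$l5, 42)
  expect_equal(lc$m10, 42)
  # invariant L5 <= M10 on random series
  for (i in 1:5) {
    r <- epoch_series(rexp(400, 1 / 50), "2023-03-06", 5)
    lr <- l5_m10(r)
    expect_lte(lr$l5, lr$m10)
  }
  expect_error(l5_m10(epoch_series(rnorm(50), "2023-03-06", 5)),
               "too short")
})

test_that("daily aggregates stratify by weekday/weekend and day/night", {
  epoch <- 60
  # 28 days from a Monday: values high 8-18h, low otherwise
  hod <- rep(0:23, 28)
  vals <- ifelse(hod >= 8 & hod < 18, 100, 10)
  s <- epoch_series(vals, "2023-03-06", epoch)
  agg <- stratified_aggregates(s)
  expect_equal(agg$n_days[agg$stratum == "weekday"], 20)
  expect_equal(agg$n_days[agg$stratum == "weekend"], 8)
  expect_gt(agg$mean_daily_mean[agg$stratum == "daytime"],
            agg$mean_daily_mean[agg$stratum == "night"])
  expect_equal(agg$mean_daily_mean[agg$stratum == "daytime"], 100)
  expect_equal(agg$mean_daily_mean[agg$stratum == "night"], 10)
  # identical days make weekday and weekend aggregates equal
  expect_equal(
    agg$mean_daily_max[agg$stratum == "weekday"],
    agg$mean_daily_max[agg$stratum == "weekend"]
  )
  # a Saturday-only series contributes nothing to weekday strata
  sat <- epoch_series(rep(5, 24), "2023-03-11", epoch)
  agg_sat <- stratified_aggregates(sat)
  expect_equal(agg_sat$n_days[agg_sat$stratum == "weekday"], 0)
  expect_equal(agg_sat$n_days[agg_sat$stratum == "weekend"], 1)
})

test_that("night epochs attribute to the evening's date", {
  # 2 days, value 1 during night hours of evening 1 (18h day1 - 8h day2)
  hod <- rep(0:23, 2)
  day <- rep(1:2, each = 24)
  vals <- as.numeric((day == 1 & hod >= 18) | (day == 2 & hod < 8))
  s <- epoch_series(vals, "2023-03-06", 60)
  agg <- stratified_aggregates(s)
  night <- agg[agg$stratum == "night", ]
  # evening-1 night block is all 1s; evening-2 block (18-24h day2) all 0s;
  # the leading 0-8h of day 1 attributes to the (absent) previous evening
  expect_equal(night$n_days, 3)
  expect_equal(night$mean_daily_mean, (0 + 1 + 0) / 3)
})
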