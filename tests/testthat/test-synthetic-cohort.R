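test_that("configuration invariants are enforced", {
  expect_error(cohort_config(group_proportions = c(0.5, 0.5, 0.1, 0)),
               "summing to 1")
  expect_error(cohort_config(group_proportions = c(1.2, -0.2, 0, 0)),
               "nonnegative")
  expect_error(cohort_config(study_days = 1), "study_days")
  expect_error(cohort_config(hr_epoch_minutes = 7), "divide 1440")
  expect_error(cohort_config(n_participants = 0), "positive")
  # parameter overrides merge into the defaults
  cfg <- cohort_config(hr = list(noise_sd = 3))
  expect_equal(cfg$hr$noise_sd, 3)
  expect_equal(cfg$hr$mesor_mean, 74.56)
})

test_that("the same config and seed reproduce the cohort exactly", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$sleep, b$sleep)
  expect_identical(a$questionnaires, b$questionnaires)
  expect_identical(a$ema, b$ema)
  expect_identical(a$truth, b$truth)
  expect_identical(a$heart_rate[["P0001"]]$values,
                   b$heart_rate[["P0001"]]$values)
  expect_identical(a$steps[["P0007"]]$values, b$steps[["P0007"]]$values)
  # a different seed changes the draw
  cfg2 <- small_config()
  cfg2$seed <- 43L
  c2 <- generate_cohort(cfg2, streams = "sleep")
  expect_false(identical(a$sleep, c2$sleep))
  # the caller's RNG stream is left untouched
  set.seed(1)
  before <- .Random.seed
  invisible(generate_cohort(cfg, streams = "sleep"))
  expect_identical(.Random.seed, before)
})

test_that("group apportionment uses largest remainders", {
  cfg <- cohort_config(n_participants = 250)
  counts <- table(generate_cohort(cfg, streams = "sleep")$truth$group)
  expect_equal(unname(c(counts[c("no_insomnia", "mild", "moderate",
                                 "severe")])),
               c(63, 106, 69, 12))
  # degenerate single-group cohort: every ISI total in the lowest band
  cfg1 <- cohort_config(n_participants = 4, study_days = 2,
                        group_proportions = c(1, 0, 0, 0), seed = 5)
  q <- generate_cohort(cfg1, streams = "questionnaires")$questionnaires
  isi <- q[q$instrument == "ISI", ] |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(total = sum(rating))
  expect_true(all(isi$total <= 7))
})

test_that("generated ISI totals always respect the assigned band", {
  cfg <- cohort_config(n_participants = 60, study_days = 2, seed = 31)
  cohort <- generate_cohort(cfg, streams = "questionnaires")
  isi <- cohort$questionnaires[cohort$questionnaires$instrument == "ISI", ] |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(total = sum(rating))
  isi <- dplyr::left_join(isi, cohort$truth, by = "participant_id")
  expect_equal(as.character(classify_isi(isi$total)), isi$group)
})

test_that("heart-rate generation follows the circadian cosine", {
  cfg <- cohort_config(n_participants = 1, study_days = 2,
                       hr = list(noise_sd = 0, missing_frac = 0))
  p <- tibble::tibble(participant_id = "X", mesor = 75, amplitude = 10,
                      acrophase = 15)
  hr <- generate_heart_rate(p, cfg)
  expect_length(hr$values, 2 * 288)
  hod <- epoch_hours(hr) %% 24
  expect_equal(hr$values[hod == 15], c(85, 85))
  expect_equal(hr$values[hod == 3], c(65, 65))
  # amplitude 0: constant at the MESOR
  p0 <- tibble::tibble(participant_id = "X", mesor = 62, amplitude = 0,
                       acrophase = 0)
  expect_true(all(generate_heart_rate(p0, cfg)$values == 62))
  # physiological clipping and missingness
  cfg2 <- cohort_config(n_participants = 1, study_days = 2,
                        hr = list(noise_sd = 80, missing_frac = 0.1))
  set.seed(2)
  hr2 <- generate_heart_rate(p, cfg2)
  v <- hr2$values[!is.na(hr2$values)]
  expect_true(all(v >= 30 & v <= 220))
  expect_gt(mean(is.na(hr2$values)), 0.05)
  expect_lt(mean(is.na(hr2$values)), 0.15)
})

test_that("cumulative steps reset daily and telescope to daily totals", {
  cfg <- cohort_config(n_participants = 1, study_days = 3, seed = 12,
                       steps = list(missing_frac = 0))
  p <- tibble::tibble(participant_id = "X")
  set.seed(12)
  st <- generate_steps_cumulative(p, cfg)
  vals <- st$values
  day <- rep(1:3, each = 288)
  for (d in 1:3) {
    within <- vals[day == d]
    expect_true(all(diff(within) >= 0))
  }
  inc <- difference_cumulative(st)$values
  for (d in 1:3) {
    expect_equal(sum(inc[day == d]), vals[day == d][288])
  }
  # day rates beat night rates on average (activity rhythm present)
  hod <- epoch_hours(st) %% 24
  expect_gt(mean(inc[hod >= 9 & hod < 18]), mean(inc[hod < 6]))
  # a constant-rate noise-free configuration gives an arithmetic ramp
  cfg_flat <- cohort_config(
    n_participants = 1, study_days = 2,
    steps = list(log_rate_mean = log(20), log_rate_amp = 0, sdlog = 0,
                 active_logit_base = 50, active_logit_amp = 0,
                 missing_frac = 0)
  )
  ramp <- generate_steps_cumulative(p, cfg_flat)$values
  expect_equal(ramp[1:288], 20 * (1:288))
  expect_equal(ramp[289:576], 20 * (1:288))
})

test_that("questionnaire ratings stay within instrument ranges", {
  cfg <- cohort_config(n_participants = 40, study_days = 2, seed = 77)
  q <- generate_cohort(cfg, streams = "questionnaires")$questionnaires
  info <- instrument_info()
  for (inst in info$instrument) {
    ratings <- q$rating[q$instrument == inst]
    row <- info[info$instrument == inst, ]
    expect_length(ratings, 40 * row$n_items)
    expect_true(all(ratings >= row$item_min & ratings <= row$item_max))
  }
})

test_that("configured scale gradients are recovered in group means", {
  cfg <- cohort_config(seed = 19)
  cohort <- generate_cohort(cfg, streams = "questionnaires")
  scored <- score_cohort_questionnaires(cohort$questionnaires)
  dbas <- scored[scored$instrument == "DBAS", ]
  dbas <- dplyr::left_join(dbas, cohort$truth, by = "participant_id")
  got <- tapply(dbas$total, factor(dbas$group, levels = c(
    "no_insomnia", "mild", "moderate", "severe")), mean)
  target <- 65.17 + cfg$effect_profile$dbas
  n_g <- c(63, 106, 69, 12)
  se <- cfg$scales$dbas$sd / sqrt(n_g)
  expect_true(all(abs(got - target) < 2 * se + 1))
  # an all-zero profile removes the gradient by construction
  flat_profile <- lapply(default_effect_profile(), function(x) x * 0)
  cfg_flat <- cohort_config(seed = 19, effect_profile = flat_profile)
  expect_true(all(vapply(cfg_flat$effect_profile, function(x) all(x == 0),
                         logical(1))))
})

test_that("EMA logs respect slots, kinds, and per-day uniqueness", {
  cfg <- cohort_config(n_participants = 30, study_days = 14, seed = 8)
  ema <- generate_cohort(cfg, streams = "ema")$ema
  expect_true(all(ema$kind %in% c("caffeine", "alcohol", "nap", "stress")))
  expect_true(all(ema$slot %in% c("morning", "afternoon", "before_bedtime")))
  expect_true(all(ema$category[ema$kind == "nap"] %in%
                    c("<1h", "1-2h", "2-3h", ">3h")))
  expect_true(all(ema$category[ema$kind == "stress"] %in%
                    c("mild", "moderate", "severe")))
  expect_true(all(ema$magnitude[ema$kind %in% c("caffeine", "alcohol")] > 0))
  # at most one entry per participant x kind x day
  dup <- ema |>
    dplyr::count(participant_id, date, kind) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
  # probability-zero kinds vanish and aggregate to zero downstream
  cfg0 <- cohort_config(
    n_participants = 10, study_days = 7, seed = 3,
    ema = list(caffeine = list(prob = 0), alcohol = list(prob = 0),
               nap = list(prob = 0), stress = list(prob = 0))
  )
  cohort0 <- generate_cohort(cfg0, streams = "ema")
  expect_equal(nrow(cohort0$ema), 0)
  feats <- ema_features(cohort0$ema, 7,
                        participant_ids = cohort0$participants$participant_id)
  expect_true(all(feats$caffeine == 0 & feats$stress == 0))
})

test_that("weighted stress rises with configured severity", {
  cfg <- cohort_config(n_participants = 200, study_days = 28, seed = 25)
  cohort <- generate_cohort(cfg, streams = "ema")
  feats <- ema_features(cohort$ema, 28,
                        participant_ids = cohort$participants$participant_id)
  feats <- dplyr::left_join(feats, cohort$truth, by = "participant_id")
  med <- tapply(feats$stress, factor(feats$group, levels = c(
    "no_insomnia", "mild", "moderate", "severe")), stats::median)
  expect_true(all(diff(med) >= 0))
  expect_gt(med[["severe"]], med[["no_insomnia"]])
})

test_that("analysis stages run without the truth sidecar", {
  cfg <- small_config()
  cohort <- generate_cohort(cfg, streams = c("sleep", "questionnaires",
                                             "ema"))
  cohort$truth <- NULL
  feats <- cohort_features(cohort)
  expect_equal(nrow(feats), cfg$n_participants)
  expect_true("group" %in% names(feats))
})
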