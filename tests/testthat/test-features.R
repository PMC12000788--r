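test_that("sample_entropy handles anchors and matches the oracle", {
  expect_equal(sample_entropy(rep(5, 60)), 0)           # constant: A == B
  expect_true(is.na(sample_entropy(c(1, 2, 3))))        # shorter than m + 2

  x <- rep(c(1, 2), 4)
  expect_equal(sample_entropy(x, m = 2, r = 0.5),
               oracle_sampen(x, m = 2, r = 0.5))

  set.seed(41)
  for (rep in 1:60) {
    n <- sample(20:60, 1)
    x <- round(rnorm(n), 2)
    r <- runif(1, 0.1, 0.5)
    expect_equal(sample_entropy(x, m = 2, r = r),
                 oracle_sampen(x, m = 2, r = r), tolerance = 1e-12)
  }
})

test_that("segment_duration_entropy matches anchors and the oracle", {
  z <- segment_duration_entropy(rep(0L, 1440))
  expect_equal(unname(z["entropy_non_step"]), 0)   # one stationary segment
  expect_equal(unname(z["entropy_step"]), 0)       # no active segments

  # active durations {3, 3, 5}: H = -(2/3 log 2/3 + 1/3 log 1/3)
  steps <- c(1, 1, 1, 0, 1, 1, 1, 0, 0, 1, 1, 1, 1, 1)
  expect_equal(unname(segment_duration_entropy(steps)["entropy_step"]),
               0.636514, tolerance = 1e-5)

  # equal-duration segments of any count -> 0
  eq <- rep(c(1, 1, 0, 0), 10)
  expect_equal(unname(segment_duration_entropy(eq)["entropy_step"]), 0)

  expect_true(all(is.na(segment_duration_entropy(integer(0)))))

  set.seed(42)
  for (rep in 1:60) {
    s <- rbinom(sample(50:200, 1), 1, runif(1, 0.2, 0.8)) *
      rpois(1, 5)
    expect_equal(segment_duration_entropy(s), oracle_segment_entropy(s),
                 tolerance = 1e-12)
  }
})

test_that("daily_features picks the longest period as main sleep", {
  parts <- data.table::data.table(id = "P1", hospital = "H1",
                                  enroll_order = 1L,
                                  start_date = as.Date("2025-01-01"),
                                  study_days = 2L)
  sp <- data.table::data.table(
    participant = "P1",
    start = ts_utc(c("2025-01-01 23:30:00", "2025-01-01 20:30:00")),
    end = ts_utc(c("2025-01-02 06:30:00", "2025-01-01 22:00:00")),
    duration_min = c(420, 90), efficiency = c(0.95, 0.9))
  ms <- data.table::data.table(participant = "P1",
                               date = as.Date("2025-01-02"),
                               main_sleep_start = NA_character_,
                               main_sleep_end = NA_character_,
                               caffeine_amount = 1L,
                               caffeine_last_time = "2025-01-01 20:00:00",
                               bath_time = NA_character_)
  co <- list(participants = parts, sleep_periods = sp, morning_survey = ms,
             evening_survey = data.table::data.table(
               participant = character(), date = as.Date(character()),
               work_seq = character()))
  df <- daily_features(co)
  expect_equal(df[date == as.Date("2025-01-02"), sleep_duration_min], 420)
  # caffeine at 20:00, onset 23:30 -> 210 min (and 180 when intake at 20:30)
  expect_equal(df[date == as.Date("2025-01-02"), caffeine_to_sleep_min], 210)
})

test_that("missing surveys propagate as missing fields, record retained", {
  co <- tiny_cohort()
  df <- tiny_daily()
  all_days <- sum(co$participants$study_days)
  expect_equal(nrow(df), all_days)  # one row per participant-day, always
  missing_eve <- df[!co$evening_survey, on = c("participant", "date")]
  expect_true(nrow(missing_eve) > 0)
  expect_true(all(is.na(missing_eve$stress)))
  expect_true(all(is.na(missing_eve$work_total_h)))
})

test_that("duplicate survey rows keep the last and warn", {
  co <- tiny_cohort()
  co2 <- co
  dup <- data.table::copy(co$morning_survey[1])
  dup[, brightness_sleep := 99L]
  co2$morning_survey <- rbind(co$morning_survey, dup)
  expect_warning(df <- daily_features(co2), "duplicate")
  expect_equal(df[co$morning_survey[1, .(participant, date)],
                  on = c("participant", "date")]$brightness_sleep, 99L)
})

test_that("advice samples aggregate 4-day windows with sample SD", {
  df <- tiny_daily()
  co <- tiny_cohort()
  s <- assemble_advice_samples(df, co$advice)
  expect_true(nrow(s) > 0)
  # verify one sample's mean/sd against direct computation
  r1 <- s[1]
  win <- df[participant == r1$participant & date >= r1$date - 4 &
              date < r1$date]
  expect_equal(nrow(win), 4L)
  expect_equal(r1$brightness_sleep_mean, mean(win$brightness_sleep))
  expect_equal(r1$brightness_sleep_sd, sd(win$brightness_sleep))
  # closed form: {1,2,3,4} -> mean 2.5, sample SD 1.2910
  expect_equal(sd(1:4), 1.2909944, tolerance = 1e-6)
  # no missing values anywhere in retained samples
  expect_false(anyNA(advice_feature_matrix(s)))
  # labels hold 1..5 positives
  labs <- as.matrix(s[, paste0("label_", 1:23), with = FALSE])
  expect_true(all(rowSums(labs) >= 1 & rowSums(labs) <= 5))
})

test_that("windows with missing values are excluded", {
  df <- data.table::copy(tiny_daily())
  co <- tiny_cohort()
  s0 <- assemble_advice_samples(df, co$advice)
  # blank one brightness value inside the first sample's window
  tgt <- s0[1]
  df[participant == tgt$participant & date == tgt$date - 2,
     brightness_sleep := NA]
  s1 <- assemble_advice_samples(df, co$advice)
  expect_equal(nrow(s1), nrow(s0) - 1L)
  expect_equal(nrow(s1[participant == tgt$participant & date == tgt$date]), 0L)
})

test_that("advice dates without 4 prior days are dropped with a warning", {
  df <- tiny_daily()
  adv <- data.table::data.table(participant = df$participant[1],
                                date = df$date[2],
                                message_ids = list(20L),
                                response = "eager")
  expect_warning(expect_error(assemble_advice_samples(df, adv), "survived"),
                 "prior days")
})

test_that("response features encode the latest response, 0 when never", {
  co_full <- simulate_cohort(
    cohort_config(n_participants = 2L,
                  missingness = list(morning = 0, evening = 0, wearable = 0)),
    seed = 77L,
    tables = c("participants", "sleep_periods", "morning_survey",
               "evening_survey"))
  df <- daily_features(co_full)
  pid <- df$participant[1]
  dts <- sort(df[participant == pid & date >= min(date) + 8, date])
  adv <- data.table::data.table(
    participant = pid, date = dts[c(1, 3, 5)],
    message_ids = list(c(20L), c(20L, 4L), c(7L)),
    response = c("eager", "difficult", "none"))
  s <- assemble_advice_samples(df, adv)
  first <- s[date == dts[1]]
  expect_equal(nrow(first), 1L)
  expect_equal(first$resp_msg_20, 0)   # never advised before
  third <- s[date == dts[5]]
  expect_equal(nrow(third), 1L)
  expect_equal(third$resp_msg_20, -1)  # latest piece containing 20: difficult
  expect_equal(third$resp_msg_4, -1)
  expect_equal(third$resp_msg_7, 0)
})

test_that("feature extraction is pure: identical inputs, identical outputs", {
  co <- tiny_cohort()
  expect_identical(daily_features(co), daily_features(co))
})
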