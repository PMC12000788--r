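test_that("configuration errors name the offending field", {
  expect_error(cohort_config(study_days = 7L, baseline_days = 7L),
               "study_days")
  sm <- default_sleep_model()
  sm$dur_sd[3] <- -1
  expect_error(cohort_config(sleep_model = sm), "dur_sd")
  tm <- default_shift_transition(); tm[1, 1] <- 0.9
  expect_error(cohort_config(shift_transition = tm), "summing to 1")
  expect_error(cohort_config(missingness = list(morning = 1.2, evening = 0,
                                                wearable = 0)),
               "missingness")
  expect_error(cohort_config(regularity = 0), "regularity")
})

test_that("same seed gives byte-identical cohorts, distinct seeds differ", {
  co1 <- simulate_cohort(cohort_config(n_participants = 3L), seed = 5,
                         tables = c("participants", "sleep_periods",
                                    "morning_survey", "evening_survey",
                                    "advice"))
  co2 <- simulate_cohort(cohort_config(n_participants = 3L), seed = 5,
                         tables = c("participants", "sleep_periods",
                                    "morning_survey", "evening_survey",
                                    "advice"))
  d1 <- file.path(tempdir(), "c1"); d2 <- file.path(tempdir(), "c2")
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  co3 <- simulate_cohort(cohort_config(n_participants = 3L), seed = 6,
                         tables = c("participants", "sleep_periods",
                                    "morning_survey", "evening_survey",
                                    "advice"))
  expect_false(identical(co1$advice$message_ids, co3$advice$message_ids))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("default scale matches the study footprint within 5%", {
  cfg <- cohort_config()
  n_days <- cfg$n_participants * cfg$study_days
  expect_equal(n_days, 2135)
  expect_lt(abs(n_days - 2123) / 2123, 0.05)
})

test_that("advice only occurs after the baseline week, about 13 per person", {
  co <- tiny_cohort(n = 8L, seed = 11L)
  adv <- merge(co$advice, co$participants[, .(participant = id, start_date)],
               by = "participant")
  expect_true(all(adv$date > adv$start_date + 7))
  per <- adv[, .N, by = participant]
  expect_gt(mean(per$N), 9)
  expect_lt(mean(per$N), 17)
  expect_true(all(vapply(co$advice$message_ids, length, integer(1)) %in% 1:5))
  expect_true(all(unlist(co$advice$message_ids) %in% 1:23))
})

test_that("shift-context sleep draws hit the short and long regimes", {
  cfg <- cohort_config()
  dm <- shift_context_sleep("day", "midnight", cfg, n = 10000L)
  expect_equal(mean(dm$duration_min), 220, tolerance = 0.02)
  od <- shift_context_sleep("off", "day", cfg, n = 10000L)
  expect_equal(mean(od$duration_min), 408, tolerance = 0.02)
  expect_true(all(dm$duration_min > 0))
  expect_true(all(od$duration_min > 0))
  # onset = wake - duration and wake before the midnight shift start
  expect_true(all(dm$wake_min <= 0))
  expect_equal(dm$onset_min, dm$wake_min - dm$duration_min)
})

test_that("apply_policy respects set-size bounds, fallback and errors", {
  windows <- data.table::data.table(
    participant = "P1", date = as.Date("2025-01-10") + 0:99,
    brightness_sleep_mean = 60, brightness_sleep_sd = 5,
    phone_use_min_mean = 100, phone_use_min_sd = 10,
    sleep_duration_min_mean = 200, sleep_duration_min_sd = 30,
    caffeine_amount_sd = 3, caffeine_amount_mean = 3,
    sleep_satisfy_mean = 1.2, sleep_satisfy_sd = 0.5,
    work_p3_h_sd = 4.6, work_p3_h_mean = 4)
  expect_error(apply_policy(windows, list()), "empty")

  # extreme window: many rules fire, still at most 5 selected
  adv <- apply_policy(windows, default_policy(), seed = 2)
  expect_true(all(vapply(adv$message_ids, length, integer(1)) <= 5))
  # the high-brightness rule leads the firing order
  expect_gt(mean(vapply(adv$message_ids, function(s) 7L %in% s, logical(1))),
            0.7)

  # all-zero policy except a fallback: every event carries exactly it
  pol <- list(policy_rule(4L, "phone_use_min_mean", ">", 1e6, 1, 0, 0),
              policy_rule(20L, fallback = TRUE))
  adv0 <- apply_policy(windows, pol, seed = 3)
  expect_true(all(vapply(adv0$message_ids, identical, logical(1), 20L)))

  # unknown feature is an error naming the rule
  expect_error(apply_policy(windows[, .(participant, date)],
                            default_policy(), seed = 1),
               "brightness_sleep_mean")
})

test_that("default policy marginals approximate the study frequencies", {
  # pool advice across several cohorts for a stable estimate
  logs <- lapply(1:3, function(s)
    simulate_cohort(cohort_config(n_participants = 40L), seed = 100L + s,
                    tables = c("participants", "sleep_periods",
                               "morning_survey", "evening_survey",
                               "advice"))$advice)
  st <- advice_statistics(data.table::rbindlist(logs))
  expect_gt(st$n_pieces, 1000)
  prop <- function(m) st$messages[message_id == m, prop_pieces]
  expect_equal(prop(20L), 0.496, tolerance = 0.12)
  expect_equal(prop(21L), 0.281, tolerance = 0.15)
  # minor modelled messages: negative:positive ratios in the 5-15 band
  for (m in c(4L, 12L, 14L, 15L)) {
    ratio <- (1 - prop(m)) / prop(m)
    expect_gt(ratio, 5); expect_lt(ratio, 15)
  }
})

test_that("cohort calibration matches the population anchors at n >= 2000", {
  co <- simulate_cohort(cohort_config(), seed = 2024L,
                        tables = c("participants", "sleep_periods",
                                   "morning_survey", "evening_survey"))
  df <- daily_features(co)
  expect_gte(nrow(df), 2000L)

  # participant-clustered standard error of a mean
  cluster_se <- function(x, g) {
    ok <- !is.na(x)
    pm <- tapply(x[ok], g[ok], mean)
    sd(pm) / sqrt(length(pm))
  }
  dur <- df$sleep_duration_min
  expect_lt(abs(mean(dur, na.rm = TRUE) - 406.46),
            2 * cluster_se(dur, df$participant))
  s7 <- df$sri_7
  expect_lt(abs(mean(s7, na.rm = TRUE) - 52.02),
            2 * cluster_se(s7, df$participant))
  # scale-bounded survey fields respect their instruments
  expect_true(all(df$brightness_sleep >= 1 & df$brightness_sleep <= 100,
                  na.rm = TRUE))
  expect_true(all(df$sleep_satisfy %in% 1:5 | is.na(df$sleep_satisfy)))
  expect_true(all(df$sleepiness_morn %in% 1:9 | is.na(df$sleepiness_morn)))
})

test_that("responses reflect the per-message response model extremes", {
  logs <- lapply(1:2, function(s)
    simulate_cohort(cohort_config(n_participants = 40L), seed = 200L + s,
                    tables = c("participants", "sleep_periods",
                               "morning_survey", "evening_survey",
                               "advice"))$advice)
  st <- advice_statistics(data.table::rbindlist(logs))
  r20 <- st$responses[message_id == 20L]
  r4 <- st$responses[message_id == 4L]
  expect_lt(r20$difficult_rate, 0.06)
  expect_gt(r4$difficult_rate, 0.10)
  expect_gt(r4$difficult_rate, r20$difficult_rate)
})
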