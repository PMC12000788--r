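#' Cohort simulation configuration
#'
#' Encodes the stated world of the synthetic shift-worker cohort: two
#' hospitals, a 5-week protocol whose first week is an advice-free
#' baseline, rotating off/day/afternoon/midnight shifts driven by a
#' first-order Markov chain, shift-context-conditioned main sleep (short
#' evening sleep before a midnight shift that follows a day shift, long
#' sleep on off-then-day days), morning/evening surveys, a rule-based
#' physician advice policy, and per-table missingness. Population-level
#' defaults (sleep duration, activity, heart rate, regularity) are
#' calibrated once against the study-scale summary statistics and frozen.
#'
#' Truncated-normal sleep-duration locations are solved at construction
#' time so that the realized per-context means equal the configured
#' targets despite the lower bound at `dur_min` minutes.
#'
#' @param n_participants number of participants (default 61).
#' @param n_hospitals hospitals; participants are assigned roughly 77/23.
#' @param study_days days per participant (default 35).
#' @param baseline_days advice-free run-in days (default 7).
#' @param advice_per_week mean advice events per week after baseline
#'   (default 3.25, about 13 events per participant).
#' @param advice_count_sd between-participant SD of the advice-event count
#'   (the study reports extreme imbalance but no magnitude; default 2).
#' @param shift_transition 4x4 row-stochastic matrix over
#'   off/day/afternoon/midnight; the default rotation is calibrated so the
#'   stationary shift shares reproduce the observed per-period work hours.
#' @param sleep_model per-(prev, cur)-context sleep table; see Details.
#' @param regularity global multiplier (> 0) on wake-time jitter; the main
#'   knob calibrating the 7-day sleep regularity index mean.
#' @param missingness named list `morning`, `evening`, `wearable` of
#'   per-day Bernoulli drop probabilities.
#' @param policy list of [policy_rule()]s (default [default_policy()]).
#' @param response_model see [default_response_model()].
#' @param seed default seed used by [simulate_cohort()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 61L,
                          n_hospitals = 2L,
                          study_days = 35L,
                          baseline_days = 7L,
                          advice_per_week = 3.25,
                          advice_count_sd = 2,
                          shift_transition = default_shift_transition(),
                          sleep_model = default_sleep_model(),
                          regularity = 1.45,
                          missingness = list(morning = 0.10, evening = 0.10,
                                             wearable = 0.05),
                          policy = default_policy(),
                          response_model = default_response_model(),
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_hospitals = as.integer(n_hospitals),
    study_days = as.integer(study_days),
    baseline_days = as.integer(baseline_days),
    advice_per_week = advice_per_week,
    advice_count_sd = advice_count_sd,
    shift_states = c("off", "day", "afternoon", "midnight"),
    shift_transition = shift_transition,
    sleep_model = copy(as.data.table(sleep_model)),
    regularity = regularity,
    nap_model = list(recovery_prob = 0.80, recovery_dur = 300,
                     recovery_sd = 90, recovery_min = 60,
                     other_rate = 0.52, other_dur = 40, other_sd = 22,
                     other_min = 10),
    behavior_model = list(
      caffeine_rate = 1.53, alcohol_any = 0.20, alcohol_extra = 0.5,
      phone_meanlog = log(26), phone_sdlog = 0.55, phone_part_sd = 0.45,
      brightness_high_prob = 0.25, brightness_low_mean = 8,
      brightness_high_mean = 46, brightness_high_sd = 14,
      brightness_day_sd = 6,
      bath_prob = 0.80, extrawork_prob = 0.495,
      wake_mode_probs = c(natural = 0.42, alarm = 0.467, other = 0.113)),
    hr_model = list(mean = 74.87, part_sd = 7.0, day_sd = 3.3,
                    circadian_amp = 4.5, sleep_dip = 7, ar_phi = 0.985,
                    ar_sd = 12.4),
    steps_model = list(daily_mean = 7545, active_prob = 0.33,
                       mult_sdlog = 0.60, hour_sdlog = 0.9),
    wellbeing_model = default_wellbeing_model(),
    missingness = missingness,
    policy = policy,
    response_model = response_model,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  # solve truncated-normal locations for the configured duration targets
  set(cfg$sleep_model, j = "dur_mu",
      value = mapply(.solve_trunc_mu, cfg$sleep_model$dur_mean,
                     cfg$sleep_model$dur_sd, cfg$sleep_model$dur_min))
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d participants x %d days ",
                     "(%d baseline), seed %d\n"),
              x$n_participants, x$study_days, x$baseline_days, x$seed))
  invisible(x)
}

validate_cohort_config <- function(cfg) {
  if (cfg$study_days <= cfg$baseline_days)
    stop("configuration error: study_days must exceed baseline_days")
  tm <- cfg$shift_transition
  if (!is.matrix(tm) || any(dim(tm) != 4L))
    stop("configuration error: shift_transition must be 4x4")
  if (any(tm < 0) || any(tm > 1) || any(abs(rowSums(tm) - 1) > 1e-8))
    stop("configuration error: shift_transition rows must be probabilities summing to 1")
  for (fld in c("dur_sd", "wake_sd"))
    if (any(cfg$sleep_model[[fld]] < 0))
      stop("configuration error: negative SD in sleep_model$", fld)
  mp <- unlist(cfg$missingness)
  if (any(mp < 0 | mp > 1))
    stop("configuration error: missingness probabilities must be in [0,1]")
  if (cfg$regularity <= 0)
    stop("configuration error: regularity must be positive")
  if (cfg$hr_model$ar_sd < 0 || cfg$steps_model$daily_mean < 0)
    stop("configuration error: negative scale in hr_model/steps_model")
  invisible(cfg)
}

# location mu such that E[max-truncated normal] hits the target mean
.solve_trunc_mu <- function(target, sd, lower) {
  if (sd <= 0) return(target)
  f <- function(mu) truncnorm::etruncnorm(a = lower, mean = mu, sd = sd) - target
  stats::uniroot(f, c(target - 4 * sd, target + sd))$root
}

#' Default shift rotation matrix
#'
#' First-order Markov chain over off/day/afternoon/midnight, biased toward
#' clockwise rotation (day to afternoon to midnight to off) and forbidding
#' the physically impossible afternoon-to-midnight hand-off (the shifts
#' abut at midnight). Calibrated so the stationary distribution matches
#' the observed mean work hours per shift period (approximately
#' off 0.30 / day 0.27 / afternoon 0.24 / midnight 0.19).
#'
#' @return 4x4 row-stochastic matrix.
#' @export
default_shift_transition <- function() {
  m <- matrix(c(
    # to:  off     day     aft     mid
    0.562, 0.204, 0.102, 0.132,   # from off
    0.090, 0.586, 0.132, 0.192,   # from day
    0.180, 0.132, 0.688, 0.000,   # from afternoon
    0.348, 0.072, 0.060, 0.520),  # from midnight
    nrow = 4L, byrow = TRUE)
  dimnames(m) <- list(c("off", "day", "afternoon", "midnight"),
                      c("off", "day", "afternoon", "midnight"))
  m
}

#' Default shift-conditioned sleep model
#'
#' One row per (previous shift, current shift) context: target mean and SD
#' of main-sleep duration (minutes, truncated below at `dur_min`) and the
#' wake-time anchor (minutes relative to the current day's midnight;
#' negative values are the previous evening). Sleep onset is derived as
#' wake minus duration, reflecting wake times pinned by shift starts.
#' Day-shift-then-midnight-shift days draw from the short-sleep regime
#' (about 220 minutes); off-then-day days from the long regime (about
#' 400 minutes).
#'
#' @return `data.table` with columns `prev`, `cur`, `dur_mean`, `dur_sd`,
#'   `dur_min`, `wake_mean`, `wake_sd`.
#' @export
default_sleep_model <- function() {
  rbindlist(list(
    # cur = day: wake before the 08:00 shift start
    list("off", "day", 408, 155, 90, 410, 22),
    list("day", "day", 392, 150, 90, 405, 20),
    list("afternoon", "day", 380, 145, 90, 415, 18),
    list("midnight", "day", 392, 155, 90, 405, 22),
    # cur = afternoon: shift starts 16:00, later wake
    list("off", "afternoon", 462, 160, 90, 462, 35),
    list("day", "afternoon", 449, 158, 90, 455, 32),
    list("afternoon", "afternoon", 457, 155, 90, 465, 33),
    list("midnight", "afternoon", 449, 160, 90, 458, 34),
    # cur = midnight: evening sleep before the 00:00 shift start
    list("off", "midnight", 290, 110, 60, -38, 16),
    list("day", "midnight", 220, 58, 60, -40, 14),
    list("afternoon", "midnight", 210, 75, 60, -45, 14),
    list("midnight", "midnight", 235, 90, 60, -42, 15),
    # cur = off: no constraint but capped at 07:55 wake
    list("off", "off", 485, 165, 90, 440, 42),
    list("day", "off", 475, 162, 90, 435, 40),
    list("afternoon", "off", 462, 160, 90, 452, 40),
    list("midnight", "off", 465, 165, 90, 430, 42)),
    use.names = FALSE)[, setNames(.SD, c("prev", "cur", "dur_mean", "dur_sd",
                                         "dur_min", "wake_mean", "wake_sd"))][
    , .(prev, cur, dur_mean, dur_sd, dur_min, wake_mean, wake_sd,
        wake_max = ifelse(cur == "midnight", -5, 475))]
}

default_wellbeing_model <- function() {
  # target mean, total SD split into participant/day parts, and effect
  # loadings (short-sleep shortfall in SDs of duration; midnight shift)
  list(
    morn100 = data.table(
      metric = c("alertness_morn", "happiness_morn", "energy_morn",
                 "health_morn", "calmness_morn"),
      target = c(41, 52.99, 44.02, 51.71, 55.97),
      part_sd = c(13, 10, 12, 11, 11), day_sd = c(17, 13, 16, 13, 13),
      k_sleep = c(14, 8, 13, 8, 8), k_mid = c(6, 4, 6, 4, 5)),
    eve100 = data.table(
      metric = c("alertness_eve", "happiness_eve", "energy_eve",
                 "health_eve", "calmness_eve"),
      target = c(41.08, 54.27, 45.88, 52.4, 56.85),
      part_sd = c(12, 10, 12, 11, 11), day_sd = c(16, 14, 16, 13, 14),
      k_sleep = c(10, 6, 10, 6, 6), k_mid = c(5, 3, 5, 3, 4)),
    likert = data.table(
      metric = c("sleepiness_daytime", "stress", "tiredness"),
      target = c(2.59, 2.93, 2.51), sd = c(1.15, 1.0, 0.95),
      k_sleep = c(0.45, 0.2, 0.4), k_work = c(0.1, 0.35, 0.3)),
    sleep_quality = data.table(
      metric = c("deep_sleep", "immediate_sleep", "fatigue_recover",
                 "mid_awake", "sleep_satisfy"),
      target = c(3.2, 3.55, 2.84, 3.2, 2.85), sd = c(1.0, 1.0, 0.95,
                                                     1.2, 0.9),
      k_sleep = c(0.5, 0.25, 0.55, 0.3, 0.55), k_mid = c(0.35, 0.1, 0.35,
                                                         0.15, 0.35)),
    sleepiness_morn = list(target = 5.49, sd = 1.85, k_sleep = 0.7,
                           k_mid = 1.0),
    sleepiness_eve = list(target = 5.7, sd = 1.70, k_sleep = 0.5,
                          k_work = 0.4))
}

#' Sample shift-conditioned sleep
#'
#' Draws main-sleep duration and onset for a (previous shift, current
#' shift) context: durations from the context's truncated normal (never
#' negative), wake times from the context anchor with jitter scaled by
#' `config$regularity`, onset = wake - duration (minutes relative to the
#' current day's midnight).
#'
#' @param prev,cur shift states among off/day/afternoon/midnight.
#' @param config a [cohort_config()].
#' @param n number of draws.
#' @return `data.table` with `duration_min`, `onset_min`, `wake_min`.
#' @export
shift_context_sleep <- function(prev, cur, config = cohort_config(), n = 1L) {
  stopifnot(prev %in% config$shift_states, cur %in% config$shift_states)
  sm <- config$sleep_model
  mask <- sm[["prev"]] == prev & sm[["cur"]] == cur
  row <- as.list(sm[mask, ])
  dur <- truncnorm::rtruncnorm(n, a = row$dur_min, mean = row$dur_mu,
                               sd = row$dur_sd)
  # longer-than-typical sleeps extend the wake as well as the onset, so
  # duration variability only half-loads onto schedule irregularity
  wake <- pmin(stats::rnorm(n, row$wake_mean,
                            row$wake_sd * config$regularity) +
                 0.5 * (dur - row$dur_mean), row$wake_max)
  data.table(duration_min = dur, onset_min = wake - dur, wake_min = wake)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.likert <- function(x, lo, hi) as.integer(.clamp(round(x), lo, hi))

#' Simulate a synthetic shift-worker cohort
#'
#' Generates every external-interface table of the data model:
#' `participants`, minute-level `minutes` (heart rate, steps),
#' wearable `sleep_periods`, `morning_survey`, `evening_survey` and the
#' `advice` log produced by the configured physician policy on 4-day
#' aggregated feature windows (advice only after the baseline week).
#' Identical seeds yield identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param tables subset of tables to generate; skipping `"minutes"` makes
#'   large simulations much faster when only sleep/survey structure is
#'   needed.
#' @return a list of `data.table`s (class `cohort`) with attributes
#'   `config` and `seed`; also carries `truth`, the internal noise-free
#'   daily table the policy saw.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed,
                            tables = c("participants", "minutes",
                                       "sleep_periods", "morning_survey",
                                       "evening_survey", "advice")) {
  validate_cohort_config(config)
  tables <- match.arg(tables, several.ok = TRUE,
                      choices = c("participants", "minutes", "sleep_periods",
                                  "morning_survey", "evening_survey", "advice"))
  n <- config$n_participants
  participants <- data.table(
    id = sprintf("P%03d", seq_len(n)),
    hospital = ifelse(seq_len(n) <= ceiling(0.77 * n), "H1", "H2"),
    enroll_order = seq_len(n),
    start_date = as.Date("2025-06-02") + 2L * (seq_len(n) - 1L),
    study_days = config$study_days)

  per <- vector("list", n)
  for (p in seq_len(n))
    per[[p]] <- .simulate_participant(config, participants$id[p],
                                      participants$start_date[p],
                                      child_seed(seed, p), tables)

  truth <- rbindlist(lapply(per, `[[`, "truth"))
  cohort <- list(participants = participants)
  for (tb in c("minutes", "sleep_periods", "morning_survey", "evening_survey"))
    if (tb %in% tables)
      cohort[[tb]] <- rbindlist(lapply(per, `[[`, tb), fill = TRUE)

  if ("advice" %in% tables) {
    windows <- rbindlist(lapply(per, `[[`, "windows"))
    cohort$advice <- if (nrow(windows))
      apply_policy(windows, config$policy, config$response_model,
                   seed = child_seed(seed, 7919L))
    else data.table(participant = character(), date = as.Date(character()),
                    message_ids = list(), response = character())
  }

  cohort <- .apply_missingness(cohort, config, seed)
  structure(cohort, class = c("cohort", "list"),
            config = config, seed = seed, truth = truth)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>\n")
  for (nm in names(x))
    cat(sprintf("  %-15s %8d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

.simulate_participant <- function(cfg, pid, start_date, seed, tables) {
  set.seed(seed)
  nd <- cfg$study_days
  dates <- seq(start_date, by = "day", length.out = nd)
  states <- cfg$shift_states
  tm <- cfg$shift_transition

  # stationary start two days before enrolment (the first evening survey
  # self-reports pre-study work days), then first-order rotation
  pi0 <- .stationary_distribution(tm)
  shifts <- character(nd + 2L)
  shifts[1L] <- sample(states, 1L, prob = pi0)
  for (d in seq_len(nd + 1L))
    shifts[d + 1L] <- sample(states, 1L, prob = tm[shifts[d], ])
  prev2 <- shifts[seq_len(nd)]
  prev <- shifts[seq_len(nd) + 1L]
  cur <- shifts[seq_len(nd) + 2L]

  sm <- cfg$sleep_model
  ctx <- match(paste(prev, cur), paste(sm$prev, sm$cur))
  dur <- truncnorm::rtruncnorm(nd, a = sm$dur_min[ctx], mean = sm$dur_mu[ctx],
                               sd = sm$dur_sd[ctx])
  wake <- pmin(stats::rnorm(nd, sm$wake_mean[ctx],
                            sm$wake_sd[ctx] * cfg$regularity) +
                 0.5 * (dur - sm$dur_mean[ctx]), sm$wake_max[ctx])
  onset <- wake - dur
  midnights <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  main_start <- midnights + onset * 60
  main_end <- midnights + wake * 60

  # naps: long recovery nap after a midnight shift (previous day), plus
  # occasional short afternoon naps; reported on the current day's survey
  nm <- cfg$nap_model
  has_recovery <- prev == "midnight" & stats::runif(nd) < nm$recovery_prob
  rec_start <- midnights - 1440 * 60 + (570 + stats::rnorm(nd, 0, 45)) * 60
  rec_dur <- truncnorm::rtruncnorm(nd, a = nm$recovery_min,
                                   mean = nm$recovery_dur, sd = nm$recovery_sd)
  n_other <- stats::rpois(nd, nm$other_rate)
  oth_start <- midnights - 1440 * 60 + stats::runif(nd, 780, 1110) * 60
  oth_dur <- truncnorm::rtruncnorm(nd, a = nm$other_min, mean = nm$other_dur,
                                   sd = nm$other_sd)

  # behaviour
  bm <- cfg$behavior_model
  bright_base <- if (stats::runif(1) < bm$brightness_high_prob)
    stats::rnorm(1, bm$brightness_high_mean, bm$brightness_high_sd)
  else stats::rexp(1, 1 / bm$brightness_low_mean)
  brightness <- .likert(bright_base + stats::rnorm(nd, 0, bm$brightness_day_sd),
                        1L, 100L)
  phone_meanlog <- bm$phone_meanlog + stats::rnorm(1, 0, bm$phone_part_sd)
  phone_use <- round(stats::rlnorm(nd, phone_meanlog, bm$phone_sdlog))
  caffeine <- stats::rpois(nd, bm$caffeine_rate)
  alcohol <- ifelse(stats::runif(nd) < bm$alcohol_any,
                    1L + stats::rpois(nd, bm$alcohol_extra), 0L)
  caffeine_last <- main_start - 60 *
    truncnorm::rtruncnorm(nd, a = 30, mean = 420, sd = 150)
  caffeine_last[caffeine == 0L] <- NA
  bath <- main_start - 60 * truncnorm::rtruncnorm(nd, a = 10, mean = 75, sd = 40)
  bath[stats::runif(nd) >= bm$bath_prob] <- NA
  wake_mode <- sample(names(bm$wake_mode_probs), nd, replace = TRUE,
                      prob = bm$wake_mode_probs)
  time_to_sleep <- round(stats::rlnorm(nd, log(14), 0.7))
  extrawork <- as.integer(stats::runif(nd) < bm$extrawork_prob)

  # shift-dependent well-being
  shortfall <- pmax(0, (406.46 - dur) / 172)
  is_mid <- as.numeric(cur == "midnight")
  worked <- as.numeric(cur != "off")
  wb <- cfg$wellbeing_model
  z_part <- stats::rnorm(1)
  survey_scores <- list()
  for (blk in c("morn100", "eve100")) {
    tab <- wb[[blk]]
    for (k in seq_len(nrow(tab))) {
      base <- tab$target[k] + tab$k_sleep[k] * 0.47 + tab$k_mid[k] * 0.19
      x <- base + tab$part_sd[k] * z_part + stats::rnorm(nd, 0, tab$day_sd[k]) -
        tab$k_sleep[k] * shortfall - tab$k_mid[k] * is_mid
      survey_scores[[tab$metric[k]]] <- .likert(x, 1L, 100L)
    }
  }
  for (k in seq_len(nrow(wb$likert))) {
    tab <- wb$likert
    base <- tab$target[k] + tab$k_sleep[k] * 0.47 - tab$k_work[k] * 0.70
    x <- base + stats::rnorm(nd, 0, tab$sd[k]) - tab$k_sleep[k] * shortfall +
      tab$k_work[k] * worked
    survey_scores[[tab$metric[k]]] <- .likert(x, 1L, 5L)
  }
  sq <- list()
  for (k in seq_len(nrow(wb$sleep_quality))) {
    tab <- wb$sleep_quality
    base <- tab$target[k] + tab$k_sleep[k] * 0.47 + tab$k_mid[k] * 0.19
    x <- base + stats::rnorm(nd, 0, tab$sd[k]) - tab$k_sleep[k] * shortfall -
      tab$k_mid[k] * is_mid
    sq[[tab$metric[k]]] <- .likert(x, 1L, 5L)
  }
  sleepiness_morn <- .likert(
    wb$sleepiness_morn$target - wb$sleepiness_morn$k_sleep * 0.47 -
      wb$sleepiness_morn$k_mid * 0.19 +
      stats::rnorm(nd, 0, wb$sleepiness_morn$sd) +
      wb$sleepiness_morn$k_sleep * shortfall +
      wb$sleepiness_morn$k_mid * is_mid, 1L, 9L)
  sleepiness_eve <- .likert(
    wb$sleepiness_eve$target - wb$sleepiness_eve$k_sleep * 0.47 -
      wb$sleepiness_eve$k_work * 0.70 +
      stats::rnorm(nd, 0, wb$sleepiness_eve$sd) +
      wb$sleepiness_eve$k_sleep * shortfall +
      wb$sleepiness_eve$k_work * worked, 1L, 9L)

  # work-hour truth per period (8-h blocks, occasional overtime)
  work_p1 <- 8 * (cur == "midnight")
  work_p2 <- 8 * (cur == "day")
  work_p3 <- 8 * (cur == "afternoon")
  overtime <- (cur != "off") & (stats::runif(nd) < 0.20)
  ot_bins <- sample(1:3, nd, replace = TRUE)
  work_p2 <- work_p2 + ifelse(overtime & cur == "midnight", 0.5 * ot_bins, 0)
  work_p3 <- work_p3 + ifelse(overtime & cur == "day", 0.5 * ot_bins, 0)
  # afternoon overtime would cross midnight; push into period 3 cap
  work_p3 <- pmin(work_p3 + ifelse(overtime & cur == "afternoon",
                                   0, 0), 8)

  truth <- data.table(
    participant = pid, date = dates, day_index = seq_len(nd),
    prev_shift = prev, shift = cur,
    sleep_duration_min = dur, sleep_onset_min = onset, sleep_wake_min = wake,
    brightness_sleep = brightness, phone_use_min = phone_use,
    caffeine_amount = caffeine, alcohol_amount = alcohol,
    sleep_satisfy = sq$sleep_satisfy,
    work_p1_h = work_p1, work_p2_h = work_p2, work_p3_h = work_p3,
    work_total_h = work_p1 + work_p2 + work_p3)

  # advice windows: mean/SD of the policy-visible features over the 4
  # previous days, for sampled advice dates after the baseline week
  n_events <- round(stats::rnorm(1, cfg$advice_per_week *
                                   (cfg$study_days - cfg$baseline_days) / 7,
                                 cfg$advice_count_sd))
  n_events <- max(4L, min(n_events, cfg$study_days - cfg$baseline_days - 2L))
  cand <- (cfg$baseline_days + 2L):cfg$study_days
  advice_days <- sort(sample(cand, min(n_events, length(cand))))
  pol_feats <- c("brightness_sleep", "phone_use_min", "sleep_duration_min",
                 "caffeine_amount", "sleep_satisfy", "work_p3_h")
  windows <- rbindlist(lapply(advice_days, function(d) {
    win <- truth[day_index >= d - 4L & day_index < d]
    stats_row <- lapply(pol_feats, function(f)
      list(mean(win[[f]]), stats::sd(win[[f]])))
    out <- data.table(participant = pid, date = dates[d])
    for (k in seq_along(pol_feats)) {
      out[[paste0(pol_feats[k], "_mean")]] <- stats_row[[k]][[1L]]
      out[[paste0(pol_feats[k], "_sd")]] <- stats_row[[k]][[2L]]
    }
    out
  }))

  # ------- emitted tables -------
  res <- list(truth = truth, windows = windows)

  # wearable sleep records: main sleep (slightly noisy) + long naps
  wr <- data.table(participant = pid,
                   start = main_start + 60 * round(stats::rnorm(nd, 0, 4)),
                   end = main_end + 60 * round(stats::rnorm(nd, 0, 4)),
                   efficiency = round(.clamp(stats::rnorm(nd, 0.93, 0.04),
                                             0.6, 0.99), 3))
  wr[, duration_min := as.numeric(difftime(end, start, units = "mins"))]
  rec <- data.table(participant = pid,
                    start = rec_start[has_recovery],
                    end = (rec_start + rec_dur * 60)[has_recovery],
                    efficiency = round(.clamp(
                      stats::rnorm(sum(has_recovery), 0.90, 0.05), 0.6, 0.99), 3))
  if (nrow(rec))
    rec[, duration_min := as.numeric(difftime(end, start, units = "mins"))]
  res$sleep_periods <- rbind(wr, rec, fill = TRUE)[order(start)]

  fmt_t <- function(x) x  # POSIXct kept in memory; CSV writer formats
  res$morning_survey <- data.table(
    participant = pid, date = dates,
    main_sleep_start = fmt_t(main_start), main_sleep_end = fmt_t(main_end),
    nap1_start = fmt_t(replace(rec_start, !has_recovery, NA)),
    nap1_end = fmt_t(replace(rec_start + rec_dur * 60, !has_recovery, NA)),
    nap2_start = fmt_t(replace(oth_start, n_other == 0L, NA)),
    nap2_end = fmt_t(replace(oth_start + oth_dur * 60, n_other == 0L, NA)),
    sleep_prev_24 = as.integer(stats::runif(nd) < 0.998),
    wake_mode = wake_mode, time_to_sleep_min = time_to_sleep,
    phone_use_min = phone_use, brightness_sleep = brightness,
    deep_sleep = sq$deep_sleep, immediate_sleep = sq$immediate_sleep,
    fatigue_recover = sq$fatigue_recover, mid_awake = sq$mid_awake,
    sleep_satisfy = sq$sleep_satisfy,
    alcohol_amount = alcohol, caffeine_amount = caffeine,
    caffeine_last_time = fmt_t(caffeine_last), bath_time = fmt_t(bath),
    sleepiness_morn = sleepiness_morn,
    alertness_morn = survey_scores$alertness_morn,
    happiness_morn = survey_scores$happiness_morn,
    energy_morn = survey_scores$energy_morn,
    health_morn = survey_scores$health_morn,
    calmness_morn = survey_scores$calmness_morn)

  wseq <- .work_seq_string(cur, overtime, ot_bins)
  wseq_prev <- .work_seq_string(prev, c(FALSE, overtime[-nd]),
                                c(1L, ot_bins[-nd]))
  wseq_prev2 <- .work_seq_string(prev2, c(FALSE, FALSE, overtime[seq_len(nd - 2L)]),
                                 c(1L, 1L, ot_bins[seq_len(nd - 2L)]))
  res$evening_survey <- data.table(
    participant = pid, date = dates,
    work_seq = wseq, work_seq_yday = wseq_prev, work_seq_2d = wseq_prev2,
    extrawork_activities = extrawork,
    sleepiness_eve = sleepiness_eve,
    sleepiness_daytime = survey_scores$sleepiness_daytime,
    stress = survey_scores$stress, tiredness = survey_scores$tiredness,
    alertness_eve = survey_scores$alertness_eve,
    happiness_eve = survey_scores$happiness_eve,
    energy_eve = survey_scores$energy_eve,
    health_eve = survey_scores$health_eve,
    calmness_eve = survey_scores$calmness_eve)

  if ("minutes" %in% tables)
    res$minutes <- .simulate_minutes(cfg, pid, dates, main_start, main_end,
                                     rec_start, rec_dur, has_recovery,
                                     oth_start, oth_dur, n_other, cur)
  res
}

.stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

.work_seq_string <- function(cur, overtime, ot_bins) {
  n <- length(cur)
  out <- character(n)
  for (i in seq_len(n)) {
    bits <- integer(48L)
    rng <- switch(cur[i], midnight = 1:16, day = 17:32, afternoon = 33:48,
                  off = integer())
    bits[rng] <- 1L
    if (overtime[i] && cur[i] != "off") {
      ext <- (max(rng) + 1L):(max(rng) + ot_bins[i])
      ext <- ext[ext <= 48L]
      bits[ext] <- 1L
    }
    out[i] <- paste(bits, collapse = "")
  }
  out
}

.simulate_minutes <- function(cfg, pid, dates, main_start, main_end,
                              rec_start, rec_dur, has_recovery,
                              oth_start, oth_dur, n_other, cur) {
  nd <- length(dates)
  n_min <- nd * 1440L
  origin <- as.POSIXct(paste(dates[1L], "00:00:00"), tz = "UTC")
  asleep <- logical(n_min)
  mark <- function(s, e) {
    i0 <- max(0L, floor(as.numeric(difftime(s, origin, units = "mins"))))
    i1 <- min(n_min, ceiling(as.numeric(difftime(e, origin, units = "mins"))))
    if (i1 > i0) asleep[(i0 + 1L):i1] <<- TRUE
  }
  for (d in seq_len(nd)) {
    mark(main_start[d], main_end[d])
    if (has_recovery[d]) mark(rec_start[d], rec_start[d] + rec_dur[d] * 60)
    if (n_other[d] > 0L) mark(oth_start[d], oth_start[d] + oth_dur[d] * 60)
  }

  hm <- cfg$hr_model
  base <- hm$mean + 0.95 + stats::rnorm(1, 0, hm$part_sd)
  day_eff <- rep(stats::rnorm(nd, 0, hm$day_sd), each = 1440L)
  clock <- rep(seq_len(1440L) - 1L, nd)
  circ <- hm$circadian_amp * sin(2 * pi * (clock - 600) / 1440)
  innov_sd <- hm$ar_sd * sqrt(1 - hm$ar_phi^2)
  noise <- stats::filter(stats::rnorm(n_min, 0, innov_sd), hm$ar_phi,
                         method = "recursive")
  hr <- round(.clamp(base + day_eff + circ - hm$sleep_dip * asleep +
                       as.numeric(noise), 35, 185))

  smod <- cfg$steps_model
  lambda0 <- smod$daily_mean /
    (880 * smod$active_prob * exp(smod$mult_sdlog^2 / 2))
  mult <- rep(stats::rlnorm(nd, 0, smod$mult_sdlog), each = 1440L)
  # hourly activity level varies (commutes, ward rounds, rest), which
  # spreads the walking-bout run-length distribution
  hour_mult <- rep(stats::rlnorm(nd * 24L, -smod$hour_sdlog^2 / 2,
                                 smod$hour_sdlog), each = 60L)
  p_act <- pmin(smod$active_prob * hour_mult, 0.95)
  active <- !asleep & stats::runif(n_min) < p_act
  steps <- integer(n_min)
  steps[active] <- stats::rpois(sum(active), lambda0 * mult[active])

  data.table(participant = pid,
             timestamp = origin + 60 * (seq_len(n_min) - 1L),
             heart_rate = as.numeric(hr), steps = steps)
}

.apply_missingness <- function(cohort, cfg, seed) {
  set.seed(child_seed(seed, 4242L))
  mp <- cfg$missingness
  drop_rows <- function(tab, p) {
    if (is.null(tab) || !nrow(tab) || p <= 0) return(tab)
    tab[stats::runif(nrow(tab)) >= p]
  }
  cohort$morning_survey <- drop_rows(cohort$morning_survey, mp$morning %||% 0)
  cohort$evening_survey <- drop_rows(cohort$evening_survey, mp$evening %||% 0)
  pw <- mp$wearable %||% 0
  if (pw > 0 && !is.null(cohort$sleep_periods)) {
    # whole wearable-days drop: both the sleep records reported that day
    # and the matching minute stream
    sp <- cohort$sleep_periods
    sp[, date := .sleep_report_day(end)]
    keys <- unique(sp[, .(participant, date)])
    keys[, drop := stats::runif(.N) < pw]
    sp <- keys[sp, on = c("participant", "date")][drop != TRUE | is.na(drop)]
    cohort$sleep_periods <- sp[, .(participant, start, end, duration_min,
                                   efficiency)]
    if (!is.null(cohort$minutes)) {
      mn <- cohort$minutes
      mn[, date := as.Date(timestamp, tz = "UTC")]
      mn <- keys[mn, on = c("participant", "date")][drop != TRUE | is.na(drop)]
      cohort$minutes <- mn[, .(participant, timestamp, heart_rate, steps)]
    }
  }
  cohort
}
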