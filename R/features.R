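#' Sample entropy of a numeric series
#'
#' `SampEn(m, r) = -ln(A/B)` where `B` counts pairs of length-`m` templates
#' within Chebyshev tolerance `r` (self-matches excluded) and `A` counts
#' the same for length `m + 1`. Low values indicate a self-similar series.
#' Gaps (`NA`) are dropped before matching. A constant series scores 0
#' (`A = B`); when no length-`m` template pairs match (`B = 0`) or the
#' series is shorter than `m + 2`, the value is missing.
#'
#' @param x numeric series (e.g. one day of per-minute heart rate).
#' @param m template length; default 2, the cardiovascular-series
#'   convention.
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return nonnegative scalar, possibly `Inf` or `NA`.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < m + 2L) return(NA_real_)
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (is.na(r)) return(NA_real_)
  .sample_entropy_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

#' Duration entropies of active and stationary segments
#'
#' Splits a day of per-minute step counts into maximal runs with steps
#' (`active`) and without (`stationary`), then computes the Shannon
#' entropy (nats) of each class's segment-duration distribution:
#' `H = -sum p_k log p_k` with `p_k` the fraction of that class's segments
#' lasting `k` minutes. A class with zero or one segment, or whose
#' segments all share one duration, scores 0. Missing minutes are treated
#' as stationary so the run structure is preserved.
#'
#' @param steps integer per-minute step counts for one day.
#' @return named numeric vector `c(entropy_step, entropy_non_step)`;
#'   both `NA` for an empty series.
#' @export
segment_duration_entropy <- function(steps) {
  if (!length(steps)) return(c(entropy_step = NA_real_, entropy_non_step = NA_real_))
  active <- !is.na(steps) & steps > 0
  runs <- rle(as.logical(active))
  h <- function(durations) {
    if (length(durations) < 2L) return(0)
    p <- table(durations) / length(durations)
    -sum(p * log(p))
  }
  c(entropy_step = h(runs$lengths[runs$values]),
    entropy_non_step = h(runs$lengths[!runs$values]))
}

# Daily feature columns that are structurally optional (undefined on days
# without the triggering activity); excluded from clustering and, by
# default, from model samples so the missing-window exclusion rule only
# reacts to genuinely absent data.
optional_daily_features <- function() {
  c("sri_3", "sri_5", "sri_7", "nap_during_work_min",
    "caffeine_to_sleep_min", "bath_to_sleep_min",
    "gap_sleep_to_shift_min", "gap_shift_to_sleep_min")
}

# Well-being / sleep-quality columns (withheld from clustering input).
wellbeing_features <- function() {
  c("deep_sleep", "immediate_sleep", "fatigue_recover", "mid_awake",
    "sleep_satisfy",
    "sleepiness_morn", "alertness_morn", "happiness_morn", "energy_morn",
    "health_morn", "calmness_morn",
    "sleepiness_eve", "alertness_eve", "happiness_eve", "energy_eve",
    "health_eve", "calmness_eve", "sleepiness_daytime", "stress", "tiredness")
}

.parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

.mins_since_midnight <- function(t) {
  as.integer(format(t, "%H")) * 60L + as.integer(format(t, "%M"))
}

# Survey sleep periods (main + naps) for one participant, long format.
.survey_periods <- function(ms) {
  mk <- function(s, e, nap) data.table(date = ms$date, start = .parse_time(s),
                                       end = .parse_time(e), is_nap = nap)
  out <- rbind(mk(ms$main_sleep_start, ms$main_sleep_end, FALSE),
               if ("nap1_start" %in% names(ms)) mk(ms$nap1_start, ms$nap1_end, TRUE),
               if ("nap2_start" %in% names(ms)) mk(ms$nap2_start, ms$nap2_end, TRUE))
  out[!(is.na(start) & is.na(end))]
}

.dedup_survey <- function(x, label) {
  if (anyDuplicated(x, by = c("participant", "date"))) {
    warning("duplicate ", label, " rows per participant-day; keeping last")
    x <- x[, .SD[.N], by = .(participant, date)]
  }
  x
}

#' Daily engineered feature records
#'
#' Assembles the per participant-day feature inventory: wearable
#' physiology (heart-rate mean/SD/sample entropy, steps,
#' segment-duration entropies), main sleep and naps (survey first,
#' wearable fallback), the sleep regularity index over 3/5/7-day trailing
#' windows, behaviour (caffeine, alcohol, bath and phone use, with
#' time-to-sleep gaps), work hours per period for today / yesterday / the
#' day before, sleep-work overlaps and gaps, and morning/evening
#' well-being scores. Fields whose source data are absent are explicitly
#' missing, never imputed.
#'
#' @param cohort a cohort list as produced by [simulate_cohort()] or
#'   [read_cohort()]: tables `participants`, `minutes`, `sleep_periods`,
#'   `morning_survey`, `evening_survey`.
#' @return `data.table`, one row per participant-day.
#' @export
daily_features <- function(cohort) {
  parts <- as.data.table(cohort$participants)
  ms <- .dedup_survey(as.data.table(cohort$morning_survey), "morning survey")
  es <- .dedup_survey(as.data.table(cohort$evening_survey), "evening survey")
  sp <- as.data.table(cohort$sleep_periods)
  sp[, `:=`(start = .parse_time(start), end = .parse_time(end))]
  minutes <- if (!is.null(cohort$minutes)) as.data.table(cohort$minutes) else NULL

  out <- vector("list", nrow(parts))
  for (pi in seq_len(nrow(parts))) {
    pid <- parts$id[pi]
    dates <- seq(as.Date(parts$start_date[pi]), by = "day",
                 length.out = parts$study_days[pi])
    base <- data.table(participant = pid, date = dates)

    p_ms <- ms[participant == pid]
    p_es <- es[participant == pid]
    p_sp <- sp[participant == pid]

    # --- sleep sequence, SRI, main sleep -------------------------------
    sv_periods <- if (nrow(p_ms)) .survey_periods(p_ms) else
      data.table(date = as.Date(character()), start = .parse_time(character()),
                 end = .parse_time(character()), is_nap = logical())
    grid <- build_sleep_sequence(sv_periods, p_sp[, .(start, end)],
                                 dates = dates, participant = pid)
    sri_tabs <- lapply(c(3L, 5L, 7L), function(w)
      setNames(sri(grid, w)[, .(date, sri)], c("date", paste0("sri_", w))))
    for (tab in sri_tabs) base <- tab[base, on = "date"]

    main <- .main_sleep_by_day(sv_periods, p_sp, dates)
    base <- main[base, on = "date"]

    nap <- .nap_minutes_by_day(sv_periods, dates)
    # nap fields are only observed on days with a morning survey
    surveyed <- dates %in% p_ms$date
    nap[!surveyed, c("nap_count", "nap_duration_min") := NA]
    base <- nap[base, on = "date"]

    # --- wearable minute streams ---------------------------------------
    if (!is.null(minutes)) {
      p_min <- minutes[participant == pid]
      if (nrow(p_min)) {
        p_min[, date := as.Date(.parse_time(timestamp), tz = "UTC")]
        phys <- p_min[, {
          hr <- heart_rate[!is.na(heart_rate)]
          ent <- segment_duration_entropy(steps)
          .(hr_mean = if (length(hr)) mean(hr) else NA_real_,
            hr_std = if (length(hr) > 1L) stats::sd(hr) else NA_real_,
            hr_entropy = sample_entropy(hr),
            steps = sum(steps, na.rm = TRUE),
            duration_entropy_step = ent[["entropy_step"]],
            duration_entropy_non_step = ent[["entropy_non_step"]])
        }, by = date]
        base <- phys[base, on = "date"]
      }
    }

    # --- work sequences -------------------------------------------------
    if (nrow(p_es)) {
      aligned <- p_es[base[, .(date)], on = "date"]
      wgrid <- build_work_sequence(aligned$work_seq, dates, pid)
      wf <- work_features(wgrid)[, -"participant"]
      base <- wf[base, on = "date"]
      ov <- sleep_work_overlap(grid, wgrid)[, -"participant"]
      base <- ov[base, on = "date"]
      # lagged work hours come from the same evening survey, which
      # self-reports yesterday and the day before
      for (lag in c("yday", "2d")) {
        col <- paste0("work_seq_", lag)
        if (!col %in% names(aligned)) next
        lw <- .work_hours_from_seq(aligned[[col]])
        setnames(lw, paste0(names(lw), "_", lag))
        base <- cbind(base, lw)
      }
    }

    # --- survey scalars -------------------------------------------------
    ms_keep <- setdiff(names(p_ms), c("participant", "main_sleep_start",
                                      "main_sleep_end", "nap1_start", "nap1_end",
                                      "nap2_start", "nap2_end"))
    if (nrow(p_ms)) base <- p_ms[, ..ms_keep][base, on = "date"]
    es_keep <- setdiff(names(p_es), c("participant", "work_seq"))
    if (nrow(p_es)) base <- p_es[, ..es_keep][base, on = "date"]

    if ("wake_mode" %in% names(base)) {
      base[, wake_natural := as.integer(wake_mode == "natural")]
      base[, wake_alarm := as.integer(wake_mode == "alarm")]
      base[, wake_other := as.integer(wake_mode == "other")]
      base[, wake_mode := NULL]
    }

    # behaviour-to-sleep gaps: minutes from last intake / bath to the next
    # main-sleep onset (missing when the activity did not occur)
    onsets <- sort(main$main_sleep_start[!is.na(main$main_sleep_start)])
    base[, caffeine_to_sleep_min := .gap_to_next_onset(
      if ("caffeine_last_time" %in% names(base)) .parse_time(caffeine_last_time) else
        .parse_time(rep(NA_character_, .N)), onsets)]
    base[, bath_to_sleep_min := .gap_to_next_onset(
      if ("bath_time" %in% names(base)) .parse_time(bath_time) else
        .parse_time(rep(NA_character_, .N)), onsets)]
    base[, c("caffeine_last_time", "bath_time") := NULL]

    # clock encodings of the main sleep period
    base[, main_sleep_onset_min := .mins_since_midnight(main_sleep_start)]
    base[, main_sleep_wake_min := .mins_since_midnight(main_sleep_end)]
    base[, c("main_sleep_start", "main_sleep_end") := NULL]
    out[[pi]] <- base
  }
  res <- rbindlist(out, use.names = TRUE, fill = TRUE)
  setcolorder(res, c("participant", "date"))
  setkey(res, participant, date)
  res[]
}

# Main sleep per reporting day: survey-reported period if present, else the
# longest wearable period assigned to the day (end date; late-evening ends
# roll to the next day). Duration in minutes; efficiency only known for
# wearable-backed periods.
.main_sleep_by_day <- function(sv_periods, wearable, dates) {
  res <- data.table(date = dates,
                    main_sleep_start = .parse_time(rep(NA_character_, length(dates))),
                    main_sleep_end = .parse_time(rep(NA_character_, length(dates))),
                    sleep_duration_min = NA_real_,
                    sleep_efficiency = NA_real_)
  wr <- copy(wearable)
  if (nrow(wr)) wr[, rday := .sleep_report_day(end)]
  sv_main <- sv_periods[!is.na(start) & !is.na(end) & !is_nap & end > start]
  for (i in seq_along(dates)) {
    d <- dates[i]
    row <- sv_main[date == d]
    if (nrow(row)) {
      k <- which.max(as.numeric(difftime(row$end, row$start, units = "mins")))
      set(res, i, "main_sleep_start", row$start[k])
      set(res, i, "main_sleep_end", row$end[k])
    } else if (nrow(wr) && any(wr$rday == d)) {
      cand <- wr[rday == d]
      k <- which.max(as.numeric(difftime(cand$end, cand$start, units = "mins")))
      set(res, i, "main_sleep_start", cand$start[k])
      set(res, i, "main_sleep_end", cand$end[k])
      if ("efficiency" %in% names(cand))
        set(res, i, "sleep_efficiency", cand$efficiency[k])
    }
  }
  res[, sleep_duration_min :=
        as.numeric(difftime(main_sleep_end, main_sleep_start, units = "mins"))]
  # wearable efficiency for survey-backed periods when a matching record exists
  if (nrow(wr) && "efficiency" %in% names(wr)) {
    for (i in which(is.na(res$sleep_efficiency) & !is.na(res$sleep_duration_min))) {
      cand <- wr[rday == res$date[i]]
      if (nrow(cand)) {
        k <- which.max(as.numeric(difftime(cand$end, cand$start, units = "mins")))
        set(res, i, "sleep_efficiency", cand$efficiency[k])
      }
    }
  }
  res
}

# Nap minutes attributed to the calendar day containing them; nap_count is
# the number of reported nap periods on the reporting day.
.nap_minutes_by_day <- function(sv_periods, dates) {
  res <- data.table(date = dates, nap_count = 0, nap_duration_min = 0)
  naps <- sv_periods[is_nap == TRUE & !is.na(start) & !is.na(end) & end > start]
  if (!nrow(naps)) return(res)
  cnt <- naps[, .N, by = date]
  res[cnt, nap_count := i.N, on = "date"]
  for (k in seq_len(nrow(naps))) {
    s <- naps$start[k]; e <- naps$end[k]
    repeat {
      day_end <- as.POSIXct(paste(as.Date(s, tz = "UTC") + 1L, "00:00:00"), tz = "UTC")
      seg_end <- min(e, day_end)
      i <- match(as.Date(s, tz = "UTC"), res$date)
      if (!is.na(i))
        set(res, i, "nap_duration_min", res$nap_duration_min[i] +
              as.numeric(difftime(seg_end, s, units = "mins")))
      if (seg_end >= e) break
      s <- day_end
    }
  }
  res
}

# period work hours from 48-character 30-min binary strings
.work_hours_from_seq <- function(seqs) {
  n <- length(seqs)
  out <- data.table(work_total_h = rep(NA_real_, n), work_p1_h = NA_real_,
                    work_p2_h = NA_real_, work_p3_h = NA_real_)
  ok <- !is.na(seqs) & nchar(seqs) == 48L
  if (any(ok)) {
    bits <- t(vapply(strsplit(seqs[ok], ""),
                     function(ch) as.integer(ch), integer(48L)))
    out[ok, `:=`(work_p1_h = rowSums(bits[, 1:16, drop = FALSE]) * 0.5,
                 work_p2_h = rowSums(bits[, 17:32, drop = FALSE]) * 0.5,
                 work_p3_h = rowSums(bits[, 33:48, drop = FALSE]) * 0.5)]
    out[ok, work_total_h := work_p1_h + work_p2_h + work_p3_h]
  }
  out
}

.gap_to_next_onset <- function(times, onsets, max_gap = 36 * 60) {
  vapply(seq_along(times), function(i) {
    t <- times[i]
    if (is.na(t) || !length(onsets)) return(NA_real_)
    nxt <- onsets[onsets >= t]
    if (!length(nxt)) return(NA_real_)
    g <- as.numeric(difftime(nxt[1L], t, units = "mins"))
    if (g > max_gap) NA_real_ else g
  }, numeric(1))
}

#' Assemble model-ready advice samples
#'
#' For each advice event, aggregates every retained daily feature over the
#' 4 calendar days strictly preceding the advice date as window mean and
#' sample SD (denominator `n - 1`), appends 23 response features (the most
#' recent response to an earlier advice piece containing each message:
#' `+1` eager, `-1` difficult, `0` no response or never advised), and the
#' binary selection label per message. Any missing value inside the window
#' drops the sample; advice dates with fewer than 4 prior study days are
#' dropped with a warning.
#'
#' @param daily output of [daily_features()].
#' @param advice advice log: `participant`, `date`, `message_ids` (list or
#'   pipe-delimited string), `response` in `none|eager|difficult`.
#' @param window_days aggregation window length (default 4).
#' @param exclude_optional drop structurally-optional daily features (SRI,
#'   activity-conditional gaps) before aggregation so their absence does
#'   not trigger the exclusion rule; default `TRUE`.
#' @return `data.table`: `participant`, `date`, `<feature>_mean` /
#'   `<feature>_sd` columns, `resp_msg_1..23`, `label_1..23`.
#' @export
assemble_advice_samples <- function(daily, advice, window_days = 4L,
                                    exclude_optional = TRUE) {
  daily <- as.data.table(daily)
  advice <- as.data.table(advice)
  advice[, date := as.Date(date)]
  if (is.character(advice$message_ids))
    advice[, message_ids := lapply(strsplit(message_ids, "|", fixed = TRUE),
                                   as.integer)]
  setkey(advice, participant, date)

  feat_cols <- setdiff(names(daily), c("participant", "date"))
  feat_cols <- feat_cols[vapply(daily[, ..feat_cols], is.numeric, logical(1))]
  if (exclude_optional) feat_cols <- setdiff(feat_cols, optional_daily_features())

  n_dropped_window <- 0L
  rows <- vector("list", nrow(advice))
  for (i in seq_len(nrow(advice))) {
    pid <- advice$participant[i]
    d <- advice$date[i]
    win <- daily[participant == pid & date >= d - window_days & date < d]
    if (nrow(win) < window_days) { n_dropped_window <- n_dropped_window + 1L; next }
    vals <- as.matrix(win[, ..feat_cols])
    if (anyNA(vals)) next  # exclusion rule: missing values drop the sample
    mu <- colMeans(vals)
    sdv <- apply(vals, 2L, stats::sd)
    prev <- advice[participant == pid & date < d]
    resp <- vapply(1:23, function(m) {
      hits <- which(vapply(prev$message_ids, function(s) m %in% s, logical(1)))
      if (!length(hits)) return(0)
      switch(prev$response[max(hits)], eager = 1, difficult = -1, 0)
    }, numeric(1))
    lab <- as.integer(1:23 %in% advice$message_ids[[i]])
    rows[[i]] <- c(list(participant = pid, date = d),
                   setNames(as.list(mu), paste0(feat_cols, "_mean")),
                   setNames(as.list(sdv), paste0(feat_cols, "_sd")),
                   setNames(as.list(resp), paste0("resp_msg_", 1:23)),
                   setNames(as.list(lab), paste0("label_", 1:23)))
  }
  if (n_dropped_window)
    warning(n_dropped_window, " advice date(s) with <", window_days,
            " prior days dropped")
  res <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(res)) stop("no advice samples survived the exclusion rule")
  res[]
}

#' Feature matrix / label accessors for advice samples
#'
#' @param samples output of [assemble_advice_samples()].
#' @param message_id message whose labels to extract (for `advice_labels`).
#' @return `advice_feature_matrix`: numeric matrix of predictors;
#'   `advice_labels`: integer 0/1 vector.
#' @export
advice_feature_matrix <- function(samples) {
  cols <- setdiff(names(samples),
                  c("participant", "date", paste0("label_", 1:23)))
  as.matrix(as.data.table(samples)[, ..cols])
}

#' @rdname advice_feature_matrix
#' @export
advice_labels <- function(samples, message_id) {
  as.integer(samples[[paste0("label_", message_id)]])
}
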