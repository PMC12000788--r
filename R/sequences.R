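#' Binary day grid
#'
#' A per-participant matrix of binary states over contiguous calendar days:
#' one row per day, one column per within-day bin. Sleep/nap sequences use
#' 1-minute bins (1440 per day); self-reported work schedules use 30-minute
#' bins (48 per day). Days whose sleep report is absent or unusable are
#' flagged and excluded from window statistics rather than treated as
#' all-awake.
#'
#' @param bits integer/logical matrix, days x bins, values in {0, 1}.
#' @param dates contiguous `Date` vector, one per row.
#' @param resolution minutes per bin; `bins * resolution` must equal 1440.
#' @param participant participant identifier.
#' @param flagged logical per day; flagged days are skipped by [sri()].
#' @param provenance optional character per day (`"survey"`, `"wearable"`,
#'   `"none"`) recording the source of the day's main sleep period.
#' @return an object of class `day_grid`.
#' @export
day_grid <- function(bits, dates, resolution = 1L, participant = NA_character_,
                     flagged = rep(FALSE, nrow(bits)), provenance = NULL) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  if (ncol(bits) * resolution != 1440L)
    stop("bins per day x resolution must equal 1440, got ",
         ncol(bits), " x ", resolution)
  if (!all(bits %in% c(0L, 1L))) stop("grid bits must be strictly binary")
  dates <- as.Date(dates)
  if (length(dates) != nrow(bits)) stop("one date per grid row required")
  if (length(dates) > 1L && any(diff(dates) != 1L))
    stop("grid dates must be contiguous calendar days")
  structure(list(bits = bits, dates = dates, resolution = as.integer(resolution),
                 participant = participant, flagged = flagged,
                 provenance = provenance),
            class = "day_grid")
}

#' @export
print.day_grid <- function(x, ...) {
  cat(sprintf("<day_grid> participant=%s  %d days (%s..%s)  %d-min bins, %d flagged\n",
              x$participant, nrow(x$bits), min(x$dates), max(x$dates),
              x$resolution, sum(x$flagged)))
  invisible(x)
}

# Assign a sleep period to its reporting day: the calendar date of its end,
# except that periods ending in the late evening (>= 20:00) belong to the
# following morning's report (short pre-midnight-shift sleeps).
.sleep_report_day <- function(end) {
  d <- as.Date(end, tz = "UTC")
  d + (as.integer(format(end, "%H")) >= 20L)
}

.set_interval_bits <- function(bits, origin, start, end) {
  # bits is a flat minute vector starting at `origin` midnight
  s <- floor(as.numeric(difftime(start, origin, units = "mins")))
  e <- ceiling(as.numeric(difftime(end, origin, units = "mins")))
  s <- max(s, 0L); e <- min(e, length(bits))
  if (e > s) bits[(s + 1L):e] <- 1L
  bits
}

#' Build a 1-minute sleep/nap sequence for one participant
#'
#' Survey-reported main sleep and nap periods populate the grid; when a
#' day's survey main-sleep times are absent, the wearable's longest sleep
#' period for that day substitutes. Periods crossing midnight are split
#' across adjacent days by construction (the grid is indexed in absolute
#' minutes). Records whose end does not follow their start are rejected
#' with a warning and the day is flagged.
#'
#' @param survey_sleep `data.frame` with columns `date` (Date), `start`,
#'   `end` (POSIXct, may be `NA` when unreported) and `is_nap` (logical).
#' @param wearable_sleep `data.frame` with POSIXct columns `start`, `end`;
#'   used as main-sleep fallback only.
#' @param dates optional contiguous span of days for the grid; defaults to
#'   the range of days covered by the inputs.
#' @param participant identifier stored on the grid.
#' @return a [day_grid()] with 1-minute resolution, per-day `provenance`,
#'   and days without any main sleep flagged incomplete.
#' @export
build_sleep_sequence <- function(survey_sleep, wearable_sleep = NULL,
                                 dates = NULL, participant = NA_character_) {
  sv <- as.data.table(survey_sleep)
  if (!nrow(sv)) sv <- data.table(date = as.Date(character()),
                                  start = as.POSIXct(character(), tz = "UTC"),
                                  end = as.POSIXct(character(), tz = "UTC"),
                                  is_nap = logical())
  wr <- if (is.null(wearable_sleep)) NULL else as.data.table(wearable_sleep)
  if (is.null(dates)) {
    all_days <- c(sv$date,
                  if (!is.null(wr) && nrow(wr)) .sleep_report_day(wr$end))
    if (!length(all_days)) stop("no sleep records and no dates supplied")
    dates <- seq(min(all_days), max(all_days), by = "day")
  }
  dates <- as.Date(dates)
  n_days <- length(dates)
  origin <- as.POSIXct(paste(dates[1L], "00:00:00"), tz = "UTC")
  flat <- integer(n_days * 1440L)
  flagged <- rep(FALSE, n_days)
  provenance <- rep("none", n_days)

  bad <- !is.na(sv$start) & !is.na(sv$end) & sv$end <= sv$start
  if (any(bad)) {
    warning(sum(bad), " sleep record(s) with end <= start rejected")
    flagged[dates %in% sv$date[bad]] <- TRUE
    sv <- sv[!bad]
  }

  wr_day <- if (!is.null(wr) && nrow(wr)) .sleep_report_day(wr$end) else NULL
  for (i in seq_len(n_days)) {
    d <- dates[i]
    day_sv <- sv[sv$date == d]
    mains <- day_sv[!day_sv$is_nap & !is.na(day_sv$start) & !is.na(day_sv$end)]
    if (nrow(mains)) {
      provenance[i] <- "survey"
      for (k in seq_len(nrow(mains)))
        flat <- .set_interval_bits(flat, origin, mains$start[k], mains$end[k])
    } else if (!is.null(wr_day) && any(wr_day == d)) {
      cand <- wr[wr_day == d]
      dur <- as.numeric(difftime(cand$end, cand$start, units = "mins"))
      k <- which.max(dur)
      provenance[i] <- "wearable"
      flat <- .set_interval_bits(flat, origin, cand$start[k], cand$end[k])
    } else {
      flagged[i] <- TRUE
    }
    naps <- day_sv[day_sv$is_nap & !is.na(day_sv$start) & !is.na(day_sv$end)]
    if (nrow(naps))
      for (k in seq_len(nrow(naps)))
        flat <- .set_interval_bits(flat, origin, naps$start[k], naps$end[k])
  }
  bits <- matrix(flat, nrow = n_days, ncol = 1440L, byrow = TRUE)
  day_grid(bits, dates, 1L, participant, flagged, provenance)
}

# SRI of a complete window (matrix of days x 1440): linear rescale of the
# fraction of 24-h-apart minute pairs in the same state.
.sri_window <- function(bits) {
  n <- nrow(bits)
  agree <- bits[-1L, , drop = FALSE] == bits[-n, , drop = FALSE]
  -100 + 200 * mean(agree)
}

#' Sleep regularity index over trailing windows
#'
#' SRI over a window of `W` days is
#' `-100 + 200 / (1440 (W - 1)) * sum over consecutive-day pairs of
#' minute-state agreements`: +100 for identical schedules on all days,
#' -100 for schedules complemented every day. Windows are trailing
#' (anchored on their last day). A window containing a flagged day yields
#' `NA`, never 0.
#'
#' @param grid a 1-minute [day_grid()].
#' @param window window length in days (the study uses 3, 5 and 7).
#' @return `data.table` with columns `participant`, `date` (anchor),
#'   `window`, `sri`.
#' @export
sri <- function(grid, window = 7L) {
  stopifnot(inherits(grid, "day_grid"))
  if (grid$resolution != 1L) stop("SRI requires a 1-minute grid")
  window <- as.integer(window)
  if (window < 2L) stop("window must span at least 2 days")
  n <- nrow(grid$bits)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i < window) next
    idx <- (i - window + 1L):i
    if (any(grid$flagged[idx])) next
    vals[i] <- .sri_window(grid$bits[idx, , drop = FALSE])
  }
  data.table(participant = grid$participant, date = grid$dates,
             window = window, sri = vals)
}

#' Build the 30-minute work-schedule grid for one participant
#'
#' @param work_seq character vector of 48-character `0`/`1` strings, one
#'   per day (self-reported work schedule at 30-minute resolution).
#' @param dates contiguous `Date` vector matching `work_seq`.
#' @param participant identifier stored on the grid.
#' @return a [day_grid()] with 30-minute resolution; days with a missing
#'   sequence are flagged.
#' @export
build_work_sequence <- function(work_seq, dates, participant = NA_character_) {
  stopifnot(length(work_seq) == length(dates))
  flagged <- is.na(work_seq) | nchar(work_seq) != 48L
  bits <- matrix(0L, length(work_seq), 48L)
  for (i in which(!flagged))
    bits[i, ] <- as.integer(strsplit(work_seq[i], "")[[1L]])
  day_grid(bits, dates, 30L, participant, flagged)
}

#' Daily work hours, total and per shift period
#'
#' Periods partition the day into midnight-8AM (bins 1-16, midnight
#' shifts), 8AM-4PM (bins 17-32, day shifts) and 4PM-midnight (bins 33-48,
#' afternoon shifts). Each set bin contributes half an hour; the period
#' sums always reconstruct the total.
#'
#' @param grid a 30-minute [day_grid()].
#' @return `data.table` with `participant`, `date`, `work_total_h`,
#'   `work_p1_h`, `work_p2_h`, `work_p3_h` (`NA` on flagged days).
#' @export
work_features <- function(grid) {
  stopifnot(inherits(grid, "day_grid"))
  if (grid$resolution != 30L) stop("work features require a 30-minute grid")
  b <- grid$bits
  out <- data.table(
    participant = grid$participant, date = grid$dates,
    work_p1_h = rowSums(b[, 1:16, drop = FALSE]) * 0.5,
    work_p2_h = rowSums(b[, 17:32, drop = FALSE]) * 0.5,
    work_p3_h = rowSums(b[, 33:48, drop = FALSE]) * 0.5)
  out[, work_total_h := work_p1_h + work_p2_h + work_p3_h]
  for (col in c("work_p1_h", "work_p2_h", "work_p3_h", "work_total_h"))
    out[grid$flagged, (col) := NA_real_]
  setcolorder(out, c("participant", "date", "work_total_h",
                     "work_p1_h", "work_p2_h", "work_p3_h"))
  out[]
}

#' Sleep/work overlap and sleep-shift gaps
#'
#' Computes, per day: minutes asleep during work (naps on shift), the
#' minimum gap from the last sleep end to a shift start that day, and the
#' minimum gap from a shift end that day to the next sleep start. Gaps are
#' `NA` when the day has no shift edge or no adjacent sleep exists.
#'
#' @param sleep_grid 1-minute [day_grid()].
#' @param work_grid 30-minute [day_grid()] over the same dates.
#' @return `data.table` with `participant`, `date`, `nap_during_work_min`,
#'   `gap_sleep_to_shift_min`, `gap_shift_to_sleep_min`.
#' @export
sleep_work_overlap <- function(sleep_grid, work_grid) {
  stopifnot(inherits(sleep_grid, "day_grid"), inherits(work_grid, "day_grid"))
  if (!identical(sleep_grid$dates, work_grid$dates))
    stop("sleep and work grids cover different date ranges")
  n_days <- length(sleep_grid$dates)
  sleep <- as.integer(t(sleep_grid$bits))              # flat minutes
  work <- rep(as.integer(t(work_grid$bits)), each = 30L)

  both <- sleep & work
  overlap <- rowSums(matrix(both, nrow = n_days, byrow = TRUE))

  edges <- function(x) {
    d <- diff(c(0L, x, 0L))
    list(rise = which(d == 1L), fall = which(d == -1L) - 1L)  # minute idx
  }
  se <- edges(sleep); we <- edges(work)
  day_of <- function(minute) ((minute - 1L) %/% 1440L) + 1L

  gap_to_shift <- rep(NA_real_, n_days)
  for (m in we$rise) {
    prior_ends <- se$fall[se$fall < m]
    if (!length(prior_ends)) next
    d <- day_of(m)
    g <- m - max(prior_ends) - 1L
    gap_to_shift[d] <- min(gap_to_shift[d], g, na.rm = TRUE)
  }
  gap_to_sleep <- rep(NA_real_, n_days)
  for (m in we$fall) {
    next_starts <- se$rise[se$rise > m]
    if (!length(next_starts)) next
    d <- day_of(m)
    g <- min(next_starts) - m - 1L
    gap_to_sleep[d] <- min(gap_to_sleep[d], g, na.rm = TRUE)
  }
  data.table(participant = sleep_grid$participant, date = sleep_grid$dates,
             nap_during_work_min = as.numeric(overlap),
             gap_sleep_to_shift_min = gap_to_shift,
             gap_shift_to_sleep_min = gap_to_sleep)
}
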