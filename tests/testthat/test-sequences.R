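test_that("day_grid enforces its invariants", {
  bits <- matrix(0L, 2, 1440)
  expect_s3_class(day_grid(bits, as.Date("2025-01-01") + 0:1), "day_grid")
  expect_error(day_grid(matrix(0L, 2, 100), as.Date("2025-01-01") + 0:1),
               "1440")
  bad <- bits; bad[1, 1] <- 2L
  expect_error(day_grid(bad, as.Date("2025-01-01") + 0:1), "binary")
  expect_error(day_grid(bits, as.Date(c("2025-01-01", "2025-01-03"))),
               "contiguous")
})

test_that("build_sleep_sequence sets the reported minutes", {
  sv <- data.table::data.table(
    date = as.Date(c("2025-01-02", "2025-01-02")),
    start = ts_utc(c("2025-01-01 23:00:00", "2025-01-02 14:00:00")),
    end = ts_utc(c("2025-01-02 07:00:00", "2025-01-02 14:30:00")),
    is_nap = c(FALSE, TRUE))
  g <- build_sleep_sequence(sv, dates = as.Date("2025-01-01") + 0:1)
  expect_equal(sum(g$bits), 510L)  # 480-min main across midnight + 30-min nap
  expect_equal(sum(g$bits[1, ]), 60L)   # 23:00-24:00 on day 1
  expect_equal(sum(g$bits[2, ]), 450L)  # 00:00-07:00 + nap on day 2

  # wearable fallback when survey main-sleep times are absent
  wr <- data.table::data.table(start = ts_utc("2025-01-02 00:10:00"),
                               end = ts_utc("2025-01-02 06:10:00"))
  g2 <- build_sleep_sequence(sv[0], wr, dates = as.Date("2025-01-01") + 0:1)
  expect_equal(sum(g2$bits), 360L)
  expect_equal(g2$provenance[2], "wearable")

  # no sleep anywhere: all-zero flagged day
  g3 <- build_sleep_sequence(sv[0], dates = as.Date("2025-01-01") + 0:1)
  expect_true(all(g3$bits == 0L))
  expect_true(all(g3$flagged))

  # end <= start is rejected with a warning and the day flagged
  bad <- data.table::data.table(date = as.Date("2025-01-01"),
                                start = ts_utc("2025-01-01 08:00:00"),
                                end = ts_utc("2025-01-01 07:00:00"),
                                is_nap = FALSE)
  expect_warning(g4 <- build_sleep_sequence(bad,
                                            dates = as.Date("2025-01-01")),
                 "rejected")
  expect_true(g4$flagged[1])
})

test_that("sri reproduces its analytic anchors", {
  dates <- as.Date("2025-03-01") + 0:6
  bits <- matrix(0L, 7, 1440)
  bits[, c(1:420, 1381:1440)] <- 1L
  expect_equal(sri(day_grid(bits, dates), 7)$sri[7], 100)

  flip <- bits
  for (d in seq(2, 7, by = 2)) flip[d, ] <- 1L - flip[d, ]
  expect_equal(sri(day_grid(flip, dates), 7)$sri[7], -100)

  # W = 2 with exactly half the minutes agreeing -> 0
  half <- matrix(0L, 2, 1440)
  half[2, 1:720] <- 1L
  expect_equal(sri(day_grid(half, dates[1:2]), 2)$sri[2], 0)
})

test_that("sri is NA over flagged or incomplete windows, not zero", {
  dates <- as.Date("2025-03-01") + 0:6
  bits <- matrix(0L, 7, 1440); bits[, 1:400] <- 1L
  g <- day_grid(bits, dates, flagged = c(rep(FALSE, 3), TRUE, rep(FALSE, 3)))
  out <- sri(g, 3)
  expect_true(is.na(out$sri[2]))          # window not yet covered
  expect_true(is.na(out$sri[4]))          # flagged day inside window
  expect_true(is.na(out$sri[6]))
  expect_equal(out$sri[3], 100)
})

test_that("sri matches the 24-h-pair oracle on random grids", {
  set.seed(71)
  for (rep in 1:40) {
    nd <- sample(2:7, 1)
    # blocky random sleep patterns (runs, not iid bits)
    bits <- t(vapply(seq_len(nd), function(i) {
      v <- integer(1440)
      s <- sample(1440, 1); len <- sample(200:600, 1)
      v[((s + seq_len(len) - 1L) %% 1440L) + 1L] <- 1L
      v
    }, integer(1440)))
    g <- day_grid(bits, as.Date("2025-01-01") + seq_len(nd) - 1)
    expect_equal(sri(g, nd)$sri[nd], oracle_sri(bits), tolerance = 1e-12)
  }
})

test_that("sri is invariant to clock-origin rotation and global complement", {
  set.seed(72)
  bits <- t(vapply(1:5, function(i) {
    v <- integer(1440); s <- sample(1440, 1)
    v[((s + 0:420) %% 1440L) + 1L] <- 1L; v
  }, integer(1440)))
  dates <- as.Date("2025-01-01") + 0:4
  base <- sri(day_grid(bits, dates), 5)$sri[5]
  rot <- bits[, c(301:1440, 1:300)]
  expect_equal(sri(day_grid(rot, dates), 5)$sri[5], base)
  expect_equal(sri(day_grid(1L - bits, dates), 5)$sri[5], base)
})

test_that("work_features sums bins per period and reconstructs totals", {
  dates <- as.Date("2025-02-01") + 0:2
  seqs <- c(paste(rep(c("1", "0"), c(16, 32)), collapse = ""),  # 00:00-08:00
            strrep("0", 48),
            paste(rep(c("0", "1", "0"), c(12, 16, 20)), collapse = ""))  # 06:00-14:00
  g <- build_work_sequence(seqs, dates)
  wf <- work_features(g)
  expect_equal(wf$work_total_h, c(8, 0, 8))
  expect_equal(wf$work_p1_h, c(8, 0, 2))
  expect_equal(wf$work_p2_h, c(0, 0, 6))
  expect_equal(wf$work_p3_h, c(0, 0, 0))
  expect_equal(wf$work_total_h, wf$work_p1_h + wf$work_p2_h + wf$work_p3_h)
})

test_that("sleep_work_overlap computes overlaps and minimum gaps", {
  dates <- as.Date("2025-02-01") + 0:1
  # day 1: shift 08:00-16:00, nap 13:00-13:20; day 2: shift 00:00-08:00
  work <- build_work_sequence(
    c(paste(rep(c("0", "1", "0"), c(16, 16, 16)), collapse = ""),
      paste(rep(c("1", "0"), c(16, 32)), collapse = "")), dates)
  sv <- data.table::data.table(
    date = rep(dates[1], 2),
    start = ts_utc(c("2025-02-01 13:00:00", "2025-02-01 20:00:00")),
    end = ts_utc(c("2025-02-01 13:20:00", "2025-02-01 22:00:00")),
    is_nap = c(TRUE, FALSE))
  sg <- build_sleep_sequence(sv, dates = dates)
  ov <- sleep_work_overlap(sg, work)
  expect_equal(ov$nap_during_work_min[1], 20)
  # sleep ends 22:00, next shift starts 00:00 the following day -> 120 min
  expect_equal(ov$gap_sleep_to_shift_min[2], 120)
  # no shift-end-to-sleep gap exists after the last shift
  expect_true(is.na(ov$gap_shift_to_sleep_min[2]))
  # day without any shift: gaps missing, overlap 0
  work0 <- build_work_sequence(c(strrep("0", 48), strrep("0", 48)), dates)
  ov0 <- sleep_work_overlap(sg, work0)
  expect_equal(ov0$nap_during_work_min, c(0, 0))
  expect_true(all(is.na(ov0$gap_sleep_to_shift_min)))
  expect_error(sleep_work_overlap(
    sg, build_work_sequence(strrep("0", 48), dates[1])), "date")
})

test_that("overlap never exceeds either daily total", {
  set.seed(73)
  dates <- as.Date("2025-02-01") + 0:3
  for (rep in 1:10) {
    sb <- matrix(rbinom(4 * 1440, 1, 0.3), 4, 1440)
    wb <- matrix(rbinom(4 * 48, 1, 0.3), 4, 48)
    ov <- sleep_work_overlap(day_grid(sb, dates),
                             day_grid(wb, dates, resolution = 30L))
    expect_true(all(ov$nap_during_work_min <=
                      pmin(rowSums(sb), rowSums(wb) * 30)))
  }
})
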