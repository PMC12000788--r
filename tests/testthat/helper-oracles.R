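# Independent brute-force oracles. These re-derive every quantity from
# first principles with the dumbest correct algorithm available and must
# stay independent of the package implementation paths they check.

# SRI: enumerate every pair of minutes exactly 24 h apart.
oracle_sri <- function(bits) {
  n_days <- nrow(bits)
  agree <- 0L
  total <- 0L
  for (d in seq_len(n_days - 1L)) {
    for (m in seq_len(ncol(bits))) {
      agree <- agree + as.integer(bits[d, m] == bits[d + 1L, m])
      total <- total + 1L
    }
  }
  -100 + 200 * agree / total
}

# Sample entropy: direct template enumeration.
oracle_sampen <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2L) return(NA_real_)
  count <- function(len) {
    hits <- 0L
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (i == j) next
        if (max(abs(x[i:(i + len - 1L)] - x[j:(j + len - 1L)])) <= r)
          hits <- hits + 1L
      }
    }
    hits / 2L
  }
  B <- count(m)
  A <- count(m + 1L)
  if (B == 0) return(NA_real_)
  if (A == 0) return(Inf)
  -log(A / B)
}

# Segment-duration entropy: explicit run splitting and tabulation.
oracle_segment_entropy <- function(steps) {
  act <- !is.na(steps) & steps > 0
  segs <- list(step = integer(), non_step = integer())
  i <- 1L
  while (i <= length(act)) {
    j <- i
    while (j < length(act) && act[j + 1L] == act[i]) j <- j + 1L
    key <- if (act[i]) "step" else "non_step"
    segs[[key]] <- c(segs[[key]], j - i + 1L)
    i <- j + 1L
  }
  ent <- function(d) {
    if (length(d) < 2L) return(0)
    p <- as.numeric(table(d)) / length(d)
    -sum(p * log(p))
  }
  c(entropy_step = ent(segs$step), entropy_non_step = ent(segs$non_step))
}

# Average precision by explicit threshold enumeration over unique scores.
oracle_auprc <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  n_pos <- sum(labels == 1L)
  for (t in ths) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / n_pos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Greedy Ward merging with explicit cluster statistics (no Lance-
# Williams): at each step merge the pair with the smallest ward.D2
# height sqrt(2 |A||B| / (|A|+|B|)) * ||mean_A - mean_B||.
oracle_ward_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        ia <- clusters[[a]]; ib <- clusters[[b]]
        ma <- colMeans(x[ia, , drop = FALSE])
        mb <- colMeans(x[ib, , drop = FALSE])
        d2 <- 2 * length(ia) * length(ib) / (length(ia) + length(ib)) *
          sum((ma - mb)^2)
        h <- sqrt(d2)
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Exhaustive F1 threshold search over unique scores (plus boundaries).
oracle_best_f1 <- function(labels, scores) {
  f1_at <- function(th) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  cands <- sort(unique(c(0, scores, 1)))
  max(vapply(cands, f1_at, numeric(1)))
}

# Welch statistic straight from the formula.
oracle_welch <- function(a, b) {
  se2 <- var(a) / length(a) + var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (var(a)^2 / (length(a)^2 * (length(a) - 1)) +
                   var(b)^2 / (length(b)^2 * (length(b) - 1)))
  p <- stats::pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

# Adjusted Rand index for cluster-recovery checks.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
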