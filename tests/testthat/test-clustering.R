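make_blobs <- function(k = 4L, per = 25L, p = 8L, sep = 10, seed = 5L) {
  stopifnot(p >= k)
  set.seed(seed)
  centers <- matrix(0, k, p)
  for (i in seq_len(k)) centers[i, i] <- sep   # orthogonal, well separated
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(per * p), per, p), 2L, centers[i, ], `+`)))
  list(x = scale(x), labels = rep(seq_len(k), each = per))
}

test_that("select_cluster_features withholds well-being and optional features", {
  df <- tiny_daily()
  mat <- suppressWarnings(select_cluster_features(df))  # sleep_prev_24 constant
  withheld <- c("sleep_satisfy", "stress", "alertness_morn", "sri_7",
                "caffeine_to_sleep_min", "gap_sleep_to_shift_min")
  expect_false(any(withheld %in% colnames(mat)))
  expect_true(all(c("sleep_duration_min", "brightness_sleep",
                    "work_total_h") %in% colnames(mat)))
  # standardized: mean 0, sd 1
  expect_true(all(abs(colMeans(mat)) < 1e-8))
  expect_true(all(abs(apply(mat, 2, sd) - 1) < 1e-8))
  expect_false(anyNA(mat))

  # all-complete toy table: nothing dropped
  toy <- data.table::data.table(participant = "P", date = Sys.Date() + 1:10,
                                a = rnorm(10), b = rnorm(10))
  expect_equal(attr(select_cluster_features(toy), "retained_fraction"), 1)
  # zero-variance column dropped with a warning
  toy$c <- 1
  expect_warning(m2 <- select_cluster_features(toy), "zero-variance")
  expect_false("c" %in% colnames(m2))
})

test_that("ward_cluster recovers planted blobs at the default 0.7 cut", {
  b <- make_blobs(k = 6L, per = 20L)
  cm <- ward_cluster(b$x)
  expect_equal(max(cm$labels), 6L)
  expect_gt(adjusted_rand(cm$labels, b$labels), 0.99)
  # merge heights nondecreasing
  expect_true(all(diff(cm$tree$height) >= -1e-8))
})

test_that("duplicate points merge at height zero", {
  x <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2))
  x[2, ] <- x[1, ]
  cm <- ward_cluster(x)
  expect_equal(min(cm$tree$height), 0)
  expect_error(ward_cluster(x, primary_threshold = -1), "positive")
  expect_error(ward_cluster(x[1, , drop = FALSE]), "2 rows")
})

test_that("ward merges match the exhaustive oracle for n <= 12", {
  set.seed(9)
  for (rep in 1:12) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    cm <- ward_cluster(x)
    expect_equal(sort(cm$tree$height), sort(oracle_ward_heights(x)),
                 tolerance = 1e-8)
  }
})

test_that("cluster counts are monotone in the threshold and cuts nest", {
  b <- make_blobs(k = 3L, per = 15L, seed = 11L)
  cm <- ward_cluster(b$x, secondary_threshold = 0.4 * max(ward_cluster(b$x)$tree$height))
  hs <- seq(0.05, 1.2, length.out = 12) * max(cm$tree$height)
  ks <- vapply(hs, function(h) max(cut_clusters(cm$tree, h)), integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_equal(ks[length(ks)], 1L)                 # above max height: 1
  expect_equal(max(cut_clusters(cm$tree, 1e-9)), nrow(b$x))  # near 0: n
  # every subcluster nests inside exactly one primary cluster
  nest <- table(cm$sublabels, cm$labels)
  expect_true(all(rowSums(nest > 0) == 1L))
  # labels are deterministic
  expect_identical(cm$labels, ward_cluster(b$x)$labels)
})

test_that("embed_days keeps the 95%-variance components and is seeded", {
  b <- make_blobs(k = 3L, per = 40L, p = 8L, seed = 13L)
  e1 <- embed_days(b$x, seed = 4, perplexity = 12)
  # eigenvalue bookkeeping oracle
  ev <- eigen(stats::cov(b$x))$values
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_equal(e1$n_components, k_oracle)
  expect_gte(e1$explained, 0.95)
  e2 <- embed_days(b$x, seed = 4, perplexity = 12)
  expect_identical(e1$coords, e2$coords)
  expect_error(embed_days(b$x[1:20, ], perplexity = 30), "perplexity")
  # planted blobs separate in the embedding
  sil <- cluster::silhouette(b$labels, stats::dist(e1$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("profiles equal an independent group-by and flag extremes", {
  df <- tiny_daily()
  mat <- suppressWarnings(select_cluster_features(df))
  cm <- ward_cluster(mat)
  prof <- cluster_profile(cm, df)
  # oracle: plain aggregate on the joined rows
  joined <- df[cm$rows, on = c("participant", "date")]
  joined$cluster <- cm$labels
  for (cl in unique(cm$labels)) {
    expect_equal(prof[cluster == cl, sleep_duration_min],
                 mean(joined$sleep_duration_min[joined$cluster == cl],
                      na.rm = TRUE))
    expect_equal(prof[cluster == cl, stress],
                 mean(joined$stress[joined$cluster == cl], na.rm = TRUE))
  }
  expect_equal(sum(prof$flag_shortest_sleep), 1L)
  # single-cluster cut: profile equals global means
  one <- ward_cluster(mat, primary_threshold = 2 * max(cm$tree$height))
  p1 <- cluster_profile(one, df)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$work_total_h, mean(joined$work_total_h, na.rm = TRUE))
})

test_that("short-sleep days cluster around the day-then-midnight context", {
  co <- simulate_cohort(cohort_config(n_participants = 25L), seed = 404L,
                        tables = c("participants", "sleep_periods",
                                   "morning_survey", "evening_survey"))
  df <- daily_features(co)
  mat <- suppressWarnings(select_cluster_features(df))
  cm <- ward_cluster(mat)
  prof <- cluster_profile(cm, df)
  short <- prof[flag_shortest_sleep == TRUE]
  # the shortest-sleep cluster sits in the pre-midnight-shift regime
  expect_lt(short$sleep_duration_min, 300)
  # and those days carry midnight-shift work (period 1 dominates)
  expect_gt(short$work_p1_h, short$work_p2_h)
})
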