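#' Select and standardize features for clustering
#'
#' Keeps the daily behavioural/physiological features, withholding
#' well-being and sleep-quality metrics and the structurally-optional
#' features that are undefined on many days (SRI, activity-conditional
#' gaps), so as many participant-days as possible survive. Rows with any
#' missing retained feature are dropped; retained columns are z-scored
#' across all participants. Zero-variance columns are dropped with a
#' warning.
#'
#' @param daily output of [daily_features()].
#' @return numeric matrix with attributes `rows` (a `data.table` of
#'   `participant`, `date` for retained rows) and `retained_fraction`.
#' @export
select_cluster_features <- function(daily) {
  daily <- as.data.table(daily)
  drop <- c("participant", "date", wellbeing_features(),
            optional_daily_features())
  cols <- setdiff(names(daily), drop)
  cols <- cols[vapply(daily[, ..cols], is.numeric, logical(1))]
  mat <- as.matrix(daily[, ..cols])
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  mat <- scale(mat)
  attr(mat, "rows") <- daily[keep, .(participant, date)]
  attr(mat, "retained_fraction") <- mean(keep)
  mat
}

#' Ward hierarchical clustering of participant-days
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances of
#' the standardized matrix (the Lance-Williams `ward.D2` recurrence,
#' whose merge heights match within-cluster-variance-minimising Ward).
#' The default primary cut is 0.7 times the maximum merge height; an
#' optional secondary threshold yields nested subclusters.
#'
#' @param mat standardized matrix from [select_cluster_features()].
#' @param primary_threshold dendrogram height for the primary cut;
#'   `NULL` (default) means `0.7 * max(height)`.
#' @param secondary_threshold optional lower height for subclusters.
#' @return object of class `cluster_model`: `hclust` tree, thresholds,
#'   `labels` and optional `sublabels`.
#' @export
ward_cluster <- function(mat, primary_threshold = NULL,
                         secondary_threshold = NULL) {
  if (nrow(mat) < 2L) stop("clustering needs at least 2 rows")
  tree <- stats::hclust(stats::dist(mat), method = "ward.D2")
  primary_threshold <- primary_threshold %||% (0.7 * max(tree$height))
  if (primary_threshold <= 0) stop("threshold must be positive")
  labels <- cut_clusters(tree, primary_threshold)
  sublabels <- if (!is.null(secondary_threshold)) {
    if (secondary_threshold <= 0) stop("threshold must be positive")
    cut_clusters(tree, secondary_threshold)
  }
  structure(list(tree = tree, mat = mat,
                 primary_threshold = primary_threshold,
                 secondary_threshold = secondary_threshold,
                 labels = labels, sublabels = sublabels,
                 rows = attr(mat, "rows")),
            class = "cluster_model")
}

#' Cut a dendrogram at a height
#'
#' Labels are deterministic: clusters are numbered by first appearance in
#' the tree's leaf order.
#'
#' @param tree an `hclust` object.
#' @param threshold height at which to cut.
#' @return integer labels, one per row.
#' @export
cut_clusters <- function(tree, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  raw <- stats::cutree(tree, h = threshold)
  first_seen <- unique(raw[tree$order])
  match(raw, first_seen)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> n=%d  primary cut %.2f -> %d clusters",
              length(x$labels), x$primary_threshold, max(x$labels)))
  if (!is.null(x$sublabels))
    cat(sprintf("; secondary cut %.2f -> %d subclusters",
                x$secondary_threshold, max(x$sublabels)))
  cat("\n")
  invisible(x)
}

#' 2-D embedding of the clustered days
#'
#' PCA retains the smallest number of components whose cumulative
#' explained variance reaches `var_target` (study protocol: 0.95), then
#' t-SNE maps those scores to 2 dimensions under a fixed seed.
#'
#' @param mat standardized matrix.
#' @param seed integer seed (t-SNE is stochastic).
#' @param perplexity t-SNE perplexity (default 30; must satisfy
#'   `3 * perplexity < n - 1`).
#' @param var_target cumulative explained-variance target.
#' @return list: `coords` (n x 2), `n_components`, `explained`.
#' @export
embed_days <- function(mat, seed = 1L, perplexity = 30, var_target = 0.95) {
  if (3 * perplexity >= nrow(mat) - 1L)
    stop("perplexity too large for n = ", nrow(mat),
         "; need 3 * perplexity < n - 1. Lower `perplexity`.")
  pc <- stats::prcomp(mat, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= var_target)[1L]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  set.seed(seed)
  ts <- Rtsne::Rtsne(scores, dims = 2L, perplexity = perplexity,
                     pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  list(coords = ts$Y, n_components = k, explained = cum[k])
}

#' Per-cluster profiles
#'
#' Feature means per cluster over the clustering inputs plus the withheld
#' well-being metrics, with narrative flags for the extreme clusters
#' (lowest mean sleep duration, highest mean steps).
#'
#' @param model a `cluster_model`.
#' @param daily full daily feature table (for withheld metrics).
#' @param use_sublabels profile subclusters instead of primary clusters.
#' @return `data.table` of per-cluster means with `n` and flag columns.
#' @export
cluster_profile <- function(model, daily, use_sublabels = FALSE) {
  labels <- if (use_sublabels) model$sublabels else model$labels
  if (is.null(labels)) stop("no labels at the requested level")
  daily <- as.data.table(daily)
  rows <- model$rows
  sub <- daily[rows, on = c("participant", "date")]
  sub[, cluster := labels]
  num_cols <- setdiff(names(sub)[vapply(sub, is.numeric, logical(1))],
                      "cluster")
  prof <- sub[, c(list(n = .N),
                  lapply(.SD, function(v) mean(v, na.rm = TRUE))),
              by = cluster, .SDcols = num_cols]
  setorder(prof, cluster)
  if ("sleep_duration_min" %in% names(prof))
    prof[, flag_shortest_sleep := sleep_duration_min ==
           min(sleep_duration_min, na.rm = TRUE)]
  if ("steps" %in% names(prof))
    prof[, flag_most_steps := steps == max(steps, na.rm = TRUE)]
  prof[]
}
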