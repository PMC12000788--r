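#' Area under the precision-recall curve
#'
#' Step-wise average-precision estimator: the sum over decreasing score
#' thresholds of precision times the recall increment (not trapezoidal
#' interpolation, which differs at small n). Tied scores form a single
#' threshold group, so constant scores yield exactly the positive
#' prevalence.
#'
#' @param labels binary 0/1 labels.
#' @param scores numeric scores, higher = more positive.
#' @return value in `[0, 1]`; `NA` with a warning when labels are
#'   single-class.
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || n_pos == length(labels)) {
    warning("AUPRC undefined for single-class labels")
    return(NA_real_)
  }
  ord <- order(-scores)
  lab <- labels[ord]
  s <- scores[ord]
  last <- !duplicated(s, fromLast = TRUE)  # end of each tied-score group
  tp <- cumsum(lab)[last]
  np <- seq_along(lab)[last]
  precision <- tp / np
  d_tp <- diff(c(0, tp))
  sum(precision * d_tp) / n_pos
}

#' Uniform-random-guessing AUPRC baseline
#'
#' Repeatedly scores the labels with i.i.d. standard-uniform predictions;
#' the sample mean approaches the positive prevalence.
#'
#' @param labels binary labels (both classes present).
#' @param n_trials number of trials (study protocol: 10).
#' @param seed integer seed.
#' @return numeric vector of `n_trials` AUPRC values.
#' @export
random_baseline <- function(labels, n_trials = 10L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_trials), function(i)
    auprc(labels, stats::runif(length(labels))), numeric(1))
}

#' One-sided Welch t test (model > baseline)
#'
#' Welch statistic with Satterthwaite degrees of freedom, alternative
#' "model mean exceeds baseline mean". When both samples have zero
#' variance: equal means give P = 0.5 by convention (with a warning);
#' otherwise P is 0 or 1 according to the sign of the mean difference.
#'
#' @param model_vals numeric sample (e.g. 10 seed AUPRCs).
#' @param baseline_vals numeric sample (e.g. 10 random-guessing AUPRCs).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_test <- function(model_vals, baseline_vals) {
  stopifnot(length(model_vals) >= 2L, length(baseline_vals) >= 2L)
  m1 <- mean(model_vals); m2 <- mean(baseline_vals)
  v1 <- stats::var(model_vals); v2 <- stats::var(baseline_vals)
  n1 <- length(model_vals); n2 <- length(baseline_vals)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      warning("zero variance in both samples with equal means; P = 0.5 by convention")
      return(list(t = 0, df = NA_real_, p_value = 0.5))
    }
    return(list(t = sign(m1 - m2) * Inf, df = NA_real_,
                p_value = if (m1 > m2) 0 else 1))
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  list(t = tstat, df = df, p_value = stats::pt(tstat, df, lower.tail = FALSE))
}

#' Cross-validated F1-optimal decision threshold
#'
#' Refits the chosen configuration per stratified fold, pools the
#' out-of-fold scores, and picks the threshold from a grid of 101 evenly
#' spaced points in `[0, 1]` maximising F1 (ties resolved toward the
#' lowest threshold).
#'
#' @param x training features.
#' @param y training labels.
#' @param family,params,balancing the configuration to refit per fold.
#' @param seed run seed.
#' @param cv_folds folds (default 5).
#' @param groups optional participant grouping for folds.
#' @return list with `threshold`, `f1` (CV F1 at the optimum).
#' @export
optimize_threshold <- function(x, y, family, params = list(),
                               balancing = "none", seed = 1L, cv_folds = 5L,
                               groups = NULL) {
  x <- as.matrix(x); y <- as.integer(y)
  fold <- .make_folds(y, cv_folds, child_seed(seed, 21L), groups)
  if (any(vapply(seq_len(cv_folds), function(f)
    length(unique(y[fold == f])) < 2L ||
      length(unique(y[fold != f])) < 2L, logical(1))))
    stop("threshold optimisation: a CV fold has a single class")
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    bal <- balance_data(x[tr, , drop = FALSE], y[tr], balancing,
                        seed = child_seed(seed, 700L + f))
    m <- fit_advice_model(bal$x, bal$y, family, params,
                          seed = child_seed(seed, 800L + f))
    oof[!tr] <- predict_proba(m, x[!tr, , drop = FALSE])
  }
  res <- f1_threshold(y, oof)
  list(threshold = res$threshold, f1 = res$f1, grid_f1 = res$grid_f1)
}

#' F1-optimal threshold on a score vector
#'
#' Grid of `grid_points` evenly spaced thresholds in `[0, 1]`; ties
#' resolve to the lowest threshold.
#'
#' @param labels binary labels.
#' @param scores scores in `[0, 1]`.
#' @param grid_points grid resolution (default 101).
#' @return list with `threshold`, `f1`, `grid_f1`.
#' @export
f1_threshold <- function(labels, scores, grid_points = 101L) {
  grid <- seq(0, 1, length.out = grid_points)
  f1s <- vapply(grid, function(th)
    .f1_score(labels, as.integer(scores >= th)), numeric(1))
  best <- which(f1s == max(f1s, na.rm = TRUE))[1L]  # lowest optimal threshold
  list(threshold = grid[best], f1 = f1s[best], grid_f1 = f1s)
}

.f1_score <- function(labels, pred) {
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Majority-vote ensemble prediction
#'
#' Each voter is a fitted classifier with its own decision threshold; the
#' ensemble predicts the majority of the binary votes. The voter count
#' must be odd so ties cannot occur (the study protocol keeps 9 of its 10
#' seeds).
#'
#' @param models list of `advice_model`s.
#' @param thresholds numeric vector, one per model.
#' @param x feature matrix.
#' @return integer 0/1 predictions.
#' @export
ensemble_predict <- function(models, thresholds, x) {
  k <- length(models)
  stopifnot(length(thresholds) == k)
  if (k %% 2L == 0L) stop("voter count must be odd to resolve ties")
  votes <- vapply(seq_len(k), function(i)
    as.integer(predict_proba(models[[i]], x) >= thresholds[i]),
    integer(nrow(as.matrix(x))))
  as.integer(rowSums(matrix(votes, ncol = k)) > k / 2)
}

#' Thresholded classification metrics
#'
#' @param labels binary labels.
#' @param pred binary predictions.
#' @return named list: sensitivity, specificity, precision, f1.
#' @export
classification_metrics <- function(labels, pred) {
  labels <- as.integer(labels); pred <- as.integer(pred)
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       f1 = .f1_score(labels, pred))
}

#' Always-positive baseline F1
#'
#' Predicting every sample positive yields `F1 = 2p / (1 + p)` at
#' prevalence `p`.
#'
#' @param labels binary labels.
#' @return scalar F1.
#' @export
always_positive_f1 <- function(labels) {
  p <- mean(as.integer(labels) == 1L)
  2 * p / (1 + p)
}

#' Run the full evaluation protocol for one message
#'
#' Tunes and fits one model per seed for a (family, balancing)
#' configuration, evaluates test AUPRC per seed, compares the seed sample
#' against a uniform-random baseline with a one-sided Welch t test, then
#' builds the thresholded majority-vote ensemble (first `n_voters` seeds,
#' each with its own CV-optimised F1 threshold) and reports thresholded
#' metrics against the always-positive baseline.
#'
#' @param train,test `x`/`y` lists (`x` matrix, `y` labels, optional
#'   `groups`).
#' @param family,balancing configuration.
#' @param seeds integer vector of run seeds (study protocol: 10).
#' @param n_search random-search budget per run.
#' @param cv_folds CV folds.
#' @param n_voters ensemble size (odd; defaults to
#'   `length(seeds) - (length(seeds) %% 2 == 0)`).
#' @return list with per-seed AUPRCs, baseline sample, Welch test,
#'   ensemble metrics and fitted artifacts.
#' @export
evaluate_configuration <- function(train, test, family, balancing,
                                   seeds = 1:10, n_search = 100L,
                                   cv_folds = 5L, n_voters = NULL) {
  n_voters <- n_voters %||% (length(seeds) - (length(seeds) %% 2L == 0L))
  fits <- lapply(seeds, function(s)
    tune_and_fit(train$x, train$y, family, balancing, seed = s,
                 n_search = n_search, cv_folds = cv_folds,
                 groups = train$groups))
  test_auprc <- vapply(fits, function(f)
    auprc(test$y, predict_proba(f$model, test$x)), numeric(1))
  baseline <- random_baseline(test$y, n_trials = max(10L, length(seeds)),
                              seed = child_seed(seeds[1L], 333L))
  wt <- welch_test(test_auprc, baseline)

  voters <- fits[seq_len(n_voters)]
  thresholds <- vapply(voters, function(f)
    optimize_threshold(train$x, train$y, family, f$params, balancing,
                       seed = child_seed(f$seed, 55L), cv_folds = cv_folds,
                       groups = train$groups)$threshold, numeric(1))
  pred <- ensemble_predict(lapply(voters, `[[`, "model"), thresholds, test$x)
  metrics <- classification_metrics(test$y, pred)

  list(family = family, balancing = balancing,
       auprc = test_auprc, auprc_mean = mean(test_auprc),
       auprc_sd = stats::sd(test_auprc),
       baseline = baseline, baseline_mean = mean(baseline),
       baseline_sd = stats::sd(baseline),
       welch = wt, thresholds = thresholds, ensemble_metrics = metrics,
       always_positive_f1 = always_positive_f1(test$y), fits = fits)
}
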