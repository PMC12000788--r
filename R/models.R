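#' Tree-ensemble classifiers for advice prediction
#'
#' Three families mirror the study's model zoo, all built on one native
#' CART-style learner:
#' * `"bagged"` — bootstrap-aggregated depth-wise trees with per-node
#'   feature subsampling (random-forest class); leaf values are class
#'   fractions and the model output is their average, so the margin is a
#'   probability.
#' * `"boosted_leafwise"` — gradient boosting with logistic loss and
#'   best-first (leaf-wise) tree growth limited by `max_leaves`
#'   (LightGBM class).
#' * `"boosted_symmetric"` — gradient boosting with oblivious trees: one
#'   shared split per depth level (CatBoost class).
#'
#' @param x numeric feature matrix (no missing values).
#' @param y binary 0/1 labels.
#' @param family one of `"bagged"`, `"boosted_leafwise"`,
#'   `"boosted_symmetric"`.
#' @param params named list of hyperparameters (see [model_grid()] for the
#'   tunable set and defaults).
#' @param seed integer seed governing bootstraps, subsampling and feature
#'   sampling.
#' @return object of class `advice_model` with `predict_proba` support.
#' @export
fit_advice_model <- function(x, y, family = c("bagged", "boosted_leafwise",
                                              "boosted_symmetric"),
                             params = list(), seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("single-class training labels; cannot fit a classifier")
  p <- defaults_for(family)
  p[names(params)] <- params
  set.seed(seed)
  model <- switch(family,
    bagged = .fit_bagged(x, y, p, seed),
    boosted_leafwise = .fit_boosted(x, y, p, seed, growth = 1L),
    boosted_symmetric = .fit_boosted(x, y, p, seed, growth = 2L))
  model$family <- family
  model$params <- p
  model$feature_names <- colnames(x)
  class(model) <- "advice_model"
  model
}

defaults_for <- function(family) {
  switch(family,
    bagged = list(n_trees = 150L, max_depth = 8L, min_leaf = 2L,
                  mtry_frac = 0.33, sample_frac = 1.0),
    boosted_leafwise = list(n_trees = 120L, max_leaves = 15L, max_depth = 8L,
                            min_leaf = 5L, learning_rate = 0.1,
                            mtry_frac = 0.8, subsample = 0.9, lambda = 1.0),
    boosted_symmetric = list(n_trees = 120L, max_depth = 4L, min_leaf = 5L,
                             learning_rate = 0.1, mtry_frac = 0.8,
                             subsample = 0.9, lambda = 1.0))
}

.fit_bagged <- function(x, y, p, seed) {
  n <- nrow(x)
  mtry <- max(1L, round(p$mtry_frac * ncol(x)))
  trees <- vector("list", p$n_trees)
  for (t in seq_len(p$n_trees)) {
    rows <- sample.int(n, size = max(2L, round(p$sample_frac * n)),
                       replace = TRUE) - 1L
    trees[[t]] <- .fit_tree_cpp(x, y, rep(1, n), rows,
                                p$max_depth, 0L, p$min_leaf, mtry, 0,
                                0L, child_seed(seed, 1000L + t))
  }
  list(trees = trees, scale = rep(1 / p$n_trees, p$n_trees), base = 0,
       link = "identity")
}

.fit_boosted <- function(x, y, p, seed, growth) {
  n <- nrow(x)
  mtry <- max(1L, round(p$mtry_frac * ncol(x)))
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  base <- stats::qlogis(p0)
  margin <- rep(base, n)
  trees <- vector("list", p$n_trees)
  for (t in seq_len(p$n_trees)) {
    prob <- stats::plogis(margin)
    grad <- y - prob
    hess <- pmax(prob * (1 - prob), 1e-6)
    rows <- sample.int(n, size = max(2L, round(p$subsample * n))) - 1L
    tree <- .fit_tree_cpp(x, grad, hess, rows,
                          p$max_depth, p$max_leaves %||% 0L, p$min_leaf,
                          mtry, p$lambda, growth,
                          child_seed(seed, 2000L + t))
    trees[[t]] <- tree
    margin <- margin + p$learning_rate * .predict_tree_cpp(tree, x)
  }
  list(trees = trees, scale = rep(p$learning_rate, p$n_trees), base = base,
       link = "logit")
}

.predict_margin <- function(model, x) {
  out <- rep(model$base, nrow(x))
  for (t in seq_along(model$trees))
    out <- out + model$scale[t] * .predict_tree_cpp(model$trees[[t]], x)
  out
}

#' Predict selection probabilities
#'
#' @param model an `advice_model`.
#' @param x feature matrix whose columns match the training schema (name
#'   order is reconciled; unknown/missing columns are an error).
#' @return numeric scores in `[0, 1]`, higher meaning more likely
#'   selected.
#' @export
predict_proba <- function(model, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(x)))
      stopifnot(ncol(x) == length(model$feature_names))
    else {
      missing <- setdiff(model$feature_names, colnames(x))
      if (length(missing))
        stop("feature schema mismatch; missing columns: ",
             paste(missing, collapse = ", "))
      x <- x[, model$feature_names, drop = FALSE]
    }
  }
  m <- .predict_margin(model, x)
  if (model$link == "logit") stats::plogis(m) else pmin(pmax(m, 0), 1)
}

#' @export
print.advice_model <- function(x, ...) {
  cat(sprintf("<advice_model> family=%s  trees=%d  features=%d\n",
              x$family, length(x$trees), length(x$feature_names)))
  invisible(x)
}

#' Shapley attributions for a tree-ensemble model
#'
#' Path-dependent TreeSHAP summed over the ensemble, in the model's raw
#' margin space (probability for bagged forests, log-odds for boosted
#' families), where additivity is exact:
#' `base_value + rowSums(phi) == margin(x)` for every sample.
#'
#' @param model an `advice_model`.
#' @param x feature matrix (training schema).
#' @return list with `phi` (n x p matrix of contributions),
#'   `base_value` (expected margin), and `global` (mean absolute
#'   contribution per feature).
#' @export
shapley_attribution <- function(model, x) {
  if (!inherits(model, "advice_model"))
    stop("sampling-based attribution fallback is only defined for ",
         "tree ensembles here; got ", class(model)[1L])
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x)) && !is.null(model$feature_names))
    x <- x[, model$feature_names, drop = FALSE]
  phi <- matrix(0, nrow(x), ncol(x))
  base_value <- model$base
  for (t in seq_along(model$trees)) {
    phi <- phi + model$scale[t] * .tree_shap_cpp(model$trees[[t]], x)
    base_value <- base_value + model$scale[t] *
      .tree_expected_cpp(model$trees[[t]])
  }
  colnames(phi) <- model$feature_names %||% colnames(x)
  global <- colMeans(abs(phi))
  list(phi = phi, base_value = base_value, global = global)
}
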