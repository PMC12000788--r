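#' Messages modelled by default
#'
#' The seven most frequently selected messages; rarer messages have too
#' few positives to support per-message classifiers.
#' @return integer vector.
#' @export
modeled_messages <- function() c(4L, 7L, 12L, 14L, 15L, 20L, 21L)

#' Split advice samples into train and test sets
#'
#' `"dependent"` splits chronologically within each participant (first
#' `train_frac` of their samples train, the rest test; fractional counts
#' floor toward training by taking `floor(train_frac * n)` forward in
#' time, so every test date follows every training date of the same
#' participant). `"independent"` splits by enrollment order: the first
#' `train_frac` of participants train, later enrollees test, with empty
#' intersection.
#'
#' @param samples output of [assemble_advice_samples()].
#' @param mode `"dependent"` or `"independent"`.
#' @param train_frac training fraction (default 0.7).
#' @param enroll_order named integer vector mapping participant id to
#'   enrollment rank (required for the independent mode).
#' @return list with `train`, `test` (`data.table`s) and `mode`.
#' @export
split_samples <- function(samples, mode = c("dependent", "independent"),
                          train_frac = 0.7, enroll_order = NULL) {
  mode <- match.arg(mode)
  s <- as.data.table(samples)
  setkey(s, participant, date)
  if (mode == "dependent") {
    s[, idx := seq_len(.N), by = participant]
    s[, n_tot := .N, by = participant]
    if (any(s$n_tot < 2L)) {
      small <- unique(s[n_tot < 2L, participant])
      warning("dropping ", length(small),
              " participant(s) with < 2 samples from the dependent split")
      s <- s[n_tot >= 2L]
    }
    if (!nrow(s)) stop("dependent split needs >= 2 samples per participant")
    train <- s[idx <= floor(train_frac * n_tot)]
    test <- s[idx > floor(train_frac * n_tot)]
    train[, c("idx", "n_tot") := NULL]
    test[, c("idx", "n_tot") := NULL]
  } else {
    if (is.null(enroll_order))
      stop("independent split requires enroll_order")
    ids <- names(sort(enroll_order))
    ids <- ids[ids %in% s$participant]
    if (length(ids) < 2L) stop("independent split needs >= 2 participants")
    n_train <- floor(train_frac * length(ids))
    train_ids <- ids[seq_len(n_train)]
    train <- s[participant %in% train_ids]
    test <- s[!participant %in% train_ids]
  }
  list(train = train[], test = test[], mode = mode)
}

#' Balance a binary training set
#'
#' `"oversample"` duplicates minority rows with replacement until the
#' classes are equal. `"smote"` synthesises minority rows as convex
#' combinations of a minority point and one of its `k` nearest minority
#' neighbours (Euclidean); when the minority count is `<= k`, `k` is
#' reduced to count - 1 with a warning, and a singleton minority class
#' falls back to random oversampling. `"none"` returns the input
#' untouched. Balancing never sees test rows.
#'
#' @param x feature matrix.
#' @param y binary 0/1 labels (both classes required).
#' @param method `"none"`, `"oversample"` or `"smote"`.
#' @param seed integer seed.
#' @param k SMOTE neighbour count (default 5).
#' @return list with balanced `x` and `y`.
#' @export
balance_data <- function(x, y, method = c("none", "oversample", "smote"),
                         seed = 1L, k = 5L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (method == "none") return(list(x = x, y = y))
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("both classes must be present to balance")
  minority <- as.integer(names(which.min(tab)))
  n_needed <- abs(diff(as.integer(tab)))
  if (n_needed == 0L) return(list(x = x, y = y))
  min_idx <- which(y == minority)
  set.seed(seed)
  if (method == "smote" && length(min_idx) == 1L) {
    warning("minority class has a single sample; falling back to random oversampling")
    method <- "oversample"
  }
  if (method == "oversample") {
    pick <- sample(min_idx, n_needed, replace = TRUE)
    new_x <- x[pick, , drop = FALSE]
  } else {
    if (length(min_idx) <= k) {
      k <- length(min_idx) - 1L
      warning("minority count <= k; reducing SMOTE k to ", k)
    }
    mx <- x[min_idx, , drop = FALSE]
    nn <- FNN::get.knn(mx, k = k)$nn.index
    base <- sample(seq_along(min_idx), n_needed, replace = TRUE)
    nbr <- nn[cbind(base, sample.int(k, n_needed, replace = TRUE))]
    gap <- stats::runif(n_needed)
    new_x <- mx[base, , drop = FALSE] +
      gap * (mx[nbr, , drop = FALSE] - mx[base, , drop = FALSE])
  }
  list(x = rbind(x, new_x), y = c(y, rep(minority, n_needed)))
}

#' Random-search hyperparameter grid
#'
#' The tunable space per family; the study names the search protocol (100
#' iterations of random search over a grid) but not the grid itself, so
#' these are repository-defined.
#'
#' @param family model family (see [fit_advice_model()]).
#' @return named list of candidate value vectors.
#' @export
model_grid <- function(family) {
  switch(family,
    bagged = list(n_trees = c(100L, 150L, 200L, 300L),
                  max_depth = c(3L, 5L, 8L, 12L),
                  min_leaf = c(1L, 2L, 4L, 8L),
                  mtry_frac = c(0.15, 0.33, 0.6, 1.0)),
    boosted_leafwise = list(n_trees = c(50L, 100L, 150L),
                            max_leaves = c(7L, 15L, 31L),
                            min_leaf = c(2L, 5L, 10L),
                            learning_rate = c(0.03, 0.1, 0.2),
                            mtry_frac = c(0.5, 0.8, 1.0),
                            subsample = c(0.7, 0.9, 1.0),
                            lambda = c(0.5, 1, 3)),
    boosted_symmetric = list(n_trees = c(50L, 100L, 150L),
                             max_depth = c(2L, 4L, 6L),
                             min_leaf = c(2L, 5L, 10L),
                             learning_rate = c(0.03, 0.1, 0.2),
                             mtry_frac = c(0.5, 0.8, 1.0),
                             subsample = c(0.7, 0.9, 1.0),
                             lambda = c(0.5, 1, 3)))
}

# stratified fold assignment; grouped by participant when groups given
.make_folds <- function(y, n_folds, seed, groups = NULL) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    gs <- unique(groups)
    # order groups by positive count so folds stay label-stratified
    pos <- vapply(gs, function(g) sum(y[groups == g]), numeric(1))
    names(pos) <- gs
    gs <- sample(gs)                     # random tie order
    gs <- gs[order(-pos[gs])]
    gf <- rep_len(seq_len(n_folds), length(gs))
    fold <- gf[match(groups, gs)]
  }
  fold
}

#' Tune and fit a per-message classifier
#'
#' Random search over [model_grid()] scored by mean out-of-fold AUPRC
#' under stratified cross-validation (participant-grouped folds in the
#' independent mode). Balancing is applied inside each training fold
#' only; validation folds stay at the original class ratio. The winning
#' configuration is refit on the full (balanced) training set. All
#' randomness derives from `seed`.
#'
#' @param x training feature matrix.
#' @param y binary labels.
#' @param family model family.
#' @param balancing `"none"`, `"oversample"` or `"smote"`.
#' @param seed run seed.
#' @param n_search random-search iterations (study protocol: 100).
#' @param cv_folds folds (study protocol: 5).
#' @param groups participant ids per row, for grouped folds.
#' @return list: `model` (fitted `advice_model`), `params`, `cv_auprc`.
#' @export
tune_and_fit <- function(x, y, family = "bagged", balancing = "none",
                         seed = 1L, n_search = 100L, cv_folds = 5L,
                         groups = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("message has a single class in training data")
  grid <- model_grid(family)
  set.seed(child_seed(seed, 11L))
  n_comb <- prod(lengths(grid))
  n_search <- min(n_search, n_comb)
  cand <- unique(rbindlist(lapply(seq_len(max(n_search * 2L, 10L)), function(i)
    as.data.table(lapply(grid, function(v) sample(v, 1L))))))
  cand <- cand[seq_len(min(n_search, nrow(cand)))]

  fold <- .make_folds(y, cv_folds, child_seed(seed, 13L), groups)
  # guard: every fold's validation part needs both classes for AUPRC
  for (attempt in 1:2) {
    bad <- any(vapply(seq_len(cv_folds), function(f)
      length(unique(y[fold == f])) < 2L, logical(1)))
    if (!bad) break
    if (attempt == 2L) stop("degenerate CV folds: a fold has a single class")
    fold <- .make_folds(y, cv_folds, child_seed(seed, 131L), groups)
  }

  scores <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    params <- as.list(cand[ci])
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      bal <- balance_data(x[tr, , drop = FALSE], y[tr], balancing,
                          seed = child_seed(seed, 300L + f))
      m <- fit_advice_model(bal$x, bal$y, family, params,
                            seed = child_seed(seed, 500L + ci * 7L + f))
      auprc(y[!tr], predict_proba(m, x[!tr, , drop = FALSE]))
    }, numeric(1))
    scores[ci] <- mean(aucs)
  }
  best <- which.max(scores)
  params <- as.list(cand[best])
  bal <- balance_data(x, y, balancing, seed = child_seed(seed, 999L))
  model <- fit_advice_model(bal$x, bal$y, family, params,
                            seed = child_seed(seed, 1234L))
  list(model = model, params = params, cv_auprc = scores[best],
       cv_scores = scores, seed = seed)
}
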