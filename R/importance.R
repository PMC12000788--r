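#' Permutation importance on held-out data
#'
#' AUPRC decrease after randomly permuting one feature column of the test
#' matrix, repeated `n_repeats` times (study protocol: 10 per classifier
#' run). Permutations derive from the run seed offset by the feature
#' index, so reruns are reproducible.
#'
#' @param model fitted `advice_model`.
#' @param x test features (both classes required in `y`).
#' @param y test labels.
#' @param features columns to assess (default all).
#' @param n_repeats permutations per feature.
#' @param seed run seed.
#' @return `data.table`: `feature`, `auprc_decrease_mean`,
#'   `auprc_decrease_sd`, plus the baseline test `auprc`.
#' @export
permutation_importance <- function(model, x, y, features = NULL,
                                   n_repeats = 10L, seed = 1L) {
  x <- as.matrix(x)
  features <- features %||% colnames(x)
  base_auc <- auprc(y, predict_proba(model, x))
  res <- lapply(features, function(f) {
    j <- match(f, colnames(x))
    decs <- vapply(seq_len(n_repeats), function(r) {
      set.seed(child_seed(seed, j * 1000L + r))
      xp <- x
      xp[, j] <- xp[sample.int(nrow(xp)), j]
      base_auc - auprc(y, predict_proba(model, xp))
    }, numeric(1))
    data.table(feature = f, auprc_decrease_mean = mean(decs),
               auprc_decrease_sd = stats::sd(decs))
  })
  out <- rbindlist(res)
  out[, auprc := base_auc]
  out[]
}

#' Aggregate importance measures across runs
#'
#' Averages per-run permutation and Shapley importances, then reports the
#' features ranked in the top `top_k` by BOTH measures whose mean AUPRC
#' decrease and mean absolute Shapley value both clear `floor_value`
#' (default 0.01), mirroring the study's joint reporting rule.
#'
#' @param perm_runs list of [permutation_importance()] tables, one per run.
#' @param shap_runs list of named global mean-|SHAP| vectors, one per run.
#' @param top_k rank cutoff (default 5).
#' @param floor_value minimum mean on both measures (default 0.01).
#' @return list: `table` (all features, mean/SD of both measures, ranks,
#'   `joint_top` flag) and `reported` (the joint top-k rows only).
#' @export
aggregate_importance <- function(perm_runs, shap_runs, top_k = 5L,
                                 floor_value = 0.01) {
  stopifnot(length(perm_runs) >= 1L, length(shap_runs) == length(perm_runs))
  perm <- rbindlist(perm_runs)[, .(
    auprc_decrease_mean = mean(auprc_decrease_mean),
    auprc_decrease_sd = stats::sd(auprc_decrease_mean)), by = feature]
  shap_mat <- do.call(rbind, lapply(shap_runs, function(v) v))
  shap <- data.table(feature = colnames(shap_mat),
                     shap_mean = colMeans(shap_mat),
                     shap_sd = apply(shap_mat, 2L, stats::sd))
  tab <- merge(perm, shap, by = "feature", all = TRUE)
  tab[is.na(auprc_decrease_mean), auprc_decrease_mean := 0]
  tab[is.na(shap_mean), shap_mean := 0]
  tab[, rank_perm := frank(-auprc_decrease_mean, ties.method = "min")]
  tab[, rank_shap := frank(-shap_mean, ties.method = "min")]
  tab[, joint_top := rank_perm <= top_k & rank_shap <= top_k &
        auprc_decrease_mean >= floor_value & shap_mean >= floor_value]
  setorder(tab, rank_perm)
  list(table = tab[], reported = tab[joint_top == TRUE][])
}

#' Importance report for one evaluated configuration
#'
#' Runs permutation importance and Shapley attribution for every fitted
#' run of an [evaluate_configuration()] result and aggregates them with
#' the joint top-5 / 0.01-floor rule.
#'
#' @param evaluation result of [evaluate_configuration()].
#' @param test list with test `x` and `y`.
#' @param n_repeats permutation repeats per feature per run.
#' @param top_k,floor_value see [aggregate_importance()].
#' @return as [aggregate_importance()].
#' @export
importance_report <- function(evaluation, test, n_repeats = 10L,
                              top_k = 5L, floor_value = 0.01) {
  perm_runs <- list(); shap_runs <- list()
  for (i in seq_along(evaluation$fits)) {
    fit <- evaluation$fits[[i]]
    perm_runs[[i]] <- permutation_importance(fit$model, test$x, test$y,
                                             n_repeats = n_repeats,
                                             seed = fit$seed)
    shap_runs[[i]] <- shapley_attribution(fit$model, test$x)$global
  }
  aggregate_importance(perm_runs, shap_runs, top_k, floor_value)
}
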