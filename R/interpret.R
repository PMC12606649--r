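# Feature attribution and correlation analysis: exact TreeSHAP attributions
# of the gradient-boosted model (per-prediction additive contributions in mV),
# cross-model importance tables, and per-feature Spearman screening against
# the reduction potential.

#' Fit a single gradient-boosted tree model
#'
#' One tuned (or default-parameter) gradient-boosted regressor, outside the
#' nested-CV protocol; the object [shap_importance()] and
#' [predict.fes_gbt_model()] operate on.
#'
#' @param X design matrix (schema-named columns).
#' @param y target (mV).
#' @param params list with `max_depth`, `n_estimators`, `learning_rate`,
#'   `min_child_weight`; defaults to a mid-grid configuration.
#' @return object of class `fes_gbt_model`.
#' @export
fit_gbt <- function(X, y, params = NULL) {
  m <- .fit_model(as.matrix(X), y, "gbt", params)
  class(m) <- "fes_gbt_model"
  m
}

#' @export
predict.fes_gbt_model <- function(object, newdata, ...) {
  .predict_model(unclass(object), as.matrix(newdata))
}

#' SHAP feature attributions of a gradient-boosted model
#'
#' Exact tree-path (TreeSHAP) attributions: for every row, each feature
#' receives an additive contribution (mV) such that contributions plus the
#' base value reproduce the prediction (local accuracy, enforced up to the
#' single-precision arithmetic of the booster). Importance is the mean of
#' absolute attributions over rows.
#'
#' @param model an `fes_gbt_model` (or the `final_model` of a [fesred()] fit).
#' @param X rows to attribute (matrix with the model's feature columns).
#' @return list: `importance` (named mean absolute attribution per feature,
#'   sorted decreasing), `attributions` (rows x features matrix), `base_value`.
#' @export
shap_importance <- function(model, X) {
  if (!inherits(model, "fes_gbt_model") ||
      !identical(unclass(model)$kind, "gbt"))
    stop("SHAP attribution supports tree-based models only")
  m <- unclass(model)
  X <- as.matrix(X)[, m$feature_names, drop = FALSE]
  contrib <- stats::predict(m$booster, X, predcontrib = TRUE)
  base <- contrib[, ncol(contrib)]
  attributions <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(attributions) <- m$feature_names
  pred <- .predict_model(m, X)
  # local accuracy, scale-aware tolerance for float32 tree sums
  tol <- max(1e-4, 1e-5 * max(abs(pred)))
  gap <- max(abs(rowSums(attributions) + base - pred))
  if (gap > tol)
    stop("SHAP local accuracy violated: max gap ", signif(gap, 3), " mV")
  imp <- colMeans(abs(attributions))
  list(importance = sort(imp, decreasing = TRUE),
       attributions = attributions, base_value = base[1])
}

#' Cross-validated SHAP importance
#'
#' The attribution protocol used for reporting: within each outer fold of a
#' repeated k-fold split, a model is fit on the training rows and attributed
#' on its own held-out rows; importances are averaged across folds and
#' repeats.
#'
#' @param X design matrix.
#' @param y target (mV).
#' @param params gradient-boosting parameters (see [fit_gbt()]).
#' @param outer_folds,repeats split geometry.
#' @param seed fold seed.
#' @return named numeric vector: mean absolute attribution per feature,
#'   sorted decreasing.
#' @export
cv_shap_importance <- function(X, y, params = NULL, outer_folds = 5,
                               repeats = 1, seed = 1) {
  X <- as.matrix(X)
  acc <- matrix(0, nrow = repeats * outer_folds, ncol = ncol(X))
  row <- 0L
  for (r in seq_len(repeats)) {
    set.seed(seed + (r - 1L))
    folds <- .make_folds(nrow(X), outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- folds != f
      m <- fit_gbt(X[tr, , drop = FALSE], y[tr], params)
      sh <- shap_importance(m, X[!tr, , drop = FALSE])
      row <- row + 1L
      acc[row, ] <- sh$importance[colnames(X)]
    }
  }
  sort(stats::setNames(colMeans(acc), colnames(X)), decreasing = TRUE)
}

#' Cross-model importance table
#'
#' Combines per-model importance vectors (e.g. one per (r1, r2) radii pair)
#' into a feature x model table: importances are normalized per model to its
#' maximum, features are ordered by their average normalized importance
#' across models, and the top-K rows are kept.
#'
#' @param importances named list of named importance vectors over a common
#'   feature set.
#' @param top_k rows to keep (default 20).
#' @return matrix (top-K features x models), ordered by row mean, attribute
#'   `normalization = "per-model max"`.
#' @export
importance_heatmap <- function(importances, top_k = 20) {
  stopifnot(length(importances) >= 1)
  feats <- names(importances[[1]])
  mat <- vapply(importances, function(v) {
    v <- v[feats]
    mx <- max(v)
    if (mx > 0) v / mx else v
  }, numeric(length(feats)))
  mat <- matrix(mat, nrow = length(feats),
                dimnames = list(feats, names(importances)))
  ord <- order(rowMeans(mat), decreasing = TRUE)
  out <- mat[ord, , drop = FALSE][seq_len(min(top_k, length(feats))), ,
                                  drop = FALSE]
  attr(out, "normalization") <- "per-model max"
  out
}

#' Spearman correlation of each feature with the reduction potential
#'
#' Per-feature rank correlation against the target; values near -1 mean
#' higher descriptor values go with lower RP and vice versa. Constant
#' features are undefined and returned as `NA`.
#'
#' @param X design matrix (>= 3 rows).
#' @param y reduction potentials (mV).
#' @return named numeric vector of Spearman correlations.
#' @export
spearman_feature_rp <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 rows")
  apply(X, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(col, y, method = "spearman")
  })
}
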