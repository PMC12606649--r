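# Training and evaluation protocol: nested cross-validation with a fixed
# hyperparameter grid (inner loop tunes by MAE, outer loop estimates
# generalization), repeated with reshuffled folds; radii scanning, spatial-
# scale ablations, leave-protein-out and leave-mutant-set-out tests, and the
# pairwise Mann-Whitney comparison of model variants.

#' The replication hyperparameter grid
#'
#' Tree depth 3/4/5, 100/150/200 boosting rounds, learning rate
#' 0.01/0.1/0.2/0.4 and minimum child weight 1/5/10 — 108 configurations,
#' designed to promote regularization when features outnumber samples.
#'
#' @return named list of candidate values per hyperparameter.
#' @export
default_hyper_grid <- function() {
  list(max_depth = c(3L, 4L, 5L),
       n_estimators = c(100L, 150L, 200L),
       learning_rate = c(0.01, 0.1, 0.2, 0.4),
       min_child_weight = c(1, 5, 10))
}

#' Enumerate a hyperparameter grid
#'
#' Full cartesian product in deterministic lexicographic order over the field
#' order (max_depth, n_estimators, learning_rate, min_child_weight).
#'
#' @param grid named list as from [default_hyper_grid()].
#' @return data.frame with one row per configuration.
#' @examples
#' nrow(enumerate_grid(default_hyper_grid()))  # 108
#' @export
enumerate_grid <- function(grid) {
  fields <- c("max_depth", "n_estimators", "learning_rate", "min_child_weight")
  stopifnot(all(fields %in% names(grid)),
            all(lengths(grid[fields]) >= 1))
  g <- expand.grid(min_child_weight = grid$min_child_weight,
                   learning_rate = grid$learning_rate,
                   n_estimators = grid$n_estimators,
                   max_depth = grid$max_depth,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(colnames(g))]
  rownames(g) <- NULL
  g
}

#' Regression performance metrics
#'
#' MAE (mean absolute error), RMSE, the coefficient of determination
#' R^2 = 1 - SSE/SST, and the Spearman rank correlation between observed and
#' predicted values. With a constant observed vector R^2 and SC are undefined
#' and returned as `NA` with attribute `undefined = TRUE`.
#'
#' @param y_true observed values (mV).
#' @param y_pred predicted values (mV), same length, length >= 2.
#' @return named numeric vector `c(mae, rmse, r2, sc)`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) < 2) stop("need at least 2 observations")
  d <- y_true - y_pred
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  undefined <- stats::sd(y_true) == 0
  r2 <- if (undefined) NA_real_ else 1 - sum(d^2) / sum((y_true - mean(y_true))^2)
  sc <- if (undefined || stats::sd(y_pred) == 0) NA_real_ else
    stats::cor(y_true, y_pred, method = "spearman")
  out <- c(mae = mae, rmse = rmse, r2 = r2, sc = sc)
  attr(out, "undefined") <- undefined
  out
}

# ---- model fitting ---------------------------------------------------------

.fit_model <- function(X, y, kind, params = NULL) {
  if (kind == "gbt") {
    if (is.null(params))
      params <- list(max_depth = 4L, n_estimators = 150L,
                     learning_rate = 0.1, min_child_weight = 5)
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(max_depth = as.integer(params$max_depth),
                    eta = params$learning_rate,
                    min_child_weight = params$min_child_weight,
                    objective = "reg:squarederror", nthread = 1),
      data = dtrain, nrounds = as.integer(params$n_estimators), verbose = 0)
    list(kind = "gbt", booster = booster, params = params,
         feature_names = colnames(X))
  } else if (kind == "linear") {
    if (ncol(X) < nrow(X) - 1 || length(y) < 3 || stats::sd(y) == 0) {
      fit <- stats::lm.fit(cbind(1, X), y)
      list(kind = "ols", coef = fit$coefficients,
           feature_names = colnames(X))
    } else {
      # wide matrix: ordinary least squares is ill-posed, ridge fallback
      cv <- glmnet::cv.glmnet(X, y, alpha = 0, nfolds = 5)
      list(kind = "ridge", fit = cv, feature_names = colnames(X))
    }
  } else stop("unknown model kind: ", kind)
}

.predict_model <- function(model, X) {
  X <- X[, model$feature_names, drop = FALSE]
  if (model$kind == "gbt") {
    as.numeric(stats::predict(model$booster, X))
  } else if (model$kind == "ols") {
    b <- model$coef
    b[is.na(b)] <- 0
    as.numeric(cbind(1, X) %*% b)
  } else {
    as.numeric(stats::predict(model$fit, newx = X, s = "lambda.min"))
  }
}

.make_folds <- function(n, k) sample(rep(seq_len(k), length.out = n))

# inner grid search minimizing cross-validated MAE; deterministic tie-break:
# first configuration in grid order
.tune <- function(X, y, kind, grid_df, inner_folds, seed) {
  if (kind != "gbt" || is.null(grid_df) || nrow(grid_df) <= 1)
    return(if (is.null(grid_df) || !nrow(grid_df)) NULL
           else as.list(grid_df[1, ]))
  set.seed(seed)
  folds <- .make_folds(nrow(X), inner_folds)
  maes <- numeric(nrow(grid_df))
  for (g in seq_len(nrow(grid_df))) {
    params <- as.list(grid_df[g, ])
    errs <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      m <- .fit_model(X[tr, , drop = FALSE], y[tr], kind, params)
      errs[f] <- mean(abs(y[!tr] - .predict_model(m, X[!tr, , drop = FALSE])))
    }
    maes[g] <- mean(errs)
  }
  as.list(grid_df[which.min(maes), ])
}

# ---- nested cross-validation ----------------------------------------------

#' Nested cross-validated model evaluation
#'
#' The evaluation protocol: an outer k-fold split estimates generalization;
#' inside each outer training set an inner k-fold grid search selects the
#' hyperparameters minimizing MAE, the tuned model is refit on the whole outer
#' training set and scored on the held-out fold. The entire procedure is
#' repeated with reshuffled folds. Metrics are aggregated as mean and sd over
#' all outer folds x repeats; every row is predicted out-of-fold exactly once
#' per repeat. Train/test disjointness is asserted programmatically for every
#' split.
#'
#' @param x an `fes_design` from [build_design_matrix()], or a numeric matrix.
#' @param y target vector (mV); ignored when `x` is an `fes_design`.
#' @param model `"gbt"` (gradient-boosted trees) or `"linear"` (least squares
#'   with ridge fallback for wide matrices).
#' @param grid hyperparameter grid (list as [default_hyper_grid()]); used for
#'   `"gbt"` only.
#' @param outer_folds,inner_folds,repeats cross-validation geometry
#'   (replication protocol: 5, 10, 10).
#' @param seed base seed; fixing it reproduces fold assignments, selected
#'   hyperparameters and metrics bit-identically.
#' @param classes optional per-row class labels for per-class MAE.
#' @return object of class `fes_eval`: `folds` (per outer fold x repeat:
#'   metrics and chosen hyperparameters), `metrics` (mean and sd per metric),
#'   `oof` (out-of-fold prediction matrix, rows x repeats), `per_class_mae`,
#'   `leakage_checked`, `wall_time_s`, and the configuration.
#' @export
nested_cv <- function(x, y = NULL, model = c("gbt", "linear"),
                      grid = default_hyper_grid(),
                      outer_folds = 5, inner_folds = 10, repeats = 10,
                      seed = 1, classes = NULL) {
  model <- match.arg(model)
  if (inherits(x, "fes_design")) {
    if (is.null(classes)) classes <- x$classes
    y <- x$y
    X <- x$X
  } else X <- as.matrix(x)
  n <- nrow(X)
  if (n < outer_folds) stop("fewer rows than outer folds")
  grid_df <- if (model == "gbt") enumerate_grid(grid) else NULL
  t0 <- proc.time()[["elapsed"]]
  fold_rows <- list()
  oof <- matrix(NA_real_, nrow = n, ncol = repeats)
  leakage_checked <- TRUE
  for (r in seq_len(repeats)) {
    set.seed(seed + (r - 1L))
    folds <- .make_folds(n, outer_folds)
    if (min(table(folds)) < 2) stop("degenerate outer fold (fewer than 2 rows)")
    for (f in seq_len(outer_folds)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      if (length(intersect(tr, te)) != 0)
        stop("leakage detected: train and test overlap")
      params <- .tune(X[tr, , drop = FALSE], y[tr], model, grid_df,
                      inner_folds, seed = seed + 1000L * r + f)
      m <- .fit_model(X[tr, , drop = FALSE], y[tr], model, params)
      pred <- .predict_model(m, X[te, , drop = FALSE])
      oof[te, r] <- pred
      met <- regression_metrics(y[te], pred)
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, mae = met["mae"], rmse = met["rmse"],
        r2 = met["r2"], sc = met["sc"],
        max_depth = if (is.null(params)) NA else params$max_depth,
        n_estimators = if (is.null(params)) NA else params$n_estimators,
        learning_rate = if (is.null(params)) NA else params$learning_rate,
        min_child_weight = if (is.null(params)) NA else params$min_child_weight,
        stringsAsFactors = FALSE)
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  rownames(folds_df) <- NULL
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE)
                       else NA_real_)
  metrics <- rbind(mae = agg(folds_df$mae), rmse = agg(folds_df$rmse),
                   r2 = agg(folds_df$r2), sc = agg(folds_df$sc))
  per_class_mae <- NULL
  if (!is.null(classes)) {
    res <- abs(sweep(oof, 1, y))
    per_class_mae <- tapply(rowMeans(res, na.rm = TRUE), classes, mean)
  }
  structure(list(
    folds = folds_df, metrics = metrics, oof = oof,
    per_class_mae = per_class_mae,
    r2_undefined = all(is.na(folds_df$r2)),
    leakage_checked = leakage_checked,
    model = model, outer_folds = outer_folds, inner_folds = inner_folds,
    repeats = repeats, seed = seed, n = n, p = ncol(X),
    grid_size = if (is.null(grid_df)) 0L else nrow(grid_df),
    library_defaults = "xgboost defaults for subsample, colsample, lambda, alpha, gamma",
    wall_time_s = proc.time()[["elapsed"]] - t0),
    class = "fes_eval")
}

#' @exportS3Method base::print
print.fes_eval <- function(x, ...) {
  cat("<fes_eval> ", x$model, ", ", x$n, " x ", x$p, "; ",
      x$outer_folds, "-fold outer / ", x$inner_folds, "-fold inner, ",
      x$repeats, " repeat(s)\n", sep = "")
  m <- x$metrics
  cat(sprintf("  MAE  %6.1f +/- %.1f mV\n", m["mae", "mean"], m["mae", "sd"]))
  cat(sprintf("  RMSE %6.1f +/- %.1f mV\n", m["rmse", "mean"], m["rmse", "sd"]))
  if (!x$r2_undefined) {
    cat(sprintf("  R2   %6.2f +/- %.2f\n", m["r2", "mean"], m["r2", "sd"]))
    cat(sprintf("  SC   %6.2f +/- %.2f\n", m["sc", "mean"], m["sc", "sd"]))
  } else cat("  R2/SC undefined (constant target)\n")
  invisible(x)
}

# ---- radii scan ------------------------------------------------------------

#' Scan model performance over the radii grids
#'
#' Evaluates the strategy-A model at every (r1, r2) combination. Features are
#' computed once per structure across all radii (the strategy-B union) and
#' each cell's design matrix is the corresponding column subset, so the scan
#' costs one featurization pass plus one nested CV per cell.
#'
#' @inheritParams build_design_matrix
#' @inheritParams nested_cv
#' @param r1_grid,r2_grid radii grids (replication: 8:16 and 3:5 Angstrom).
#' @return list of class `fes_radii_scan`: `table` (one row per cell with
#'   metric means/sds), `best` (r1, r2 of minimal mean MAE), `evals` (named
#'   list of `fes_eval`).
#' @export
scan_radii <- function(entries, structures, model = "gbt",
                       grid = default_hyper_grid(),
                       r1_grid = 8:16, r2_grid = 3:5,
                       outer_folds = 5, inner_folds = 10, repeats = 10,
                       seed = 1, table = aa_properties(), rule = "any") {
  designB <- build_design_matrix(entries, structures, strategy = "B",
                                 table = table, rule = rule)
  rows <- list(); evals <- list()
  for (r1 in r1_grid) for (r2 in r2_grid) {
    if (r2 >= r1) next
    sa <- feature_schema("A", r1 = r1, r2 = r2)
    bnames <- schema_a_names_in_b(sa)
    X <- designB$X[, bnames, drop = FALSE]
    colnames(X) <- sa$name
    ev <- nested_cv(X, designB$y, model = model, grid = grid,
                    outer_folds = outer_folds, inner_folds = inner_folds,
                    repeats = repeats, seed = seed, classes = designB$classes)
    key <- sprintf("r1=%d,r2=%d", r1, r2)
    evals[[key]] <- ev
    rows[[key]] <- data.frame(r1 = r1, r2 = r2,
                              mae_mean = ev$metrics["mae", "mean"],
                              mae_sd = ev$metrics["mae", "sd"],
                              rmse_mean = ev$metrics["rmse", "mean"],
                              r2_mean = ev$metrics["r2", "mean"],
                              sc_mean = ev$metrics["sc", "mean"])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- tab[which.min(tab$mae_mean), c("r1", "r2")]
  structure(list(table = tab, best = best, evals = evals),
            class = "fes_radii_scan")
}

# ---- scale ablations -------------------------------------------------------

#' Spatial-scale masks for ablation experiments
#'
#' The seven replication variants: the full model, each scale removed in turn,
#' and each scale alone. pH (a condition feature, not a structural scale) is
#' retained in every variant.
#'
#' @return named list of masks `list(long =, medium =, short =)`.
#' @export
default_scale_masks <- function() {
  list(full = list(long = TRUE, medium = TRUE, short = TRUE),
       no_long = list(long = FALSE, medium = TRUE, short = TRUE),
       no_medium = list(long = TRUE, medium = FALSE, short = TRUE),
       no_short = list(long = TRUE, medium = TRUE, short = FALSE),
       short_only = list(long = FALSE, medium = FALSE, short = TRUE),
       medium_only = list(long = FALSE, medium = TRUE, short = FALSE),
       long_only = list(long = TRUE, medium = FALSE, short = FALSE))
}

.mask_columns <- function(schema, mask) {
  keep <- schema$scale == "condition"
  if (isTRUE(mask$long)) keep <- keep | schema$scale == "long"
  if (isTRUE(mask$medium)) keep <- keep | schema$scale == "medium"
  if (isTRUE(mask$short)) keep <- keep | schema$scale == "short"
  if (!any(schema$scale[keep] != "condition"))
    stop("mask removes all structural features")
  schema$name[keep]
}

#' Ablate descriptor scales and re-evaluate
#'
#' Runs the nested-CV evaluation on column subsets of a design matrix defined
#' by spatial-scale masks (long / medium / short; condition features always
#' retained), preserving the mask order for downstream pairwise comparison.
#'
#' @param design an `fes_design`.
#' @param masks named list of masks (default [default_scale_masks()]).
#' @inheritParams nested_cv
#' @return list of class `fes_ablation`: `table` (mask, n features, metric
#'   summaries), `evals`, `fold_maes` (named list of per-fold MAE vectors).
#' @export
ablate_scales <- function(design, masks = default_scale_masks(),
                          model = "gbt", grid = default_hyper_grid(),
                          outer_folds = 5, inner_folds = 10, repeats = 10,
                          seed = 1) {
  stopifnot(inherits(design, "fes_design"))
  rows <- list(); evals <- list(); fold_maes <- list()
  for (nm in names(masks)) {
    cols <- .mask_columns(design$schema, masks[[nm]])
    ev <- nested_cv(design$X[, cols, drop = FALSE], design$y, model = model,
                    grid = grid, outer_folds = outer_folds,
                    inner_folds = inner_folds, repeats = repeats, seed = seed,
                    classes = design$classes)
    evals[[nm]] <- ev
    fold_maes[[nm]] <- ev$folds$mae
    rows[[nm]] <- data.frame(mask = nm, n_features = length(cols),
                             mae_mean = ev$metrics["mae", "mean"],
                             mae_sd = ev$metrics["mae", "sd"],
                             r2_mean = ev$metrics["r2", "mean"])
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, evals = evals, fold_maes = fold_maes),
            class = "fes_ablation")
}

# ---- held-out generalization tests ----------------------------------------

#' Leave-protein-out evaluation
#'
#' Removes every entry (wild type and mutants) of the held-out proteins from
#' training, tunes on the remainder with an inner grid search, and predicts
#' all held-out entries de novo.
#'
#' @param design an `fes_design`.
#' @param held_out character vector of parent protein ids to exclude.
#' @inheritParams nested_cv
#' @return list: `per_protein_mae`, `overall_mae`, `predictions` (data.frame
#'   with entry id, protein, observed, predicted), `params`.
#' @export
leave_proteins_out <- function(design, held_out, model = "gbt",
                               grid = default_hyper_grid(),
                               inner_folds = 10, seed = 1) {
  stopifnot(inherits(design, "fes_design"))
  if (!length(held_out)) stop("held-out protein set is empty")
  if (!all(held_out %in% design$groups))
    stop("held-out proteins not in data set: ",
         paste(setdiff(held_out, design$groups), collapse = ", "))
  te <- design$groups %in% held_out
  if (all(te)) stop("cannot hold out every protein")
  tr <- which(!te); te <- which(te)
  stopifnot(length(intersect(tr, te)) == 0)
  grid_df <- if (model == "gbt") enumerate_grid(grid) else NULL
  params <- .tune(design$X[tr, , drop = FALSE], design$y[tr], model, grid_df,
                  inner_folds, seed = seed)
  m <- .fit_model(design$X[tr, , drop = FALSE], design$y[tr], model, params)
  pred <- .predict_model(m, design$X[te, , drop = FALSE])
  df <- data.frame(entry_id = design$entries$entry_id[te],
                   protein_id = design$groups[te],
                   observed = design$y[te], predicted = pred,
                   stringsAsFactors = FALSE)
  per_protein <- tapply(abs(df$observed - df$predicted), df$protein_id, mean)
  list(per_protein_mae = per_protein,
       overall_mae = mean(abs(df$observed - df$predicted)),
       predictions = df, params = params)
}

#' Leave-mutant-set-out evaluation
#'
#' Excludes selected mutant entries from training (their wild types remain),
#' predicts them, and compares the predicted direction of the mutational
#' reduction-potential shift (prediction for the mutant minus prediction for
#' its wild-type entry at the closest pH) with the experimental one. Mutants
#' whose experimental shift is within the dead-band are classified as
#' "unchanged" and excluded from the sign-agreement rate.
#'
#' @param design an `fes_design`.
#' @param mutant_entries entry ids of the mutants to hold out.
#' @param dead_band absolute experimental shift (mV) below which a mutant
#'   counts as essentially unchanged (default 5 mV).
#' @inheritParams leave_proteins_out
#' @return list: `mae` over held-out mutants, `sign_agreement` (rate over
#'   mutants outside the dead-band), `table` (per-mutant observed/predicted
#'   shifts and classification).
#' @export
leave_mutants_out <- function(design, mutant_entries, dead_band = 5,
                              model = "gbt", grid = default_hyper_grid(),
                              inner_folds = 10, seed = 1) {
  stopifnot(inherits(design, "fes_design"))
  ent <- design$entries
  idx <- match(mutant_entries, ent$entry_id)
  if (anyNA(idx)) stop("unknown entry ids: ",
                       paste(mutant_entries[is.na(idx)], collapse = ", "))
  if (any(ent$mutation[idx] == "WT"))
    stop("held-out entries must be mutants")
  for (i in idx) {
    wt <- which(ent$protein_id == ent$protein_id[i] & ent$mutation == "WT")
    if (!length(wt))
      stop("wild type missing from training for protein ", ent$protein_id[i])
  }
  tr <- setdiff(seq_len(nrow(ent)), idx)
  grid_df <- if (model == "gbt") enumerate_grid(grid) else NULL
  params <- .tune(design$X[tr, , drop = FALSE], design$y[tr], model, grid_df,
                  inner_folds, seed = seed)
  m <- .fit_model(design$X[tr, , drop = FALSE], design$y[tr], model, params)
  rows <- list()
  for (i in idx) {
    wt <- which(ent$protein_id == ent$protein_id[i] & ent$mutation == "WT")
    wt <- wt[which.min(abs(ent$ph[wt] - ent$ph[i]))]
    p_mut <- .predict_model(m, design$X[i, , drop = FALSE])
    p_wt <- .predict_model(m, design$X[wt, , drop = FALSE])
    d_exp <- design$y[i] - design$y[wt]
    d_pred <- p_mut - p_wt
    rows[[length(rows) + 1L]] <- data.frame(
      entry_id = ent$entry_id[i], protein_id = ent$protein_id[i],
      observed = design$y[i], predicted = p_mut,
      shift_exp = d_exp, shift_pred = d_pred,
      classification = if (abs(d_exp) < dead_band) "unchanged"
      else if (d_exp > 0) "increase" else "decrease",
      sign_agrees = abs(d_exp) >= dead_band && sign(d_exp) == sign(d_pred),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  changed <- tab$classification != "unchanged"
  list(mae = mean(abs(tab$observed - tab$predicted)),
       sign_agreement = if (any(changed)) mean(tab$sign_agrees[changed])
       else NA_real_,
       table = tab, params = params)
}

# ---- model comparison and diagnostics --------------------------------------

#' Pairwise Mann-Whitney comparison of model variants
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests between every pair of
#' per-fold MAE samples; exact p-values for untied small samples. The matrix
#' is symmetric with unit diagonal.
#'
#' @param results named list of numeric vectors (per-fold MAEs per variant),
#'   each of length >= 3.
#' @return symmetric matrix of p-values.
#' @export
compare_models_mw <- function(results) {
  if (length(results) < 2) stop("need at least two result sets")
  if (any(lengths(results) < 3)) stop("each result set needs >= 3 values")
  k <- length(results)
  p <- matrix(1, k, k, dimnames = list(names(results), names(results)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pij <- suppressWarnings(
      stats::wilcox.test(results[[i]], results[[j]],
                         alternative = "two.sided")$p.value)
    p[i, j] <- pij
    p[j, i] <- pij
  }
  p
}

#' Correlation between prediction error and crystallographic resolution
#'
#' Spearman correlation of absolute prediction errors with resolution over the
#' entries that have a reported resolution; a diagnostic that poorly
#' determined structures are not biasing the model.
#'
#' @param abs_errors absolute prediction errors (mV).
#' @param resolutions resolutions (Angstrom), `NA` allowed.
#' @return list: `sc`, `p_value`, `n` (resolved entries used), `undefined`
#'   (TRUE when either variable is constant).
#' @export
error_vs_resolution <- function(abs_errors, resolutions) {
  ok <- is.finite(abs_errors) & is.finite(resolutions)
  if (sum(ok) < 3) stop("need at least 3 entries with resolution")
  e <- abs_errors[ok]; r <- resolutions[ok]
  if (stats::sd(e) == 0 || stats::sd(r) == 0)
    return(list(sc = NA_real_, p_value = NA_real_, n = sum(ok),
                undefined = TRUE))
  ct <- suppressWarnings(stats::cor.test(e, r, method = "spearman"))
  list(sc = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       undefined = FALSE)
}
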