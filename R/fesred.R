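# The user-facing model interface: fesred() runs the whole protocol -- design
# matrix assembly, nested cross-validated evaluation, and a final tuned fit on
# all entries -- and returns one classed object with the usual methods.

#' Fit and evaluate a reduction-potential model
#'
#' The main entry point. Builds the descriptor design matrix for the entries
#' (strategy A at fixed radii, or strategy B across all radii), estimates
#' generalization performance by repeated nested cross-validation (inner grid
#' search minimizing MAE, outer folds scored out-of-fold), and fits a final
#' model on all entries with hyperparameters tuned by inner CV on the full
#' set. The returned object supports `print`, `summary`, `predict`,
#' `fitted`, `residuals`, `plot` and (for the linear baseline) `coef`.
#'
#' @param data entries: a path to a delimited table (see [load_dataset()]),
#'   an entry data.frame, or a prebuilt `fes_design` (then `structures` is
#'   ignored).
#' @param structures named list of `fes_structure` objects or a directory of
#'   PDB files.
#' @param strategy `"A"` (one model per radii pair; default radii are the
#'   best-performing combination r1 = 11, r2 = 4) or `"B"` (all radii at
#'   once).
#' @param r1,r2 strategy-A radii, Angstrom.
#' @param model `"gbt"` or `"linear"`.
#' @param grid hyperparameter grid (see [default_hyper_grid()]).
#' @param outer_folds,inner_folds,repeats nested-CV geometry (replication
#'   protocol: 5, 10, 10).
#' @param technique include the one-hot measurement-technique block.
#' @param seed base seed; the whole fit is bit-reproducible given it.
#' @param table residue property table.
#' @param rule residue-to-region assignment rule.
#' @return object of class `fesred`.
#' @examples
#' \donttest{
#' ds <- make_synthetic_dataset(synthetic_rp_spec(n_proteins = 6,
#'   mutants_per_protein = 1, seed = 7))
#' fit <- fesred(ds$entries, ds$structures, repeats = 1, inner_folds = 2,
#'               grid = list(max_depth = 3, n_estimators = 50,
#'                           learning_rate = 0.2, min_child_weight = 5))
#' fit
#' }
#' @export
fesred <- function(data, structures = NULL, strategy = c("A", "B"),
                   r1 = 11, r2 = 4, model = c("gbt", "linear"),
                   grid = default_hyper_grid(),
                   outer_folds = 5, inner_folds = 10, repeats = 10,
                   technique = FALSE, seed = 1,
                   table = aa_properties(), rule = "any") {
  strategy <- match.arg(strategy)
  model <- match.arg(model)
  cl <- match.call()
  design <- if (inherits(data, "fes_design")) data else {
    entries <- if (is.character(data)) load_dataset(data) else data
    build_design_matrix(entries, structures, strategy = strategy,
                        r1 = r1, r2 = r2, technique = technique,
                        table = table, rule = rule)
  }
  eval <- nested_cv(design, model = model, grid = grid,
                    outer_folds = outer_folds, inner_folds = inner_folds,
                    repeats = repeats, seed = seed)
  grid_df <- if (model == "gbt") enumerate_grid(grid) else NULL
  final_params <- .tune(design$X, design$y, model, grid_df, inner_folds,
                        seed = seed)
  final_model <- .fit_model(design$X, design$y, model, final_params)
  if (model == "gbt") class(final_model) <- "fes_gbt_model"
  structure(list(call = cl, design = design, eval = eval,
                 final_model = final_model, final_params = final_params,
                 model = model, strategy = strategy,
                 r1 = if (strategy == "A") r1 else NA,
                 r2 = if (strategy == "A") r2 else NA,
                 technique = technique, rule = rule, seed = seed),
            class = "fesred")
}

#' @exportS3Method base::print
print.fesred <- function(x, ...) {
  cat("Reduction-potential model (", x$model,
      if (x$strategy == "A")
        sprintf(", strategy A, r1 = %s A, r2 = %s A", x$r1, x$r2)
      else ", strategy B (all radii)", ")\n", sep = "")
  cat("  ", x$eval$n, " entries, ", x$eval$p, " features, ",
      length(unique(x$design$groups)), " parent proteins\n", sep = "")
  m <- x$eval$metrics
  cat(sprintf("  nested CV: MAE %.1f +/- %.1f mV, RMSE %.1f +/- %.1f mV",
              m["mae", "mean"], m["mae", "sd"],
              m["rmse", "mean"], m["rmse", "sd"]), "\n")
  if (!x$eval$r2_undefined)
    cat(sprintf("             R2 %.2f +/- %.2f, SC %.2f +/- %.2f\n",
                m["r2", "mean"], m["r2", "sd"],
                m["sc", "mean"], m["sc", "sd"]))
  invisible(x)
}

#' @exportS3Method base::summary
summary.fesred <- function(object, ...) {
  sel <- object$eval$folds[, c("max_depth", "n_estimators", "learning_rate",
                               "min_child_weight")]
  structure(list(metrics = object$eval$metrics,
                 per_class_mae = object$eval$per_class_mae,
                 selected_hyperparameters = if (object$model == "gbt")
                   unique(sel) else NULL,
                 final_params = object$final_params,
                 model = object$model, n = object$eval$n, p = object$eval$p,
                 repeats = object$eval$repeats,
                 outer_folds = object$eval$outer_folds),
            class = "summary.fesred")
}

#' @exportS3Method base::print
print.summary.fesred <- function(x, ...) {
  cat("Nested cross-validation (", x$outer_folds, " outer folds x ",
      x$repeats, " repeats, model ", x$model, ")\n", sep = "")
  print(round(x$metrics, 3))
  if (!is.null(x$per_class_mae)) {
    cat("\nPer-class MAE (mV):\n")
    print(round(x$per_class_mae, 1))
  }
  if (!is.null(x$selected_hyperparameters)) {
    cat("\nHyperparameters selected across outer folds:\n")
    print(x$selected_hyperparameters, row.names = FALSE)
  }
  invisible(x)
}

#' Predict reduction potentials for new entries
#'
#' @param object a fitted [fesred()] model.
#' @param newdata new entries (data.frame in the entry-table dialect) with
#'   `structures`, a prebuilt `fes_design`, or a bare feature matrix; `NULL`
#'   returns the in-sample predictions of the final model.
#' @param structures structures for `newdata` (list or directory).
#' @param ... unused.
#' @return numeric vector of predicted RP (mV).
#' @export
predict.fesred <- function(object, newdata = NULL, structures = NULL, ...) {
  X <- if (is.null(newdata)) {
    object$design$X
  } else if (inherits(newdata, "fes_design")) {
    newdata$X
  } else if (is.matrix(newdata)) {
    newdata
  } else {
    build_design_matrix(newdata, structures, strategy = object$strategy,
                        r1 = object$r1, r2 = object$r2,
                        technique = object$technique, rule = object$rule)$X
  }
  .predict_model(unclass(object$final_model), X)
}

#' @export
fitted.fesred <- function(object, ...) {
  stats::setNames(.predict_model(unclass(object$final_model),
                                 object$design$X),
                  object$design$entries$entry_id)
}

#' Residuals of a reduction-potential model
#'
#' @param object a fitted [fesred()] model.
#' @param type `"oof"` (default): observed minus the out-of-fold prediction
#'   averaged over repeats — the honest generalization residual; `"final"`:
#'   observed minus the in-sample prediction of the final model.
#' @param ... unused.
#' @return named numeric vector (mV).
#' @export
residuals.fesred <- function(object, type = c("oof", "final"), ...) {
  type <- match.arg(type)
  pred <- if (type == "oof") rowMeans(object$eval$oof, na.rm = TRUE)
  else .predict_model(unclass(object$final_model), object$design$X)
  stats::setNames(object$design$y - pred, object$design$entries$entry_id)
}

#' @export
coef.fesred <- function(object, ...) {
  fm <- unclass(object$final_model)
  if (identical(fm$kind, "ols")) {
    stats::setNames(fm$coef, c("(Intercept)", fm$feature_names))
  } else if (identical(fm$kind, "ridge")) {
    b <- as.numeric(stats::coef(fm$fit, s = "lambda.min"))
    stats::setNames(b, c("(Intercept)", fm$feature_names))
  } else {
    stop("coefficients are defined for the linear baseline only")
  }
}

#' Observed versus predicted reduction potentials
#'
#' Scatter of out-of-fold predictions (averaged over repeats) against
#' observed values, colored by protein class, with the identity line.
#'
#' @param x a fitted [fesred()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fesred <- function(x, ...) {
  obs <- x$design$y
  pred <- rowMeans(x$eval$oof, na.rm = TRUE)
  cls <- factor(x$design$classes)
  cols <- grDevices::hcl.colors(max(2L, nlevels(cls)), "Dark 3")
  graphics::plot(obs, pred, col = cols[as.integer(cls)], pch = 16,
                 xlab = "experimental RP (mV)",
                 ylab = "predicted RP (mV, out-of-fold)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = levels(cls),
                   col = cols[seq_len(nlevels(cls))], pch = 16, bty = "n")
  invisible(x)
}
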