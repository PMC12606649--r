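# Grid enumeration, metrics, nested cross-validation, radii scan, ablations,
# hold-out evaluations and model comparison.

test_that("grid enumeration is the deterministic cartesian product", {
  expect_equal(nrow(enumerate_grid(default_hyper_grid())), 108L)
  one <- list(max_depth = 3, n_estimators = 100, learning_rate = 0.1,
              min_child_weight = 1)
  expect_equal(nrow(enumerate_grid(one)), 1L)
  two <- list(max_depth = c(3, 5), n_estimators = c(100, 200),
              learning_rate = c(0.1, 0.4), min_child_weight = c(1, 10))
  g <- enumerate_grid(two)
  expect_equal(nrow(g), 16L)
  # pure function of the grid: identical on re-enumeration
  expect_identical(g, enumerate_grid(two))
  # lexicographic over (max_depth, n_estimators, learning_rate, mcw)
  expect_equal(g$max_depth, rep(c(3, 5), each = 8))
  expect_equal(g$min_child_weight[1:2], c(1, 10))
})

test_that("metrics match an independent reimplementation", {
  y <- c(10, 20, 30, 40)
  expect_equal(as.numeric(regression_metrics(y, y)),
               c(0, 0, 1, 1))
  # symmetric-error example
  m <- regression_metrics(c(50, 50 + 1e-9), c(0, 100))
  expect_equal(unname(m["mae"]), 50, tolerance = 1e-6)
  # reference implementation written out longhand
  set.seed(99)
  yt <- rnorm(20, 0, 50); yp <- yt + rnorm(20, 0, 10)
  m2 <- regression_metrics(yt, yp)
  mae_ref <- sum(abs(yt - yp)) / 20
  rmse_ref <- sqrt(sum((yt - yp)^2) / 20)
  r2_ref <- 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2)
  sc_ref <- cor(rank(yt), rank(yp))
  expect_equal(as.numeric(m2), c(mae_ref, rmse_ref, r2_ref, sc_ref),
               tolerance = 1e-9)
  expect_error(regression_metrics(1:3, 1:4), "equal length")
  # constant truth: R2/SC undefined-flagged
  mc <- regression_metrics(rep(5, 4), c(4, 5, 6, 5))
  expect_true(is.na(mc["r2"]))
  expect_true(attr(mc, "undefined"))
})

test_that("nested CV recovers a noiseless linear target almost exactly", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("f", 1:5)))
  y <- drop(X %*% c(3, -2, 1, 0.5, -1)) + 10
  ev <- nested_cv(X, y, model = "linear", outer_folds = 5, repeats = 2,
                  seed = 3)
  expect_gte(ev$metrics["r2", "mean"], 0.999)
  expect_lt(ev$metrics["mae", "mean"], 1e-6)
})

test_that("label permutation drives R2 to zero and RMSE >= MAE holds", {
  set.seed(8)
  X <- matrix(rnorm(80 * 4), 80, dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(drop(X %*% c(5, 5, 5, 5)))  # permuted: no signal
  ev <- nested_cv(X, y, model = "linear", outer_folds = 5, repeats = 3,
                  seed = 4)
  expect_lt(abs(ev$metrics["r2", "mean"]), 0.45)
  expect_true(all(ev$folds$rmse >= ev$folds$mae))
})

test_that("constant targets flag R2 as undefined without failing", {
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(7, 40)
  ev <- nested_cv(X, y, model = "gbt", grid = tiny_grid(), outer_folds = 4,
                  inner_folds = 2, repeats = 1, seed = 5)
  expect_true(ev$r2_undefined)
  expect_lt(ev$metrics["mae", "mean"], 1)
})

test_that("fixing the seed reproduces the evaluation bit-identically", {
  set.seed(9)
  X <- matrix(rnorm(50 * 6), 50, dimnames = list(NULL, paste0("f", 1:6)))
  y <- drop(X %*% rnorm(6)) * 30 + rnorm(50, 0, 5)
  ev1 <- nested_cv(X, y, model = "gbt", grid = small_grid(), outer_folds = 3,
                   inner_folds = 2, repeats = 2, seed = 11)
  ev2 <- nested_cv(X, y, model = "gbt", grid = small_grid(), outer_folds = 3,
                   inner_folds = 2, repeats = 2, seed = 11)
  expect_identical(ev1$folds, ev2$folds)
  expect_identical(ev1$oof, ev2$oof)
  ev3 <- nested_cv(X, y, model = "gbt", grid = small_grid(), outer_folds = 3,
                   inner_folds = 2, repeats = 2, seed = 12)
  expect_false(identical(ev1$folds$mae, ev3$folds$mae))
  # every row predicted out-of-fold exactly once per repeat
  expect_false(anyNA(ev1$oof))
  expect_error(nested_cv(X[1:3, ], y[1:3], outer_folds = 5), "fewer rows")
})

test_that("radii scans cover the requested cells and report the best", {
  ds <- make_synthetic_dataset(synthetic_rp_spec(
    n_proteins = 8, mutants_per_protein = 1, ph_per_entry = 2, seed = 40))
  sc <- scan_radii(ds$entries, ds$structures, model = "gbt",
                   grid = tiny_grid(), r1_grid = c(9, 12), r2_grid = 4,
                   outer_folds = 3, inner_folds = 2, repeats = 1, seed = 2)
  expect_equal(nrow(sc$table), 2L)
  expect_equal(sc$table$r1, c(9, 12))
  expect_true(sc$best$r1 %in% c(9, 12))
  # scanned cells reuse the strategy-B featurization: A-consistency spot check
  d1 <- build_design_matrix(ds$entries, ds$structures, r1 = 9, r2 = 4)
  ev <- nested_cv(d1, model = "gbt", grid = tiny_grid(), outer_folds = 3,
                  inner_folds = 2, repeats = 1, seed = 2)
  expect_equal(ev$metrics["mae", "mean"], sc$table$mae_mean[1],
               tolerance = 1e-9)
})

test_that("scale masks subset columns correctly and the full mask is a no-op", {
  ds <- make_synthetic_dataset(synthetic_rp_spec(
    n_proteins = 8, mutants_per_protein = 1, ph_per_entry = 2, seed = 41))
  design <- build_design_matrix(ds$entries, ds$structures)
  ab <- ablate_scales(design, masks = default_scale_masks()[c("full",
                                                              "short_only",
                                                              "long_only")],
                      model = "gbt", grid = tiny_grid(), outer_folds = 3,
                      inner_folds = 2, repeats = 1, seed = 6)
  expect_equal(nrow(ab$table), 3L)
  sch <- design$schema
  expect_equal(ab$table$n_features[ab$table$mask == "short_only"],
               sum(sch$scale %in% c("short", "condition")))
  expect_equal(ab$table$n_features[ab$table$mask == "long_only"],
               sum(sch$scale %in% c("long", "condition")))
  # full mask reproduces plain nested CV on the full matrix
  ev <- nested_cv(design, model = "gbt", grid = tiny_grid(), outer_folds = 3,
                  inner_folds = 2, repeats = 1, seed = 6)
  expect_equal(ab$table$mae_mean[ab$table$mask == "full"],
               ev$metrics["mae", "mean"], tolerance = 1e-9)
  expect_error(ablate_scales(design,
                             masks = list(none = list(long = FALSE,
                                                      medium = FALSE,
                                                      short = FALSE))),
               "removes all")
})

test_that("ablation separates scales on a short-range-only signal", {
  # target built purely from a short-range feature: long-only must be worse
  ds <- make_synthetic_dataset(synthetic_rp_spec(
    n_proteins = 12, mutants_per_protein = 1, ph_per_entry = 2,
    support = c("CofAtom.Fe.n.his", "AroundFe.sum.steric.flex"),
    weights = c(60, -40), sigma = 5, seed = 43))
  design <- build_design_matrix(ds$entries, ds$structures)
  ab <- ablate_scales(design,
                      masks = default_scale_masks()[c("full", "long_only")],
                      model = "gbt", grid = tiny_grid(), outer_folds = 3,
                      inner_folds = 2, repeats = 3, seed = 7)
  mae <- ab$table$mae_mean
  names(mae) <- ab$table$mask
  expect_gt(mae["long_only"], mae["full"])
  # statistical confirmation on the fold-level MAEs
  p <- compare_models_mw(ab$fold_maes)
  expect_lt(p["full", "long_only"], 0.05)
})

test_that("leave-protein-out never trains on held-out entries and recovers", {
  ds <- make_synthetic_dataset(synthetic_rp_spec(
    n_proteins = 10, mutants_per_protein = 1, ph_per_entry = 2,
    sigma = 0, seed = 44))
  design <- build_design_matrix(ds$entries, ds$structures)
  held <- c("prot01", "prot02")
  # linear model on the true support: noiseless target is recovered de novo
  Xs <- design$X[, ds$true$support, drop = FALSE]
  d2 <- design
  d2$X <- Xs
  lpo <- leave_proteins_out(d2, held, model = "linear", seed = 8)
  expect_setequal(names(lpo$per_protein_mae), held)
  expect_lt(lpo$overall_mae, 1e-6)
  expect_true(all(design$groups[match(lpo$predictions$entry_id,
                                      design$entries$entry_id)] %in% held))
  expect_error(leave_proteins_out(design, character()), "empty")
  expect_error(leave_proteins_out(design, unique(design$groups)), "every")
  expect_error(leave_proteins_out(design, "nonexistent"), "not in data set")
})

test_that("leave-mutants-out reproduces injected directional shifts", {
  ds <- make_synthetic_dataset(synthetic_rp_spec(
    n_proteins = 10, mutants_per_protein = 2, ph_per_entry = 1,
    sigma = 0, seed = 45))
  design <- build_design_matrix(ds$entries, ds$structures)
  ent <- design$entries
  # linear model on the true support predicts exactly, so predicted shift
  # signs must match the generative ones outside the dead-band
  d2 <- design
  d2$X <- design$X[, ds$true$support, drop = FALSE]
  muts <- ent$entry_id[ent$mutation != "WT"][1:4]
  res <- leave_mutants_out(d2, muts, model = "linear", dead_band = 5,
                           seed = 9)
  expect_lt(res$mae, 1e-6)
  changed <- res$table$classification != "unchanged"
  if (any(changed)) expect_true(all(res$table$sign_agrees[changed]))
  # dead-band: tiny experimental shifts classify as unchanged
  small <- res$table$classification[abs(res$table$shift_exp) < 5]
  expect_true(all(small == "unchanged"))
  # a mutant entry with features identical to its WT predicts a zero shift
  ent2 <- ent[c(1, 1), ]
  ent2$entry_id <- c("wt", "mut")
  ent2$mutation <- c("WT", "A1G")
  d3 <- list(X = d2$X[c(1, 1), , drop = FALSE], y = design$y[c(1, 1)],
             groups = ent2$protein_id, classes = ent2$class,
             entries = ent2, schema = design$schema)
  class(d3) <- "fes_design"
  r3 <- leave_mutants_out(d3, "mut", model = "linear", seed = 10)
  expect_equal(r3$table$shift_pred, 0, tolerance = 1e-9)
  expect_error(leave_mutants_out(d2, ent$entry_id[ent$mutation == "WT"][1]),
               "must be mutants")
})

test_that("the exact Mann-Whitney p for fully separated triples is 0.1", {
  res <- list(a = c(1, 2, 3), b = c(101, 102, 103))
  p <- compare_models_mw(res)
  expect_equal(p["a", "b"], 0.1)
  expect_equal(p["a", "b"], p["b", "a"])
  expect_equal(unname(diag(p)), c(1, 1))
  # identical samples: p at (or extremely near) 1
  p2 <- compare_models_mw(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gte(p2["a", "b"], 0.99)
  expect_error(compare_models_mw(list(a = 1:3)), "two result sets")
  expect_error(compare_models_mw(list(a = 1:2, b = 1:3)), ">= 3")
})

test_that("error-resolution diagnostics flag degenerate inputs", {
  expect_error(error_vs_resolution(c(1, 2), c(1.5, 1.7)), "at least 3")
  r <- error_vs_resolution(rep(2, 5), c(1.2, 1.5, 1.8, 2.1, 2.4))
  expect_true(r$undefined)
  mono <- error_vs_resolution(c(1, 2, 3, 4), c(1.1, 1.4, 1.9, 2.5))
  expect_equal(mono$sc, 1)
  # null simulation: independent errors give small |SC| on average
  set.seed(13)
  scs <- replicate(30, error_vs_resolution(abs(rnorm(40)),
                                           runif(40, 1, 3))$sc)
  expect_lt(abs(mean(scs)), 0.1)
})
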