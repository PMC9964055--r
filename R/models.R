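#' Configuration for one base learner
#'
#' @param algorithm One of `"MLR"`, `"LASSO"`, `"SVR_RBF"`, `"RF"`, `"GBR"`.
#' @param features Character vector of feature names the model may use
#'   (e.g. a [cfs_select()]/[rfe_select()] subset); `NULL` means all columns.
#'   `MLR` requires an explicit subset unless `p < n` (ordinary least
#'   squares is not identifiable with more descriptors than compounds).
#' @param grid Optional tibble of hyperparameter candidates; `NULL` uses the
#'   algorithm's default grid (see Details). Columns: `lambda` (LASSO);
#'   `cost`, `gamma`, `epsilon` (SVR); `num_trees`, `mtry` (RF); `nrounds`,
#'   `max_depth`, `eta` (GBR).
#' @param seed Integer seed governing fold assignment and any stochastic
#'   fitting.
#'
#' @details Default grids: LASSO penalty log-spaced `1e-4`--`1e1` (25
#'   points); SVR cost `{0.25,0.5,1,2,4,8}` x kernel width (scale heuristic
#'   `1/(p Var)` times `{0.25,0.5,1,2,4}`) x tube width `{0.01,0.1,0.2}`;
#'   RF 500 trees with `mtry` in `{p/3, sqrt(p), p/2}`; GBR trees
#'   `100..1000` (step 150) x depth `{1,2,3}` x learning rate
#'   `{0.01,0.05,0.1}`.
#' @return A `qsrr_model_config` object.
#' @export
model_config <- function(algorithm = c("MLR", "LASSO", "SVR_RBF", "RF", "GBR"),
                         features = NULL, grid = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (!is.null(grid)) {
    grid <- tibble::as_tibble(grid)
    if (!nrow(grid)) qsrr_abort("`grid` must have at least one row.",
                                class = "qsrrkit_config_error")
  }
  structure(
    list(algorithm = algorithm, features = features, grid = grid,
         seed = as.integer(seed)),
    class = "qsrr_model_config"
  )
}

subset_features <- function(X, features) {
  if (is.null(features)) return(X)
  missing_f <- setdiff(features, colnames(X))
  if (length(missing_f)) {
    qsrr_abort(sprintf("Features missing from X: %s.",
                       paste(missing_f, collapse = ", ")))
  }
  X[, features, drop = FALSE]
}

#' Grid-search hyperparameters under k-fold cross-validation
#'
#' Evaluates every grid point on the same seeded fold assignment, scoring by
#' the mean of the per-fold RMSE on held-out folds; the point with the least
#' CV RMSE wins (ties go to the first point in grid order, so results are
#' reproducible). The final model is refit on all rows with the chosen
#' hyperparameters. Folds whose training targets are constant are skipped
#' with a warning.
#'
#' @param config A [model_config()].
#' @param X Standardized descriptor matrix/tibble (rows = compounds).
#' @param y Numeric target (retention on the modeling scale).
#' @param folds Number of CV folds (default 10).
#' @return A `qsrr_model`: fitted learner plus `chosen` hyperparameters,
#'   `cv_rmse`, `cv_r2` (from pooled out-of-fold predictions at the chosen
#'   point), and the full `grid_results` tibble.
#' @export
grid_search <- function(config, X, y, folds = 10) {
  stopifnot(inherits(config, "qsrr_model_config"))
  X <- as_descriptor_matrix(X)
  X <- subset_features(X, config$features)
  n <- nrow(X)
  if (length(y) != n) qsrr_abort("`y` length must match rows of `X`.")
  if (n < folds) {
    qsrr_abort(sprintf("Need at least `folds` (%d) observations, got %d.",
                       folds, n), class = "qsrrkit_config_error")
  }
  if (config$algorithm == "MLR" && ncol(X) >= n) {
    qsrr_abort(paste0(
      "MLR with ", ncol(X), " descriptors and ", n, " compounds is not ",
      "identifiable; select features first (CFS/RFE) or use a regularized learner."
    ))
  }
  reg <- learner_registry()[[config$algorithm]]
  grid <- config$grid %||% reg$default_grid(X)
  fold_id <- cv_folds(n, folds, seed = config$seed)

  oof <- matrix(NA_real_, n, nrow(grid))
  fold_rmse <- matrix(NA_real_, folds, nrow(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sd(y[tr]) == 0) {
      warning(sprintf("Fold %d has constant training targets; skipped.", f))
      next
    }
    for (g in seq_len(nrow(grid))) {
      fit <- reg$fit(X[tr, , drop = FALSE], y[tr], as.list(grid[g, ]),
                     seed = derive_seed(config$seed, paste0("fit", f, "_", g)))
      pred <- reg$predict(fit, X[!tr, , drop = FALSE])
      oof[!tr, g] <- pred
      fold_rmse[f, g] <- rmse(y[!tr], pred)
    }
  }
  mean_rmse <- colMeans(fold_rmse, na.rm = TRUE)
  best <- which.min(mean_rmse)   # ties: first index in grid order

  final_fit <- reg$fit(X, y, as.list(grid[best, ]),
                       seed = derive_seed(config$seed, "final_fit"))
  keep <- !is.na(oof[, best])
  grid_results <- dplyr::bind_cols(
    grid, tibble::tibble(cv_rmse = mean_rmse)
  )

  structure(
    list(
      config = config,
      algorithm = config$algorithm,
      feature_names = colnames(X),
      chosen = as.list(grid[best, ]),
      cv_rmse = mean_rmse[best],
      cv_r2 = if (sum(keep) >= 2L && sd(y[keep]) > 0) {
        r2(y[keep], oof[keep, best])
      } else NA_real_,
      oof_predictions = stats::setNames(oof[, best], rownames(X)),
      grid_results = grid_results,
      fit = final_fit,
      registry = config$algorithm
    ),
    class = "qsrr_model"
  )
}

#' @export
print.qsrr_model <- function(x, ...) {
  ch <- x$chosen[setdiff(names(x$chosen), ".dummy")]
  cat(sprintf("<qsrr_model> %s on %d features\n", x$algorithm,
              length(x$feature_names)))
  if (length(ch)) {
    cat("  chosen:", paste(sprintf("%s = %.4g", names(ch), unlist(ch)),
                           collapse = ", "), "\n")
  }
  cat(sprintf("  CV RMSE %.4f, CV R2 %.3f\n", x$cv_rmse, x$cv_r2))
  invisible(x)
}

#' Predict retention with a fitted model
#'
#' Returns predictions on the modeling scale and, when `transform` is
#' `"log"`, back-transformed retention in minutes.
#'
#' @param model A `qsrr_model` from [grid_search()].
#' @param X_new Descriptor matrix/tibble containing the model's features.
#' @param transform `"log"` or `"none"`; when omitted only the modeling
#'   scale column is returned.
#' @return A tibble with `.pred` and (for log transform) `.pred_min`.
#' @export
fit_predict <- function(model, X_new, transform = NULL) {
  p <- predict_model(model, X_new)
  out <- tibble::tibble(.pred = p)
  if (!is.null(transform) && transform == "log") {
    out$.pred_min <- exp(p)
  }
  out
}

# vector-returning internal prediction path
predict_model <- function(model, X_new) {
  stopifnot(inherits(model, "qsrr_model"))
  X <- as_descriptor_matrix(X_new, "X_new")
  X <- subset_features(X, model$feature_names)
  reg <- learner_registry()[[model$algorithm]]
  p <- reg$predict(model$fit, X)
  if (any(!is.finite(p))) qsrr_abort("Non-finite predictions produced.")
  p
}

#' Top features by a learner's own importance measure
#'
#' Embedded feature selection: LASSO ranks its nonzero coefficients by
#' absolute value; RF and GBR rank impurity-based importances. MLR and SVR
#' carry no embedded selection and are rejected.
#'
#' @param model A fitted `qsrr_model` (LASSO, RF or GBR).
#' @param top_k Maximum number of features returned (default 20).
#' @return A `qsrr_selection` object (see [cfs_select()]) with
#'   `method = "embedded"`.
#' @export
embedded_importances <- function(model, top_k = 20) {
  stopifnot(inherits(model, "qsrr_model"))
  reg <- learner_registry()[[model$algorithm]]
  if (!isTRUE(reg$embedded)) {
    qsrr_abort(sprintf("%s has no embedded feature selection (use LASSO, RF or GBR).",
                       model$algorithm),
               class = "qsrrkit_unsupported_error")
  }
  # X/y are not needed by the embedded importance extractors
  dummy <- matrix(0, 1L, length(model$feature_names),
                  dimnames = list(NULL, model$feature_names))
  imp <- reg$importance(model$fit, dummy, NULL, seed = model$config$seed)
  imp <- imp[imp > 0]
  # order by importance, ties broken lexicographically for reproducibility
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  sel <- utils::head(names(imp), top_k)
  new_selection("embedded", selected = sel, scores = imp[sel],
                settings = list(algorithm = model$algorithm, top_k = top_k))
}
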