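#' Performance of a set of fitted models on an external set
#'
#' Assembles the model x metric comparison grid for one pH: cross-validated
#' RMSE and R-squared from each model's grid search, plus RMSE and
#' R-squared on the external test set. All metrics are on the modeling
#' scale (log-retention by default), as in the per-pH comparison tables.
#'
#' @param models Named list of fitted `qsrr_model` objects.
#' @param test_X Standardized external descriptor matrix.
#' @param test_y External targets on the modeling scale.
#' @param stack Optional `qsrr_stack` appended as row `"Stack"`.
#' @return A tibble: `model`, `RMSECV`, `R2CV`, `RMSE_test`, `R2_test`.
#' @export
performance_table <- function(models, test_X, test_y, stack = NULL) {
  rows <- purrr::imap(models, function(m, key) {
    pred <- predict_model(m, test_X)
    tibble::tibble(model = key, RMSECV = m$cv_rmse, R2CV = m$cv_r2,
                   RMSE_test = rmse(test_y, pred),
                   R2_test = r2(test_y, pred))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(stack)) {
    sp <- stack_predict(stack, test_X)
    g <- glance(stack)
    out <- dplyr::bind_rows(out, tibble::tibble(
      model = "Stack", RMSECV = g$meta_rmse, R2CV = g$meta_r2,
      RMSE_test = rmse(test_y, sp), R2_test = r2(test_y, sp)
    ))
  }
  class(out) <- c("qsrr_performance", class(out))
  out
}

#' Nested cross-validation of one model configuration
#'
#' Outer folds estimate generalization error; all modeling decisions
#' (standardization, hyperparameter grid search over inner folds) are made
#' inside each outer training fold, so no outer-test compound influences
#' them. The reported RMSE is the mean of the outer-fold RMSEs; R-squared
#' is computed on the pooled outer-fold predictions.
#'
#' @param config A [model_config()], or the string `"mean"` for the
#'   training-mean baseline predictor.
#' @param X Raw (unstandardized) descriptor matrix/tibble.
#' @param y Targets on the modeling scale.
#' @param outer_folds,inner_folds Fold counts (default 10 each).
#' @param seed Integer seed.
#' @return A tibble row: `model`, `RMSECV`, `R2CV`, `outer_folds`.
#' @export
nested_evaluate <- function(config, X, y, outer_folds = 10, inner_folds = 10,
                            seed = 1L) {
  X <- as_descriptor_matrix(X)
  n <- nrow(X)
  fold_id <- cv_folds(n, outer_folds, seed = derive_seed(seed, "outer"))
  oof <- rep(NA_real_, n)
  fold_rmse <- numeric(outer_folds)
  is_mean <- identical(config, "mean")
  for (f in seq_len(outer_folds)) {
    tr <- fold_id != f
    if (is_mean) {
      oof[!tr] <- mean(y[tr])
    } else {
      Xtr_raw <- X[tr, , drop = FALSE]
      keep <- apply(Xtr_raw, 2L, function(col) length(unique(col)) > 1L)
      std <- standardize(Xtr_raw[, keep, drop = FALSE],
                         X[!tr, keep, drop = FALSE])
      cfg <- config
      cfg$seed <- derive_seed(seed, paste0("inner", f))
      if (!is.null(cfg$features)) {
        cfg$features <- intersect(cfg$features, colnames(std$train))
      }
      m <- grid_search(cfg, std$train, y[tr], folds = inner_folds)
      oof[!tr] <- predict_model(m, std$test)
    }
    fold_rmse[f] <- rmse(y[!tr], oof[!tr])
  }
  tibble::tibble(
    model = if (is_mean) "mean" else config$algorithm,
    RMSECV = mean(fold_rmse),
    R2CV = r2(y, oof),
    outer_folds = outer_folds
  )
}

#' Observed/predicted/residual report for the external set
#'
#' The numeric backbone of observed-vs-predicted and residual plots: one
#' row per external compound and pH with observed and predicted retention
#' on both the modeling scale and in minutes.
#'
#' @param run A `qsrr_run` from [run_qsrr()].
#' @return A tibble: `compound_id`, `ph`, `observed`, `predicted`,
#'   `residual` (modeling scale), `observed_min`, `predicted_min`,
#'   `abs_error_min`.
#' @export
prediction_report <- function(run) {
  stopifnot(inherits(run, "qsrr_run"))
  run$predictions
}
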