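#' Fit a two-level stacked ensemble
#'
#' Level 1 is a set of tuned base learners; level 2 is a multiple linear
#' regression (the meta-learner) on their predictions. Two ways to obtain
#' the level-1 prediction matrix the meta-learner trains on are offered:
#'
#' * `"out_of_fold"` (default): each base learner is refit on k-1 folds of
#'   the training set with its already-chosen hyperparameters and predicts
#'   the held-out fold, so every meta-training row is a prediction from a
#'   model that never saw that compound. This is the standard leak-free
#'   stacking construction.
#' * `"external"`: the meta-learner is trained on the base models'
#'   predictions of a designated external set (and its targets). Because
#'   the evaluation compounds then shape the meta-coefficients, external
#'   metrics of such a stack are optimistically biased; a leakage warning
#'   is always emitted. The mode is retained for fidelity experiments with
#'   workflows built this way.
#'
#' When the base predictions are collinear the normal equations are rank
#' deficient; the meta-fit then falls back to the minimum-norm least-squares
#' solution (via the pseudoinverse) with a warning.
#'
#' @param base_models Named list of fitted `qsrr_model` objects (>= 2); each
#'   applies its own feature subset internally.
#' @param X Training descriptor matrix/tibble (standardized).
#' @param y Training targets on the modeling scale.
#' @param mode `"out_of_fold"` or `"external"`.
#' @param external_X,external_y Required in `"external"` mode.
#' @param folds Folds for the out-of-fold construction (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A `qsrr_stack`: meta `intercept`, `weights` (one per base model),
#'   `mode`, and the retained `base_models`.
#' @export
stack_fit <- function(base_models, X, y, mode = c("out_of_fold", "external"),
                      external_X = NULL, external_y = NULL,
                      folds = 10, seed = 1L) {
  mode <- match.arg(mode)
  if (length(base_models) < 2L) {
    qsrr_abort("Stacking needs at least two base models.")
  }
  if (is.null(names(base_models)) || any(!nzchar(names(base_models))) ||
      anyDuplicated(names(base_models))) {
    qsrr_abort("`base_models` must have unique nonempty names.")
  }
  stopifnot(all(vapply(base_models, inherits, logical(1), "qsrr_model")))
  X <- as_descriptor_matrix(X)

  if (mode == "out_of_fold") {
    n <- nrow(X)
    fold_id <- cv_folds(n, folds, seed = seed)
    Z <- matrix(NA_real_, n, length(base_models),
                dimnames = list(NULL, names(base_models)))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      for (b in seq_along(base_models)) {
        bm <- base_models[[b]]
        reg <- learner_registry()[[bm$algorithm]]
        Xb <- subset_features(X, bm$feature_names)
        refit <- reg$fit(Xb[tr, , drop = FALSE], y[tr], bm$chosen,
                         seed = derive_seed(seed, paste0("stack", f, "_", b)))
        Z[!tr, b] <- reg$predict(refit, Xb[!tr, , drop = FALSE])
      }
    }
    meta_y <- y
  } else {
    if (is.null(external_X) || is.null(external_y)) {
      qsrr_abort("`external` mode needs `external_X` and `external_y`.")
    }
    warning(paste(
      "Meta-learner trained on the external set: its external metrics are",
      "optimistically biased (the evaluation compounds shaped the meta fit)."
    ))
    Z <- vapply(base_models, function(bm) predict_model(bm, external_X),
                numeric(nrow(as_descriptor_matrix(external_X))))
    meta_y <- external_y
  }

  A <- cbind(`(Intercept)` = 1, Z)
  fit <- stats::lm.fit(A, meta_y)
  if (fit$rank < ncol(A)) {
    warning("Collinear base predictions; using the minimum-norm meta solution.")
    coefs <- drop(pracma_pinv(A) %*% meta_y)
    names(coefs) <- colnames(A)
  } else {
    coefs <- stats::coef(fit)
  }

  structure(
    list(
      base_keys = names(base_models),
      intercept = unname(coefs[1L]),
      weights = stats::setNames(unname(coefs[-1L]), names(base_models)),
      mode = mode,
      base_models = base_models,
      meta_training = tibble::tibble(y = meta_y) |>
        dplyr::bind_cols(tibble::as_tibble(Z))
    ),
    class = "qsrr_stack"
  )
}

# Moore-Penrose pseudoinverse via SVD (tolerance scaled to the leading
# singular value), for rank-deficient meta designs.
pracma_pinv <- function(A, tol = NULL) {
  s <- svd(A)
  tol <- tol %||% max(dim(A)) * .Machine$double.eps * s$d[1L]
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.qsrr_stack <- function(x, ...) {
  cat(sprintf("<qsrr_stack> %d base models, mode = %s\n",
              length(x$base_keys), x$mode))
  cat(sprintf("  intercept %.4f; weights: %s\n", x$intercept,
              paste(sprintf("%s = %.3f", names(x$weights), x$weights),
                    collapse = ", ")))
  invisible(x)
}

#' Predict with a stacked ensemble
#'
#' `prediction = intercept + sum_i w_i * base_i(X_new)`.
#'
#' @param stack A `qsrr_stack`.
#' @param X_new Descriptor matrix/tibble.
#' @param base_models Optional replacement list of base models (must cover
#'   `stack$base_keys`); defaults to the models stored in the stack.
#' @return Numeric vector of predictions on the modeling scale.
#' @export
stack_predict <- function(stack, X_new, base_models = NULL) {
  stopifnot(inherits(stack, "qsrr_stack"))
  base_models <- base_models %||% stack$base_models
  missing_b <- setdiff(stack$base_keys, names(base_models))
  if (length(missing_b)) {
    qsrr_abort(sprintf("Base models missing: %s.",
                       paste(missing_b, collapse = ", ")))
  }
  Z <- vapply(stack$base_keys, function(k) predict_model(base_models[[k]], X_new),
              numeric(nrow(as_descriptor_matrix(X_new))))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  drop(stack$intercept + Z %*% stack$weights[stack$base_keys])
}

#' @method tidy qsrr_stack
#' @export
tidy.qsrr_stack <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$weights)),
    estimate = c(x$intercept, unname(x$weights))
  )
}

#' @method glance qsrr_stack
#' @export
glance.qsrr_stack <- function(x, ...) {
  yhat <- as.matrix(x$meta_training[-1L]) %*% x$weights + x$intercept
  tibble::tibble(
    n_base = length(x$base_keys),
    mode = x$mode,
    meta_rmse = rmse(x$meta_training$y, drop(yhat)),
    meta_r2 = r2(x$meta_training$y, drop(yhat))
  )
}
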