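#' Root-mean-squared error
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) qsrr_abort("`y` and `yhat` lengths differ.")
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    qsrr_abort("`y` and `yhat` must be finite.")
  }
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST`; can be negative when predictions are worse than the mean.
#'
#' @inheritParams rmse
#' @return R-squared value (at most 1).
#' @export
r2 <- function(y, yhat) {
  if (length(y) != length(yhat)) qsrr_abort("`y` and `yhat` lengths differ.")
  if (length(y) < 2L) qsrr_abort("R-squared needs at least 2 observations.")
  if (any(!is.finite(y)) || any(!is.finite(yhat))) {
    qsrr_abort("`y` and `yhat` must be finite.")
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) qsrr_abort("R-squared is undefined for constant `y`.")
  1 - sum((y - yhat)^2) / sst
}

#' Seeded k-fold assignment
#'
#' Randomly partitions `n` indices into `folds` disjoint groups whose sizes
#' differ by at most one; every index appears in exactly one fold.
#'
#' @param n Number of observations.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of length `n` with fold labels `1..folds`.
#' @export
#' @examples
#' table(cv_folds(67, 10, seed = 1))   # seven folds of 7, three of 6
cv_folds <- function(n, folds = 10, seed = 1L) {
  check_count(n, "n")
  check_count(folds, "folds", min = 2L)
  if (n < folds) {
    qsrr_abort(sprintf("Cannot make %d folds from %d observations.", folds, n),
               class = "qsrrkit_config_error")
  }
  with_seed(derive_seed(seed, "cv_folds"), {
    sample(rep(seq_len(folds), length.out = n))
  })
}

#' Rank models across pH conditions
#'
#' Ranks every model within each performance table by a chosen metric
#' (rank 1 = best, i.e. lowest RMSE or highest R-squared), with ties given
#' their average rank, then averages ranks over the pH conditions. The mean
#' rank is the cross-condition summary used to pick an overall winner.
#'
#' @param tables Named list (by pH) of performance tibbles with a `model`
#'   column; all must share the same models.
#' @param metric Column to rank on (default `"RMSE_test"`).
#' @param lower_is_better Direction of the metric (`TRUE` for RMSE).
#' @return A `qsrr_ranks` tibble: `model`, one `rank_pH*` column per table,
#'   `mean_rank`, sorted by `mean_rank`.
#' @export
rank_models <- function(tables, metric = "RMSE_test", lower_is_better = TRUE) {
  if (!length(tables)) qsrr_abort("`tables` must be nonempty.")
  keys <- sort(tables[[1L]]$model)
  for (tb in tables) {
    if (!metric %in% names(tb)) {
      qsrr_abort(sprintf("Metric column `%s` missing from a table.", metric))
    }
    if (!setequal(tb$model, keys) || anyDuplicated(tb$model)) {
      qsrr_abort("All tables must share the same unique model keys.")
    }
  }
  rank_one <- function(tb) {
    v <- stats::setNames(tb[[metric]], tb$model)[keys]
    r <- rank(if (lower_is_better) v else -v, ties.method = "average")
    r
  }
  ranks <- purrr::map(tables, rank_one)
  out <- tibble::tibble(model = keys)
  nm <- names(tables) %||% as.character(seq_along(tables))
  for (i in seq_along(ranks)) {
    out[[sprintf("rank_pH%s", nm[i])]] <- unname(ranks[[i]])
  }
  out$mean_rank <- rowMeans(as.matrix(out[-1L]))
  out <- dplyr::arrange(out, .data$mean_rank, .data$model)
  class(out) <- c("qsrr_ranks", class(out))
  out
}
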