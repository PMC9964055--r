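#' Remove compounds that elute before a retention threshold at every pH
#'
#' A compound is dropped only when its retention time is below `threshold`
#' at *all* pH conditions (the rule is conjunctive over pH): such compounds
#' elute with the solvent front and carry no usable retention signal.
#' Survivor order is preserved.
#'
#' @param table Compound tibble with `rt_pH*` columns (one per pH).
#' @param threshold Retention threshold in minutes (default 2).
#' @return The filtered tibble, with attribute `"removed"` listing dropped
#'   compound ids.
#' @export
#' @examples
#' tb <- tibble::tibble(compound_id = c("a", "b"),
#'                      rt_pH2.7 = c(1.2, 1.2), rt_pH8 = c(1.5, 2.5))
#' filter_low_retention(tb)   # drops "a" only
filter_low_retention <- function(table, threshold = 2.0) {
  table <- tibble::as_tibble(table)
  rt_cols <- grep("^rt_pH", names(table), value = TRUE)
  if (!length(rt_cols)) qsrr_abort("`table` has no `rt_pH*` retention columns.")
  rt <- as.matrix(table[rt_cols])
  if (anyNA(rt)) {
    bad <- which(is.na(rt), arr.ind = TRUE)[1L, ]
    qsrr_abort(sprintf("Missing retention value for compound %s at %s.",
                       table$compound_id[bad[["row"]]], rt_cols[bad[["col"]]]))
  }
  drop <- apply(rt < threshold, 1L, all)
  out <- table[!drop, , drop = FALSE]
  attr(out, "removed") <- table$compound_id[drop]
  out
}

#' Drop zero-variance descriptors
#'
#' Removes columns whose sample variance is exactly zero (constants carry no
#' information and break standardization).
#'
#' @param X Descriptor tibble (optionally with a `compound_id` column) or
#'   numeric matrix.
#' @return `X` without its constant columns; attribute `"dropped"` holds the
#'   removed names.
#' @export
remove_zero_variance <- function(X) {
  is_tb <- is.data.frame(X)
  m <- as_descriptor_matrix(X)
  n_distinct <- apply(m, 2L, function(col) length(unique(col)))
  const <- n_distinct == 1L
  if (all(const)) {
    qsrr_abort("All descriptor columns have zero variance; nothing would remain.")
  }
  kept <- m[, !const, drop = FALSE]
  out <- if (is_tb) {
    keep_cols <- c(intersect("compound_id", names(X)), colnames(kept))
    tibble::as_tibble(X)[keep_cols]
  } else {
    kept
  }
  attr(out, "dropped") <- colnames(m)[const]
  out
}

#' Standardize descriptors with train-only parameters
#'
#' Two-step autoscaling: mean centering, then division by the standard
#' deviation so every descriptor has unit variance. Means and standard
#' deviations are learned on the training rows only; test rows are
#' transformed with the training parameters (never refit), which keeps the
#' external set out of every modeling decision.
#'
#' @param train_X Training descriptor tibble/matrix.
#' @param test_X Optional test descriptor tibble/matrix with identical
#'   feature names.
#' @return List with `train`, `test` (or `NULL`) and `scaler` (tibble:
#'   feature, mean, sd).
#' @export
standardize <- function(train_X, test_X = NULL) {
  tr <- as_descriptor_matrix(train_X, "train_X")
  mu <- colMeans(tr)
  sigma <- apply(tr, 2L, sd)
  if (any(sigma == 0)) {
    qsrr_abort(sprintf(
      "Zero standard deviation in: %s. Run remove_zero_variance() first.",
      paste(names(sigma)[sigma == 0], collapse = ", ")
    ))
  }
  scale_mat <- function(m) sweep(sweep(m, 2L, mu, "-"), 2L, sigma, "/")
  tr_s <- scale_mat(tr)
  te_s <- NULL
  if (!is.null(test_X)) {
    te <- as_descriptor_matrix(test_X, "test_X")
    missing_f <- setdiff(colnames(tr), colnames(te))
    if (length(missing_f)) {
      qsrr_abort(sprintf("`test_X` lacks features: %s.",
                         paste(missing_f, collapse = ", ")))
    }
    te_s <- scale_mat(te[, colnames(tr), drop = FALSE])
  }
  list(
    train = tr_s,
    test = te_s,
    scaler = tibble::tibble(feature = colnames(tr), mean = unname(mu),
                            sd = unname(sigma))
  )
}

#' Invert standardization
#'
#' @param X_std Standardized matrix/tibble.
#' @param scaler Scaler tibble from [standardize()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(X_std, scaler) {
  m <- as_descriptor_matrix(X_std, "X_std")
  mu <- stats::setNames(scaler$mean, scaler$feature)[colnames(m)]
  sigma <- stats::setNames(scaler$sd, scaler$feature)[colnames(m)]
  sweep(sweep(m, 2L, sigma, "*"), 2L, mu, "+")
}

#' Split compounds into a modeling set and an external test set
#'
#' The same compounds form the external set at every pH, so per-pH models
#' are validated on identical molecules. The draw is seeded; optional
#' stratification balances the test set across retention quartiles
#' (computed on the mean retention over pH), and specific compounds can be
#' forced into the external set (e.g. a known structural outlier whose
#' behaviour the applicability domain should be confronted with).
#'
#' @param table Compound tibble (after [filter_low_retention()]).
#' @param matrices Named list of per-pH descriptor tibbles aligned with
#'   `table`.
#' @param n_test External-set size (default 10).
#' @param seed Integer seed for the draw.
#' @param stratify Balance the test set across retention quartiles.
#' @param force_test Character vector of compound ids guaranteed to be in
#'   the external set.
#' @param transform `"log"` (default) models log-retention and reports in
#'   minutes by back-transformation; `"none"` models raw minutes.
#' @return A `qsrr_split` object: list of per-pH entries, each with
#'   `train_X`, `train_y`, `test_X`, `test_y`, `scaler`, `transform`, `ph`,
#'   plus `train_ids`/`test_ids` at the top level.
#' @export
split_dataset <- function(table, matrices, n_test = 10, seed = 1L,
                          stratify = FALSE, force_test = character(),
                          transform = c("log", "none")) {
  transform <- match.arg(transform)
  table <- tibble::as_tibble(table)
  n <- nrow(table)
  check_count(n_test, "n_test")
  if (n_test >= n) {
    qsrr_abort(sprintf("`n_test` (%d) must be smaller than the number of compounds (%d).",
                       n_test, n), class = "qsrrkit_config_error")
  }
  ids <- table$compound_id
  bad_force <- setdiff(force_test, ids)
  if (length(bad_force)) {
    qsrr_abort(sprintf("`force_test` ids not present: %s.",
                       paste(bad_force, collapse = ", ")))
  }
  rt_cols <- grep("^rt_pH", names(table), value = TRUE)

  test_ids <- with_seed(derive_seed(seed, "split"), {
    chosen <- force_test
    remaining <- setdiff(ids, chosen)
    n_more <- n_test - length(chosen)
    if (n_more < 0) qsrr_abort("`force_test` larger than `n_test`.")
    if (n_more > 0) {
      if (stratify) {
        mean_rt <- rowMeans(as.matrix(table[rt_cols]))
        names(mean_rt) <- ids
        q <- stats::quantile(mean_rt, probs = c(0.25, 0.5, 0.75))
        stratum <- findInterval(mean_rt[remaining], q)
        # proportional allocation across quartiles, remainder spread from
        # the largest strata, so quartile counts differ from proportional
        # by at most one
        alloc <- floor(n_more * table(factor(stratum, levels = 0:3)) /
                         length(remaining))
        short <- n_more - sum(alloc)
        if (short > 0) {
          order_strata <- order(table(factor(stratum, levels = 0:3)),
                                decreasing = TRUE)
          alloc[order_strata[seq_len(short)]] <-
            alloc[order_strata[seq_len(short)]] + 1L
        }
        picked <- unlist(lapply(0:3, function(s) {
          pool <- remaining[stratum == s]
          sample(pool, min(alloc[[s + 1L]], length(pool)))
        }))
        # top up if rounding left a shortfall
        if (length(picked) < n_more) {
          picked <- c(picked, sample(setdiff(remaining, picked),
                                     n_more - length(picked)))
        }
        chosen <- c(chosen, picked)
      } else {
        chosen <- c(chosen, sample(remaining, n_more))
      }
    }
    sort(chosen)
  })
  train_ids <- ids[!ids %in% test_ids]

  per_ph <- purrr::imap(matrices, function(mat, ph_key) {
    mat <- tibble::as_tibble(mat)
    stopifnot(identical(mat$compound_id, ids))
    rt_col <- rt_column(as.numeric(ph_key))
    y <- stats::setNames(table[[rt_col]], ids)
    if (transform == "log") y <- log(y)
    X <- as_descriptor_matrix(mat)
    std <- standardize(X[train_ids, , drop = FALSE],
                       X[test_ids, , drop = FALSE])
    list(ph = as.numeric(ph_key),
         train_X = std$train, train_y = y[train_ids],
         test_X = std$test, test_y = y[test_ids],
         scaler = std$scaler, transform = transform)
  })

  structure(
    list(per_ph = per_ph, train_ids = train_ids, test_ids = test_ids,
         transform = transform, seed = as.integer(seed)),
    class = "qsrr_split"
  )
}

#' @export
print.qsrr_split <- function(x, ...) {
  cat(sprintf("<qsrr_split> %d train / %d external test compounds, %d pH conditions (transform: %s)\n",
              length(x$train_ids), length(x$test_ids), length(x$per_ph),
              x$transform))
  invisible(x)
}

#' Back-transform modeled retention to minutes
#' @param y Values on the modeling scale.
#' @param transform `"log"` or `"none"`.
#' @return Retention times in minutes.
#' @export
back_transform <- function(y, transform) {
  if (transform == "log") exp(y) else y
}
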