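new_selection <- function(method, selected, scores, settings = list()) {
  structure(
    list(method = method, selected = as.character(selected),
         scores = scores, settings = settings),
    class = "qsrr_selection"
  )
}

#' @export
print.qsrr_selection <- function(x, ...) {
  cat(sprintf("<qsrr_selection> %s: %d feature(s)\n", x$method,
              length(x$selected)))
  if (length(x$selected)) {
    cat(" ", paste(utils::head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @method tidy qsrr_selection
#' @export
tidy.qsrr_selection <- function(x, ...) {
  tibble::tibble(
    feature = x$selected,
    score = unname(x$scores[x$selected]),
    rank = seq_along(x$selected),
    method = x$method
  )
}

#' Hall's merit of a feature subset
#'
#' `M(S) = k * mean|cor(f, y)| / sqrt(k + k (k-1) * mean|cor(f, f')|)`:
#' subsets score well when their features correlate with the target but not
#' with each other.
#'
#' @param cfy Absolute feature-target correlations (named).
#' @param cff Absolute feature-feature correlation matrix.
#' @param subset Feature names in the subset.
#' @return The merit value.
#' @export
cfs_merit <- function(cfy, cff, subset) {
  k <- length(subset)
  if (!k) return(0)
  rcf <- mean(cfy[subset])
  rff <- if (k > 1L) {
    m <- cff[subset, subset, drop = FALSE]
    mean(m[upper.tri(m)])
  } else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature selection (CFS)
#'
#' Greedy forward search maximizing Hall's merit: start empty, repeatedly
#' add the feature that most increases the merit, stop when no candidate
#' strictly increases it (or `max_features` is reached). This favours small
#' subsets of features that are individually predictive of retention yet
#' mutually uncorrelated -- the filter-style antidote to the heavy
#' multicollinearity of molecular-descriptor blocks. A plain correlation
#' threshold filter is available via `min_correlation` instead of the
#' merit search.
#'
#' @param X Standardized descriptor matrix/tibble.
#' @param y Numeric target.
#' @param max_features Optional cap on the subset size.
#' @param min_correlation When non-`NULL`, switch to a simple filter that
#'   keeps every feature with `|cor(x, y)| >=` this threshold.
#' @return A `qsrr_selection` with `method = "cfs"`; `scores` hold the merit
#'   after each greedy addition (or `|cor|` for the threshold filter).
#' @export
cfs_select <- function(X, y, max_features = NULL, min_correlation = NULL) {
  X <- as_descriptor_matrix(X)
  if (length(y) != nrow(X)) qsrr_abort("`y` length must match rows of `X`.")
  if (sd(y) == 0) qsrr_abort("`y` is constant; correlations are undefined.")
  feats <- colnames(X)
  cfy <- abs(drop(stats::cor(X, y)))
  names(cfy) <- feats

  if (!is.null(min_correlation)) {
    sel <- feats[cfy >= min_correlation]
    sel <- sel[order(-cfy[sel], sel)]
    return(new_selection("cfs", sel, cfy[sel],
                         settings = list(min_correlation = min_correlation)))
  }

  cff <- abs(stats::cor(X))
  max_features <- max_features %||% length(feats)
  selected <- character()
  merit_trace <- numeric()
  current <- 0
  repeat {
    if (length(selected) >= max_features) break
    candidates <- setdiff(feats, selected)
    if (!length(candidates)) break
    merits <- vapply(candidates, function(f) {
      cfs_merit(cfy, cff, c(selected, f))
    }, numeric(1))
    # ties broken lexicographically by feature name
    ord <- order(-merits, candidates)
    best <- candidates[ord[1L]]
    if (merits[ord[1L]] <= current + 1e-12) break
    selected <- c(selected, best)
    current <- merits[ord[1L]]
    merit_trace <- c(merit_trace, current)
  }
  if (!length(selected) && length(feats)) {
    # first feature always has merit |cor| > 0 unless all correlations are 0;
    # keep the single best to honour the non-empty contract
    best <- feats[order(-cfy, feats)][1L]
    selected <- best
    merit_trace <- cfy[best]
  }
  new_selection("cfs", selected, stats::setNames(merit_trace, selected),
                settings = list(max_features = max_features))
}

#' Recursive feature elimination with cross-validated size choice
#'
#' Wrapper selection: features are ranked by the learner's own importance
#' (absolute coefficients for linear learners, impurity for trees,
#' permutation importance for kernel SVR), the lowest-ranked are dropped to
#' reach each candidate subset size, and every size is scored by k-fold CV
#' RMSE of the learner refit on that subset. The size minimizing CV RMSE
#' wins (ties go to the smaller size); the returned feature set is the
#' recursion's subset at the winning size, with scores from a refit on all
#' rows.
#'
#' @param X Standardized descriptor matrix/tibble.
#' @param y Numeric target.
#' @param learner Algorithm name (`"MLR"`, `"LASSO"`, `"SVR_RBF"`, `"RF"`,
#'   `"GBR"`) or a [model_config()] carrying hyperparameters to use during
#'   elimination (no grid search inside RFE; a single parameter set keeps
#'   the wrapper affordable).
#' @param subset_sizes Candidate subset sizes (descending recursion).
#' @param folds CV folds per size (default 10).
#' @param size_rule How the winning size is picked from the CV profile:
#'   `"1se"` (default) takes the smallest size whose CV RMSE is within one
#'   standard error of the minimum -- the parsimony rule needed because the
#'   CV curve is nearly flat beyond the true support, so the raw argmin
#'   drifts into oversized subsets; `"min"` takes the strict argmin (exact
#'   ties still go to the smaller size).
#' @param seed Integer seed.
#' @return A `qsrr_selection` with `method = "rfe"`; `settings$profile` is
#'   the size-vs-CV-RMSE tibble (with per-size standard errors).
#' @export
rfe_select <- function(X, y, learner = "MLR",
                       subset_sizes = NULL, folds = 10,
                       size_rule = c("1se", "min"), seed = 1L) {
  size_rule <- match.arg(size_rule)
  X <- as_descriptor_matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  if (is.character(learner)) learner <- model_config(learner, seed = seed)
  stopifnot(inherits(learner, "qsrr_model_config"))
  reg <- learner_registry()[[learner$algorithm]]
  params <- if (!is.null(learner$grid)) {
    as.list(learner$grid[1L, ])
  } else {
    as.list(reg$default_grid(X)[1L, ])
  }
  subset_sizes <- sort(unique(as.integer(
    subset_sizes %||% pmax(1L, unique(floor(p * c(1, 0.75, 0.5, 0.25, 0.1, 0.05))))
  )))
  if (any(subset_sizes > p) || any(subset_sizes < 1L)) {
    qsrr_abort(sprintf("`subset_sizes` must lie in [1, %d].", p),
               class = "qsrrkit_config_error")
  }
  if (learner$algorithm == "MLR" && max(subset_sizes) >= n) {
    qsrr_abort("MLR inside RFE needs every subset size < n.")
  }

  fit_rank <- function(M) {
    fit <- reg$fit(M, y, params, seed = derive_seed(seed, "rfe_fit"))
    imp <- reg$importance(fit, M, y, seed = derive_seed(seed, "rfe_imp"))
    # higher importance first; ties broken lexicographically by name
    names(imp)[order(-imp, names(imp))]
  }

  # recursion: rank on the current subset, cut to the next smaller size
  sizes_desc <- rev(subset_sizes)
  subsets <- vector("list", length(sizes_desc))
  current <- colnames(X)
  for (i in seq_along(sizes_desc)) {
    s <- sizes_desc[i]
    if (length(current) > s) {
      ranked <- fit_rank(X[, current, drop = FALSE])
      current <- sort(ranked[seq_len(s)])
    }
    subsets[[i]] <- current
  }
  names(subsets) <- as.character(sizes_desc)

  fold_id <- cv_folds(n, folds, seed = seed)
  cv_for_subset <- function(feats) {
    vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- reg$fit(X[tr, feats, drop = FALSE], y[tr], params,
                     seed = derive_seed(seed, paste0("rfe_cv", f)))
      rmse(y[!tr], reg$predict(fit, X[!tr, feats, drop = FALSE]))
    }, numeric(1))
  }
  fold_errs <- vapply(subsets, cv_for_subset, numeric(folds))
  profile <- tibble::tibble(
    size = sizes_desc,
    cv_rmse = colMeans(fold_errs),
    cv_rmse_se = apply(fold_errs, 2L, sd) / sqrt(folds)
  ) |> dplyr::arrange(.data$size)

  # profile is sorted ascending, so which.min resolves exact ties to the
  # smaller size; the 1se rule additionally trades a standard error of CV
  # RMSE for parsimony
  i_min <- which.min(profile$cv_rmse)
  best_size <- if (size_rule == "1se") {
    cutoff <- profile$cv_rmse[i_min] + profile$cv_rmse_se[i_min]
    profile$size[which(profile$cv_rmse <= cutoff)[1L]]
  } else {
    profile$size[i_min]
  }
  sel <- subsets[[as.character(best_size)]]

  final_fit <- reg$fit(X[, sel, drop = FALSE], y, params,
                       seed = derive_seed(seed, "rfe_final"))
  imp <- reg$importance(final_fit, X[, sel, drop = FALSE], y,
                        seed = derive_seed(seed, "rfe_final_imp"))
  sel <- names(imp)[order(-imp, names(imp))]

  new_selection("rfe", sel, imp[sel],
                settings = list(learner = learner$algorithm, params = params,
                                profile = profile, folds = folds, seed = seed))
}

#' Consensus features across selection methods
#'
#' Intersects the feature sets chosen by several selectors (embedded
#' results are first truncated to their `embedded_top_k` most important
#' features). The mutually selected features are the ones every view of
#' the data agrees matter -- on retention data these are typically the
#' lipophilicity-related descriptors.
#'
#' @param results List of `qsrr_selection` objects (>= 2).
#' @param embedded_top_k Truncation applied to embedded results (default 20).
#' @return Character vector of consensus features, sorted for determinism;
#'   empty (with a warning) when the intersection is empty.
#' @export
consensus_features <- function(results, embedded_top_k = 20) {
  if (length(results) < 2L) qsrr_abort("Need at least two selection results.")
  sets <- purrr::map(results, function(r) {
    stopifnot(inherits(r, "qsrr_selection"))
    if (r$method == "embedded") {
      utils::head(r$selected, embedded_top_k)
    } else {
      r$selected
    }
  })
  out <- sort(purrr::reduce(sets, intersect))
  if (!length(out)) {
    warning("No feature was selected by every method; consensus is empty.")
  }
  out
}

#' Embedded feature selection with the LASSO
#'
#' Fits the full LASSO path with k-fold cross-validation and keeps the
#' features with nonzero coefficients at the chosen penalty. The default
#' `"1se"` rule (largest penalty within one standard error of the CV
#' minimum) gives the parsimonious support appropriate for *selection*;
#' `"min"` uses the CV-RMSE-minimising penalty, which predicts better but
#' admits more false-positive features.
#'
#' @param X Standardized descriptor matrix/tibble.
#' @param y Numeric target.
#' @param folds CV folds (default 10).
#' @param rule `"1se"` or `"min"`.
#' @param seed Integer seed for the fold assignment.
#' @return A `qsrr_selection` with `method = "embedded"`, scores = |coef|.
#' @export
lasso_select <- function(X, y, folds = 10, rule = c("1se", "min"), seed = 1L) {
  rule <- match.arg(rule)
  X <- as_descriptor_matrix(X)
  fold_id <- cv_folds(nrow(X), folds, seed = seed)
  cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = fold_id,
                             standardize = FALSE)
  s <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
  b <- as.numeric(stats::coef(cvfit, s = s))[-1L]
  names(b) <- colnames(X)
  b <- b[b != 0]
  ord <- order(-abs(b), names(b))
  sel <- names(b)[ord]
  new_selection("embedded", sel, abs(b)[sel],
                settings = list(learner = "LASSO", rule = rule,
                                lambda = s, folds = folds))
}
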