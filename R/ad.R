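#' Mean k-nearest-neighbour distances to a training set
#'
#' For each query compound, the mean Euclidean distance to its `k` nearest
#' training compounds in the (standardized) descriptor space. When the
#' query set *is* the training set (`query_X = NULL`), each compound's
#' distance to itself is excluded, so the score reflects how deep in the
#' cloud a training compound sits.
#'
#' @param train_X Standardized training descriptor matrix/tibble.
#' @param query_X Optional query matrix with the same feature names;
#'   `NULL` scores the training compounds themselves (leave-self-out).
#' @param k Number of neighbours (default 5).
#' @return Numeric vector of mean kNN distances, one per query row.
#' @export
ad_distances <- function(train_X, query_X = NULL, k = 5) {
  tr <- as_descriptor_matrix(train_X, "train_X")
  n_train <- nrow(tr)
  check_count(k, "k")
  if (k >= n_train) {
    qsrr_abort(sprintf("`k` (%d) must be smaller than the training size (%d).",
                       k, n_train), class = "qsrrkit_config_error")
  }
  self <- is.null(query_X)
  q <- if (self) tr else {
    qm <- as_descriptor_matrix(query_X, "query_X")
    missing_f <- setdiff(colnames(tr), colnames(qm))
    if (length(missing_f)) {
      qsrr_abort(sprintf("`query_X` lacks features: %s.",
                         paste(missing_f, collapse = ", ")))
    }
    qm[, colnames(tr), drop = FALSE]
  }
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  tr_sq <- rowSums(tr^2)
  q_sq <- rowSums(q^2)
  d2 <- outer(q_sq, tr_sq, "+") - 2 * tcrossprod(q, tr)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  vapply(seq_len(nrow(q)), function(i) {
    di <- d[i, ]
    if (self) di <- di[-i]
    mean(sort(di, partial = k)[seq_len(k)])
  }, numeric(1))
}

#' Applicability-domain distance threshold
#'
#' The threshold is a percentile (linear interpolation between order
#' statistics) of the training compounds' own leave-self-out mean kNN
#' distances. Query compounds farther from the training cloud than this
#' value are outside the model's applicability domain.
#'
#' @inheritParams ad_distances
#' @param percentile Percentile in (0, 100); default 95.
#' @return The threshold distance (same units as the standardized space).
#' @export
ad_threshold <- function(train_X, k = 5, percentile = 95) {
  check_range(percentile, "percentile", 0, 100, inclusive_lower = FALSE)
  d <- ad_distances(train_X, NULL, k = k)
  unname(stats::quantile(d, percentile / 100, type = 7))
}

#' Classify compounds as inside or outside the applicability domain
#'
#' A compound is `Out` when its mean kNN distance strictly exceeds the
#' threshold (a distance exactly equal to the threshold is `In`).
#'
#' @param distances Mean kNN distances (from [ad_distances()]).
#' @param threshold Threshold (from [ad_threshold()]).
#' @param compound_id Optional ids for the report rows.
#' @return A tibble: `compound_id`, `mean_knn_distance`, `threshold`,
#'   `flag` (`"In"`/`"Out"`), rows in input order.
#' @export
#' @examples
#' ad_classify(c(21.72, 8.39), threshold = 15.87)
ad_classify <- function(distances, threshold, compound_id = NULL) {
  if (any(!is.finite(distances)) || !is.finite(threshold)) {
    qsrr_abort("Distances and threshold must be finite.")
  }
  tibble::tibble(
    compound_id = compound_id %||% sprintf("Q%03d", seq_along(distances)),
    mean_knn_distance = as.numeric(distances),
    threshold = threshold,
    flag = ifelse(distances > threshold, "Out", "In")
  )
}

#' Applicability-domain report across pH conditions
#'
#' Builds a per-compound report in the shape of a published AD table: one
#' row per external compound with its mean kNN distance at every pH, the
#' per-pH thresholds, per-pH flags, and an aggregate flag. The default
#' aggregation calls a compound `Out` when it is out at *any* pH -- a
#' structural outlier drifts outside the cloud at every condition, while
#' borderline compounds are caught conservatively.
#'
#' @param split A `qsrr_split` from [split_dataset()].
#' @param k Neighbours (default 5).
#' @param percentile Threshold percentile (default 95).
#' @param aggregate `"any"` (Out if out at any pH) or `"all"` (Out only if
#'   out at every pH).
#' @return A `qsrr_ad_report` tibble: `compound_id`, `distance_pH*` and
#'   `threshold_pH*` columns, `flag_pH*` columns, and `applicability`.
#' @export
ad_report <- function(split, k = 5, percentile = 95,
                      aggregate = c("any", "all")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(split, "qsrr_split"))
  out <- tibble::tibble(compound_id = split$test_ids)
  flags <- NULL
  for (entry in split$per_ph) {
    key <- sprintf("%g", entry$ph)
    d <- ad_distances(entry$train_X, entry$test_X, k = k)
    thr <- ad_threshold(entry$train_X, k = k, percentile = percentile)
    out[[sprintf("distance_pH%s", key)]] <- d
    out[[sprintf("threshold_pH%s", key)]] <- thr
    f <- d > thr
    out[[sprintf("flag_pH%s", key)]] <- ifelse(f, "Out", "In")
    flags <- if (is.null(flags)) f else if (aggregate == "any") flags | f else flags & f
  }
  out$applicability <- ifelse(flags, "Out", "In")
  class(out) <- c("qsrr_ad_report", class(out))
  out
}
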