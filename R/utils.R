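# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing validation failures carry the "qsrrkit_error" class so
#' callers (and tests) can distinguish them from programming errors.
#' @noRd
qsrr_abort <- function(msg, class = "qsrrkit_error", ...) {
  rlang::abort(msg, class = c(class, "qsrrkit_error"), ...)
}

#' Derive a deterministic sub-seed from a root seed
#'
#' A single root seed governs a run; stage-level streams are derived from it
#' so that adding a stage never perturbs the draws of another. Kept below
#' 2^31 - 1 to stay within R's integer range.
#' @noRd
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  chars <- utf8ToInt(as.character(stage))
  offset <- sum(chars * seq_along(chars)) * 2654435
  as.integer((abs(seed) + offset) %% .Machine$integer.max)
}

#' Run code under a local seed without disturbing the caller's RNG
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Coerce a descriptor table (tibble or matrix) to a numeric matrix
#'
#' Accepts a tibble with an optional `compound_id` column, a data.frame, or
#' a numeric matrix. Row identity is preserved via rownames when ids exist.
#' @noRd
as_descriptor_matrix <- function(X, arg = "X") {
  if (is.matrix(X)) {
    if (!is.numeric(X)) qsrr_abort(sprintf("`%s` must be numeric.", arg))
    return(X)
  }
  if (is.data.frame(X)) {
    ids <- NULL
    if ("compound_id" %in% names(X)) {
      ids <- as.character(X[["compound_id"]])
      X <- X[setdiff(names(X), "compound_id")]
    }
    bad <- names(X)[!vapply(X, is.numeric, logical(1))]
    if (length(bad)) {
      qsrr_abort(sprintf(
        "`%s` has non-numeric descriptor columns: %s.",
        arg, paste(bad, collapse = ", ")
      ))
    }
    m <- as.matrix(X)
    if (!is.null(ids)) rownames(m) <- ids
    return(m)
  }
  qsrr_abort(sprintf("`%s` must be a matrix or data frame.", arg))
}

#' Matrix -> tibble with compound_id column restored from rownames
#' @noRd
matrix_to_tibble <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  if (!is.null(rownames(m))) {
    out <- dplyr::bind_cols(tibble::tibble(compound_id = rownames(m)), out)
  }
  out
}

#' Check a scalar is a count (positive integerish)
#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    qsrr_abort(sprintf("`%s` must be an integer >= %d.", name, min),
               class = "qsrrkit_config_error")
  }
  invisible(as.integer(x))
}

#' Check a scalar lies in an interval
#' @noRd
check_range <- function(x, name, lower, upper, inclusive_lower = TRUE,
                        inclusive_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (inclusive_lower) x >= lower else x > lower) &&
    (if (inclusive_upper) x <= upper else x < upper)
  if (!ok) {
    qsrr_abort(sprintf("`%s` must lie in %s%g, %g%s.", name,
                       if (inclusive_lower) "[" else "(", lower, upper,
                       if (inclusive_upper) "]" else ")"),
               class = "qsrrkit_config_error")
  }
  invisible(x)
}
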