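#' Simulation configuration for synthetic chromatographic datasets
#'
#' Builds a validated configuration for [qsrr_simulate()]. The defaults
#' emulate the shape of a small reversed-phase LC dataset: ~97 pharmaceutical
#' compounds, 239 correlated molecular descriptors, five mobile-phase pH
#' conditions, retention times on a 0--20 min gradient scale, a sparse
#' lipophilicity-like signal whose coefficients drift with pH, a fifth of
#' compounds eluting before 2 min at every pH, and one structural outlier
#' sitting far outside the descriptor cloud.
#'
#' @param n_compounds Number of compounds (rows).
#' @param n_descriptors Number of molecular descriptors (columns).
#' @param n_informative Number of descriptors that truly drive retention.
#' @param ph_levels Strictly increasing pH values of the mobile phases.
#' @param block_size Width of the equicorrelated descriptor blocks.
#' @param intra_block_correlation Pairwise correlation within a block, in
#'   `[0, 1)`.
#' @param noise_sd Gaussian noise standard deviation on the log-retention
#'   scale.
#' @param coefficient_drift Relative random-walk step of the true
#'   coefficients per pH step (unitless).
#' @param n_outliers Number of structural outliers whose descriptors are
#'   shifted away from the cloud.
#' @param outlier_shift Outlier displacement in multiples of the per-feature
#'   standard deviation.
#' @param low_retention_fraction Fraction of compounds eluting below 2 min at
#'   every pH, in `[0, 1)`.
#' @param gradient_minutes Length of the elution gradient; retention times of
#'   regular compounds stay within `[0, gradient_minutes]`.
#' @param ph_jitter_sd Standard deviation of the small pH-to-pH perturbation
#'   of descriptor values (microspecies re-weighting changes descriptors
#'   slightly between pH conditions).
#' @param seed Integer root seed; every stage stream is derived from it.
#'
#' @return A `qsrr_sim_config` object (a validated list).
#' @seealso [qsrr_simulate()]
#' @export
#' @examples
#' cfg <- qsrr_sim_config(n_compounds = 30, n_descriptors = 20, seed = 1)
#' cfg$ph_levels
qsrr_sim_config <- function(n_compounds = 97,
                            n_descriptors = 239,
                            n_informative = 8,
                            ph_levels = c(2.7, 3.5, 5.0, 6.5, 8.0),
                            block_size = 10,
                            intra_block_correlation = 0.7,
                            noise_sd = 0.12,
                            coefficient_drift = 0.1,
                            n_outliers = 1,
                            outlier_shift = 10,
                            low_retention_fraction = 20 / 97,
                            gradient_minutes = 20,
                            ph_jitter_sd = 0.05,
                            seed = 1L) {
  check_count(n_compounds, "n_compounds", min = 4L)
  check_count(n_descriptors, "n_descriptors")
  check_count(n_informative, "n_informative")
  if (n_informative > n_descriptors) {
    qsrr_abort("`n_informative` must not exceed `n_descriptors`.",
               class = "qsrrkit_config_error")
  }
  if (!is.numeric(ph_levels) || length(ph_levels) < 1L ||
      any(!is.finite(ph_levels)) || is.unsorted(ph_levels, strictly = TRUE)) {
    qsrr_abort("`ph_levels` must be a nonempty strictly increasing numeric vector.",
               class = "qsrrkit_config_error")
  }
  check_count(block_size, "block_size")
  check_range(intra_block_correlation, "intra_block_correlation", 0, 1,
              inclusive_upper = FALSE)
  check_range(noise_sd, "noise_sd", 0, Inf)
  check_range(coefficient_drift, "coefficient_drift", 0, Inf)
  check_count(n_outliers, "n_outliers", min = 0L)
  check_range(outlier_shift, "outlier_shift", 0, Inf)
  check_range(low_retention_fraction, "low_retention_fraction", 0, 1,
              inclusive_upper = FALSE)
  check_range(gradient_minutes, "gradient_minutes", 1, Inf)
  check_range(ph_jitter_sd, "ph_jitter_sd", 0, Inf)
  if (n_outliers + ceiling(low_retention_fraction * n_compounds) >=
      n_compounds) {
    qsrr_abort("`n_outliers` plus low-retention compounds must leave regular compounds.",
               class = "qsrrkit_config_error")
  }
  check_count(seed, "seed", min = 0L)

  structure(
    list(
      n_compounds = as.integer(n_compounds),
      n_descriptors = as.integer(n_descriptors),
      n_informative = as.integer(n_informative),
      ph_levels = as.numeric(ph_levels),
      block_size = as.integer(block_size),
      intra_block_correlation = intra_block_correlation,
      noise_sd = noise_sd,
      coefficient_drift = coefficient_drift,
      n_outliers = as.integer(n_outliers),
      outlier_shift = outlier_shift,
      low_retention_fraction = low_retention_fraction,
      gradient_minutes = gradient_minutes,
      ph_jitter_sd = ph_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "qsrr_sim_config"
  )
}

#' @export
print.qsrr_sim_config <- function(x, ...) {
  cat("<qsrr_sim_config>\n")
  cat(sprintf("  %d compounds x %d descriptors, %d informative\n",
              x$n_compounds, x$n_descriptors, x$n_informative))
  cat(sprintf("  pH levels: %s\n", paste(x$ph_levels, collapse = ", ")))
  cat(sprintf("  noise sd (log scale): %g, coefficient drift: %g\n",
              x$noise_sd, x$coefficient_drift))
  cat(sprintf("  outliers: %d (shift %g sd), low-retention fraction: %.3f\n",
              x$n_outliers, x$outlier_shift, x$low_retention_fraction))
  invisible(x)
}

rt_column <- function(ph) sprintf("rt_pH%g", ph)

#' Generate a seeded synthetic chromatographic dataset
#'
#' Draws descriptors from an equicorrelated Gaussian block design, builds a
#' sparse linear signal (plus one pairwise interaction, so nonlinear learners
#' have a measurable edge) on the log-retention scale, lets the true
#' coefficients drift across pH, plants structural outliers and early-eluting
#' compounds, and exponentiates into minutes on the configured gradient.
#' The full ground truth (coefficients per pH, informative set, outlier and
#' low-retention indices, per-compound offsets) is returned in `$oracle` so
#' parameter-recovery tests can score any downstream method.
#'
#' Identical seeds give bit-identical datasets.
#'
#' @param config A [qsrr_sim_config()] object.
#' @return A `qsrr_dataset`: list with `compound_table` (tibble: compound_id,
#'   smiles placeholder, one `rt_pH*` column per pH), `descriptors` (named
#'   list of per-pH tibbles, compounds x descriptors), `oracle` (ground
#'   truth) and `config`.
#' @export
#' @examples
#' ds <- qsrr_simulate(qsrr_sim_config(n_compounds = 40, n_descriptors = 30,
#'                                     n_informative = 4, seed = 7))
#' ds$compound_table
qsrr_simulate <- function(config) {
  if (!inherits(config, "qsrr_sim_config")) {
    config <- do.call(qsrr_sim_config, as.list(config))
  }
  n <- config$n_compounds
  p <- config$n_descriptors
  phs <- config$ph_levels

  with_seed(derive_seed(config$seed, "simulate"), {
    ids <- sprintf("C%03d", seq_len(n))
    desc_names <- sprintf("D%03d", seq_len(p))

    # Equicorrelated Gaussian blocks: one latent factor per block.
    blocks <- rep(seq_len(ceiling(p / config$block_size)),
                  each = config$block_size)[seq_len(p)]
    rho <- config$intra_block_correlation
    factors <- matrix(rnorm(n * max(blocks)), n, max(blocks))
    X_base <- sqrt(rho) * factors[, blocks, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    colnames(X_base) <- desc_names

    informative <- sort(sample.int(p, config$n_informative))
    beta_base <- numeric(p)
    beta_base[informative] <- sample(c(-1, 1), config$n_informative, TRUE) *
      runif(config$n_informative, 0.5, 1.5)
    has_interaction <- config$n_informative >= 2L
    int_pair <- if (has_interaction) informative[1:2] else c(NA_integer_, NA_integer_)
    # the interaction carries a meaningful share of the signal (sd of the
    # product term = half the sd of the linear term), so kernel and tree
    # learners have something real to gain over purely linear fits
    int_weight_base <- if (has_interaction) {
      lin_sd <- sd(drop(X_base %*% beta_base))
      prod_sd <- sd(X_base[, int_pair[1L]] * X_base[, int_pair[2L]])
      0.5 * lin_sd / max(prod_sd, 1e-8)
    } else 0

    # Special-compound roles.
    n_low <- ceiling(config$low_retention_fraction * n)
    special <- sample.int(n, n_low + config$n_outliers)
    low_idx <- sort(special[seq_len(n_low)])
    out_idx <- sort(setdiff(special, special[seq_len(n_low)]))
    regular <- setdiff(seq_len(n), c(low_idx, out_idx))

    # Coefficient drift: multiplicative random walk across pH steps.
    n_ph <- length(phs)
    walk <- matrix(0, p, n_ph)
    if (n_ph > 1L) {
      steps <- matrix(rnorm(p * (n_ph - 1L)), p, n_ph - 1L)
      walk[, -1L] <- t(apply(steps, 1L, cumsum))
    }

    rt_max <- config$gradient_minutes
    lo <- log(0.125 * rt_max)   # noiseless regular compounds span
    hi <- log(0.950 * rt_max)   # ~2.5 to 19 min on a 20-min gradient

    coefs <- matrix(0, p, n_ph, dimnames = list(desc_names, as.character(phs)))
    intercepts <- numeric(n_ph)
    int_weights <- numeric(n_ph)
    offsets <- matrix(0, n, n_ph, dimnames = list(ids, as.character(phs)))
    rt <- matrix(NA_real_, n, n_ph, dimnames = list(ids, as.character(phs)))
    descriptors <- vector("list", n_ph)
    names(descriptors) <- as.character(phs)

    low_targets <- matrix(runif(n_low * n_ph, 0.3, 1.8), n_low, n_ph)

    for (j in seq_len(n_ph)) {
      X_ph <- X_base +
        config$ph_jitter_sd * matrix(rnorm(n * p), n, p)
      colnames(X_ph) <- desc_names

      beta_j <- beta_base * (1 + config$coefficient_drift * walk[, j])
      w_j <- int_weight_base *
        (1 + config$coefficient_drift * if (n_ph > 1L && j > 1L) mean(walk[informative, j]) else 0)

      latent_pre <- function(M) {
        drop(M %*% beta_j) + if (has_interaction) {
          w_j * M[, int_pair[1L]] * M[, int_pair[2L]]
        } else 0
      }

      # Shift outlier descriptors away from the cloud center after the
      # response is formed from the pre-shift values: structural outliers
      # break the descriptor-retention relationship.
      X_final <- X_ph
      if (length(out_idx)) {
        sds <- apply(X_ph, 2L, sd)
        dir_sign <- sample(c(-1, 1), p, TRUE)
        for (i in out_idx) {
          X_final[i, ] <- X_ph[i, ] + config$outlier_shift * sds * dir_sign
        }
      }

      lat0 <- latent_pre(X_ph)
      rng <- range(lat0[regular])
      a <- if (diff(rng) > 0) (hi - lo) / diff(rng) else 1
      b <- lo - a * rng[1L]

      beta_s <- a * beta_j
      w_s <- a * w_j
      ic <- b

      latent_final <- drop(X_final %*% beta_s) + ic + if (has_interaction) {
        w_s * X_final[, int_pair[1L]] * X_final[, int_pair[2L]]
      } else 0

      # Offsets absorb the special-compound deviations from the sparse
      # model so the oracle reproduces noiseless retention exactly.
      off <- numeric(n)
      if (length(out_idx)) {
        latent_unshifted <- a * lat0 + b
        off[out_idx] <- latent_unshifted[out_idx] - latent_final[out_idx]
      }
      if (n_low) {
        off[low_idx] <- log(low_targets[, j]) -
          (latent_final[low_idx] + off[low_idx])
        # note: composed so latent + off = log(target)
      }

      noise <- config$noise_sd * rnorm(n)
      rt_j <- exp(latent_final + off + noise)
      rt_j <- pmin(rt_j, rt_max)
      if (n_low) rt_j[low_idx] <- pmin(rt_j[low_idx], 1.99)

      coefs[, j] <- beta_s
      intercepts[j] <- ic
      int_weights[j] <- w_s
      offsets[, j] <- off
      rt[, j] <- rt_j
      descriptors[[j]] <- dplyr::bind_cols(
        tibble::tibble(compound_id = ids),
        tibble::as_tibble(X_final)
      )
    }

    compound_table <- dplyr::bind_cols(
      tibble::tibble(compound_id = ids, smiles = NA_character_),
      tibble::as_tibble(rt, .name_repair = "minimal") |>
        stats::setNames(rt_column(phs))
    )

    oracle <- list(
      informative = desc_names[informative],
      informative_idx = informative,
      coefficients = coefs,
      intercepts = stats::setNames(intercepts, as.character(phs)),
      interaction = list(
        features = if (has_interaction) desc_names[int_pair] else character(),
        weights = stats::setNames(int_weights, as.character(phs))
      ),
      offsets = offsets,
      outlier_ids = ids[out_idx],
      low_retention_ids = ids[low_idx],
      transform = "log"
    )

    structure(
      list(compound_table = compound_table, descriptors = descriptors,
           oracle = oracle, config = config),
      class = "qsrr_dataset"
    )
  })
}

#' @export
print.qsrr_dataset <- function(x, ...) {
  cat("<qsrr_dataset>\n")
  cat(sprintf("  %d compounds, %d descriptors, %d pH conditions\n",
              nrow(x$compound_table),
              ncol(x$descriptors[[1L]]) - 1L,
              length(x$descriptors)))
  cat(sprintf("  outliers: %s\n",
              if (length(x$oracle$outlier_ids)) paste(x$oracle$outlier_ids, collapse = ", ") else "none"))
  invisible(x)
}

#' Predict retention with the simulation ground truth
#'
#' Evaluates the oracle model (sparse linear term + interaction + intercept +
#' per-compound offsets, exponentiated back to minutes) at one pH. With
#' `noise_sd = 0` this reproduces the generated retention times exactly.
#'
#' @param dataset A `qsrr_dataset` from [qsrr_simulate()].
#' @param ph One of the dataset's pH levels.
#' @param newdata Optional descriptor tibble/matrix; defaults to the
#'   dataset's own descriptors at `ph` (only then are offsets applied).
#' @return Numeric vector of retention times in minutes.
#' @export
oracle_predict <- function(dataset, ph, newdata = NULL) {
  stopifnot(inherits(dataset, "qsrr_dataset"))
  key <- as.character(ph)
  if (!key %in% names(dataset$descriptors)) {
    qsrr_abort(sprintf("pH %s is not in the dataset (levels: %s).", key,
                       paste(names(dataset$descriptors), collapse = ", ")))
  }
  own_data <- is.null(newdata)
  X <- as_descriptor_matrix(if (own_data) dataset$descriptors[[key]] else newdata)
  orc <- dataset$oracle
  beta <- orc$coefficients[, key]
  lat <- drop(X[, names(beta), drop = FALSE] %*% beta) + orc$intercepts[[key]]
  if (length(orc$interaction$features) == 2L) {
    f <- orc$interaction$features
    lat <- lat + orc$interaction$weights[[key]] * X[, f[1L]] * X[, f[2L]]
  }
  if (own_data) lat <- lat + orc$offsets[, key]
  unname(exp(lat))
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the compound table as `compounds.csv`, one `descriptors_pH<value>.csv`
#' per pH, and the ground truth as `oracle.json`.
#'
#' @param dataset A `qsrr_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
qsrr_write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "qsrr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$compound_table, file.path(dir, "compounds.csv"))
  for (ph in names(dataset$descriptors)) {
    readr::write_csv(dataset$descriptors[[ph]],
                     file.path(dir, sprintf("descriptors_pH%s.csv", ph)))
  }
  orc <- dataset$oracle
  orc$coefficients <- as.data.frame(orc$coefficients)
  orc$offsets <- as.data.frame(orc$offsets)
  jsonlite::write_json(orc, file.path(dir, "oracle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
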