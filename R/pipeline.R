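#' The seven-model registry
#'
#' The comparison lineup: MLR and SVR each coupled with the CFS filter and
#' the RFE wrapper (linear learners cannot face all 239 collinear
#' descriptors directly), plus the three embedded learners (LASSO, RF, GBM)
#' on the full post-preprocessing feature set.
#'
#' @return A tibble: `key`, `algorithm`, `feature_source`.
#' @export
qsrr_model_lineup <- function() {
  tibble::tribble(
    ~key,       ~algorithm, ~feature_source,
    "MLR_CFS",  "MLR",      "cfs",
    "SVR_CFS",  "SVR_RBF",  "cfs",
    "MLR_RFE",  "MLR",      "rfe",
    "SVR_RFE",  "SVR_RBF",  "rfe",
    "Lasso",    "LASSO",    "all",
    "RF",       "RF",       "all",
    "GBM",      "GBR",      "all"
  )
}

# The five level-1 algorithms feeding the stacked ensemble.
stack_base_keys <- function() c("MLR_RFE", "Lasso", "SVR_RFE", "RF", "GBM")

default_pipeline_settings <- function() {
  list(
    folds = 10,
    cfs = list(max_features = NULL),
    rfe = list(learner = "LASSO", subset_sizes = c(5, 10, 20, 40), folds = 10),
    grids = list(),          # per-algorithm grid overrides (tibbles/data.frames)
    stack = list(mode = "out_of_fold", folds = 10),
    ad = list(k = 5, percentile = 95, aggregate = "any"),
    embedded_top_k = 20
  )
}

merge_settings <- function(defaults, overrides) {
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.data.frame(overrides[[nm]])) {
      defaults[[nm]] <- merge_settings(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Fit the full model lineup at one pH
#'
#' Runs CFS and RFE on the training half, fits the seven registry models by
#' cross-validated grid search, stacks the five level-1 learners, and
#' scores everything on the external set.
#'
#' @param entry One per-pH element of a `qsrr_split` (fields `train_X`,
#'   `train_y`, `test_X`, `test_y`, `ph`, `transform`).
#' @param settings Pipeline settings list (see [run_qsrr()]); missing
#'   entries take the defaults.
#' @param seed Integer seed for this pH's fits.
#' @param keys Registry keys to fit (default: the full seven-model lineup);
#'   must include the five stacking bases when a stack is wanted.
#' @return List: `models` (named list of `qsrr_model`), `stack`,
#'   `selections` (cfs/rfe/embedded), `performance` (tibble),
#'   `predictions` (external observed/predicted tibble), `ph`.
#' @export
fit_ph_models <- function(entry, settings = list(), seed = 1L,
                          keys = qsrr_model_lineup()$key) {
  st <- merge_settings(default_pipeline_settings(), settings)
  X <- entry$train_X
  y <- entry$train_y

  lineup <- qsrr_model_lineup()
  bad_keys <- setdiff(keys, lineup$key)
  if (length(bad_keys)) {
    qsrr_abort(sprintf("Unknown model keys: %s.",
                       paste(bad_keys, collapse = ", ")))
  }
  lineup <- lineup[lineup$key %in% keys, , drop = FALSE]

  need_cfs <- any(lineup$feature_source == "cfs")
  sel_cfs <- if (need_cfs) {
    cfs_select(X, y, max_features = st$cfs$max_features)
  }
  rfe_sizes <- st$rfe$subset_sizes
  rfe_sizes <- rfe_sizes[rfe_sizes <= ncol(X)]
  if (!length(rfe_sizes)) rfe_sizes <- ncol(X)
  sel_rfe <- rfe_select(X, y, learner = st$rfe$learner,
                        subset_sizes = rfe_sizes,
                        folds = st$rfe$folds,
                        seed = derive_seed(seed, "rfe"))

  models <- vector("list", nrow(lineup))
  names(models) <- lineup$key
  for (i in seq_len(nrow(lineup))) {
    key <- lineup$key[i]
    feats <- switch(lineup$feature_source[i],
                    cfs = sel_cfs$selected,
                    rfe = sel_rfe$selected,
                    all = NULL)
    cfg <- model_config(lineup$algorithm[i], features = feats,
                        grid = st$grids[[lineup$algorithm[i]]],
                        seed = derive_seed(seed, key))
    models[[key]] <- grid_search(cfg, X, y, folds = st$folds)
  }

  base_keys <- intersect(stack_base_keys(), names(models))
  if (length(base_keys) < 2L) {
    qsrr_abort("At least two of the stacking base models must be in `keys`.")
  }
  stack <- stack_fit(models[base_keys], X, y,
                     mode = st$stack$mode,
                     external_X = entry$test_X, external_y = entry$test_y,
                     folds = st$stack$folds,
                     seed = derive_seed(seed, "stack"))

  perf <- performance_table(models, entry$test_X, entry$test_y, stack = stack)

  pred <- stack_predict(stack, entry$test_X)
  predictions <- tibble::tibble(
    compound_id = rownames(entry$test_X),
    ph = entry$ph,
    observed = unname(entry$test_y),
    predicted = pred,
    residual = pred - unname(entry$test_y),
    observed_min = back_transform(unname(entry$test_y), entry$transform),
    predicted_min = back_transform(pred, entry$transform)
  )
  predictions$abs_error_min <- abs(predictions$predicted_min -
                                     predictions$observed_min)

  embedded <- purrr::map(models[intersect(c("Lasso", "RF", "GBM"),
                                          names(models))],
                         embedded_importances, top_k = st$embedded_top_k)

  selections <- c(if (need_cfs) list(cfs = sel_cfs),
                  list(rfe = sel_rfe), embedded)

  list(models = models, stack = stack,
       selections = selections,
       performance = perf, predictions = predictions, ph = entry$ph)
}

#' Run the complete QSRR workflow on a synthetic dataset
#'
#' End-to-end driver: generate (or accept) a dataset, apply the cleaning
#' rules (conjunctive sub-2-min retention filter, zero-variance removal),
#' split off the external set, standardize with training parameters, fit
#' the seven-model lineup plus the stacked ensemble at every pH, compute
#' the cross-pH rank summary, extract consensus features, and build the
#' kNN applicability-domain report (with the stacking model's per-compound
#' back-transformed errors).
#'
#' @param config A list or YAML file path with (all optional) entries:
#'   `sim` (arguments to [qsrr_sim_config()]), `n_test`, `transform`,
#'   `seed`, `stratify`, `force_outlier_test` (put planted outliers in the
#'   external set), `pipeline` (settings for [fit_ph_models()]: `folds`,
#'   `cfs`, `rfe`, `grids`, `stack`, `ad`, `embedded_top_k`).
#' @param dataset Optional pre-built `qsrr_dataset`; overrides `config$sim`.
#' @param out_dir Optional directory; when given, the per-pH performance
#'   tables, AD report, rank summary, consensus features, external
#'   predictions and a run log are written as plain-text files.
#' @return A `qsrr_run` object.
#' @export
run_qsrr <- function(config = list(), dataset = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  transform <- config$transform %||% "log"
  n_test <- config$n_test %||% 10

  if (is.null(dataset)) {
    sim_args <- config$sim %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(seed, "sim")
    dataset <- qsrr_simulate(do.call(qsrr_sim_config, sim_args))
  }

  filtered <- filter_low_retention(dataset$compound_table)
  keep_ids <- filtered$compound_id
  matrices <- purrr::map(dataset$descriptors, function(m) {
    m <- tibble::as_tibble(m)
    m <- m[match(keep_ids, m$compound_id), , drop = FALSE]
    remove_zero_variance(m)
  })

  force_test <- character()
  if (isTRUE(config$force_outlier_test)) {
    force_test <- intersect(dataset$oracle$outlier_ids, keep_ids)
  }
  split <- split_dataset(filtered, matrices, n_test = n_test,
                         seed = derive_seed(seed, "split"),
                         stratify = isTRUE(config$stratify),
                         force_test = force_test,
                         transform = transform)

  pipeline_settings <- config$pipeline %||% list()
  st <- merge_settings(default_pipeline_settings(), pipeline_settings)

  ph_results <- purrr::imap(split$per_ph, function(entry, key) {
    fit_ph_models(entry, settings = pipeline_settings,
                  seed = derive_seed(seed, paste0("ph", key)))
  })

  perf_tables <- purrr::map(ph_results, "performance")
  ranks <- rank_models(perf_tables, metric = "RMSE_test")

  consensus <- purrr::map(ph_results, function(r) {
    consensus_features(r$selections, embedded_top_k = st$embedded_top_k)
  })

  predictions <- dplyr::bind_rows(purrr::map(ph_results, "predictions"))

  adr <- ad_report(split, k = st$ad$k, percentile = st$ad$percentile,
                   aggregate = st$ad$aggregate)
  err_wide <- predictions |>
    dplyr::select("compound_id", "ph", "abs_error_min") |>
    tidyr::pivot_wider(names_from = "ph", values_from = "abs_error_min",
                       names_prefix = "error_pH")
  adr <- dplyr::left_join(err_wide, adr, by = "compound_id")
  class(adr) <- c("qsrr_ad_report", class(adr))

  run <- structure(
    list(dataset = dataset, split = split, ph_results = ph_results,
         performance = perf_tables, ranks = ranks,
         consensus_features = consensus, predictions = predictions,
         ad_report = adr, settings = st, seed = seed,
         transform = transform),
    class = "qsrr_run"
  )
  if (!is.null(out_dir)) qsrr_write_run(run, out_dir)
  run
}

#' @export
print.qsrr_run <- function(x, ...) {
  cat(sprintf("<qsrr_run> %d pH conditions, %d train / %d external compounds\n",
              length(x$ph_results), length(x$split$train_ids),
              length(x$split$test_ids)))
  cat("  mean ranks (external RMSE):\n")
  print(as.data.frame(x$ranks[, c("model", "mean_rank")]), row.names = FALSE)
  invisible(x)
}

#' Write a run's result tables as CSV/text
#'
#' Emits `performance_pH<value>.csv` per pH, `ad_report.csv`,
#' `rank_summary.csv`, `predictions.csv`, `consensus_features.txt`, and a
#' `run_log.txt` recording seed and settings. Numeric columns are printed
#' with full precision so identical runs produce byte-identical files.
#'
#' @param run A `qsrr_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
qsrr_write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(run$performance)) {
    readr::write_csv(run$performance[[key]],
                     file.path(out_dir, sprintf("performance_pH%s.csv", key)))
  }
  readr::write_csv(run$ad_report, file.path(out_dir, "ad_report.csv"))
  readr::write_csv(run$ranks, file.path(out_dir, "rank_summary.csv"))
  readr::write_csv(run$predictions, file.path(out_dir, "predictions.csv"))
  writeLines(
    unlist(purrr::imap(run$consensus_features, function(f, ph) {
      sprintf("pH %s: %s", ph, paste(f, collapse = ", "))
    })),
    file.path(out_dir, "consensus_features.txt")
  )
  writeLines(c(
    sprintf("seed: %d", run$seed),
    sprintf("transform: %s", run$transform),
    sprintf("train/test: %d/%d", length(run$split$train_ids),
            length(run$split$test_ids)),
    sprintf("qsrrkit version: %s",
            as.character(utils::packageVersion("qsrrkit")))
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Stacked-vs-single-model benchmark on synthetic data
#'
#' Repeats the core experiment on independent synthetic datasets: fit the
#' five level-1 learners at one pH, stack them out-of-fold, and compare the
#' stacked external RMSE with the best single base model's. Stacking should
#' be at worst marginally behind the best base model (and often ahead),
#' which this benchmark quantifies as a win rate.
#'
#' @param n_replicates Number of independent replicates (default 20).
#' @param seed Root seed.
#' @param sim_args Overrides for [qsrr_sim_config()] (the benchmark's
#'   dataset conditions).
#' @param settings Pipeline settings overrides; defaults to
#'   [stacking_benchmark_settings()], compact grids sized so a full
#'   20-replicate benchmark runs in minutes.
#' @param tolerance Multiplier defining a "win": stacked RMSE must be
#'   `<= tolerance * best base RMSE` (default 1.05).
#' @return A `qsrr_benchmark` tibble: one row per replicate with
#'   `rmse_stack`, `rmse_best_base`, `best_base`, `win`.
#' @export
stacking_benchmark <- function(n_replicates = 20, seed = 1L,
                               sim_args = list(),
                               settings = stacking_benchmark_settings(),
                               tolerance = 1.05) {
  rows <- purrr::map(seq_len(n_replicates), function(rep_i) {
    rep_seed <- derive_seed(seed, paste0("bench", rep_i))
    args <- merge_settings(list(seed = rep_seed), sim_args)
    args$seed <- rep_seed
    ds <- qsrr_simulate(do.call(qsrr_sim_config, args))

    filtered <- filter_low_retention(ds$compound_table)
    ph1 <- names(ds$descriptors)[1L]
    mat <- tibble::as_tibble(ds$descriptors[[ph1]])
    mat <- mat[match(filtered$compound_id, mat$compound_id), , drop = FALSE]
    mat <- remove_zero_variance(mat)
    split <- split_dataset(filtered, stats::setNames(list(mat), ph1),
                           n_test = 10, seed = rep_seed)
    entry <- split$per_ph[[1L]]

    res <- fit_ph_models(entry, settings = settings,
                         seed = derive_seed(rep_seed, "fit"),
                         keys = stack_base_keys())
    perf <- res$performance
    base <- perf[perf$model %in% stack_base_keys(), ]
    best_i <- which.min(base$RMSE_test)
    stack_rmse <- perf$RMSE_test[perf$model == "Stack"]
    tibble::tibble(
      replicate = rep_i,
      rmse_stack = stack_rmse,
      rmse_best_base = base$RMSE_test[best_i],
      best_base = base$model[best_i],
      win = stack_rmse <= tolerance * base$RMSE_test[best_i]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qsrr_benchmark", class(out))
  out
}

#' Default settings for the stacking benchmark
#'
#' Compact hyperparameter grids (SVR keeps its subset-aware default grid)
#' and 5-fold tuning with 10-fold out-of-fold stacking.
#'
#' @return A settings list for [fit_ph_models()].
#' @export
stacking_benchmark_settings <- function() {
  list(
    folds = 5,
    rfe = list(learner = "LASSO", subset_sizes = c(5, 10, 20, 40), folds = 5),
    grids = list(
      LASSO = data.frame(lambda = 10^seq(-3, 0, length.out = 7)),
      RF = data.frame(num_trees = 300, mtry = c(15, 79)),
      GBR = expand.grid(nrounds = c(150, 300), max_depth = c(2, 3),
                        eta = c(0.05, 0.1))
    ),
    stack = list(mode = "out_of_fold", folds = 10)
  )
}
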