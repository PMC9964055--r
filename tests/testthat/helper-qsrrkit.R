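# Shared fixtures, all generated in code.

# A small but fully featured synthetic dataset: 3 pH levels, one planted
# outlier, some early-eluting compounds.
small_dataset <- function(seed = 101, ...) {
  qsrr_simulate(qsrr_sim_config(
    n_compounds = 40, n_descriptors = 25, n_informative = 4,
    ph_levels = c(2.7, 5.0, 8.0), block_size = 5,
    intra_block_correlation = 0.6, noise_sd = 0.08,
    n_outliers = 1, outlier_shift = 10, low_retention_fraction = 0.15,
    seed = seed, ...
  ))
}

# Preprocess a dataset end to end: filter, zero-variance, split, standardize.
small_split <- function(ds, n_test = 6, seed = 7, ...) {
  filt <- filter_low_retention(ds$compound_table)
  mats <- lapply(ds$descriptors, function(m) {
    remove_zero_variance(m[match(filt$compound_id, m$compound_id), ])
  })
  split_dataset(filt, mats, n_test = n_test, seed = seed, ...)
}

# Plain sparse linear regression data with known support.
sparse_linear_data <- function(n = 100, p = 20, support = 1:3,
                               beta = c(2, -1.5, 1), sigma = 0.5, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("x%02d", seq_len(p))))
    y <- drop(X[, support, drop = FALSE] %*% beta) + sigma * rnorm(n)
    list(X = X, y = y, support = colnames(X)[support])
  })
}

# Light hyperparameter grids so pipeline-level tests stay fast.
fast_grids <- function() {
  list(
    LASSO = data.frame(lambda = 10^seq(-3, 0, length.out = 8)),
    SVR_RBF = expand.grid(cost = c(1, 4), gamma = NA, epsilon = 0.1),
    RF = data.frame(num_trees = 200, mtry = NA),
    GBR = expand.grid(nrounds = c(100, 300), max_depth = 2:3, eta = 0.1)
  )
}

# Fill data-dependent grid entries (gamma scale heuristic, mtry).
fill_fast_grids <- function(X) {
  g <- fast_grids()
  v <- mean(apply(X, 2, var))
  g$SVR_RBF$gamma <- 1 / (ncol(X) * v)
  g$RF$mtry <- max(1L, floor(sqrt(ncol(X))))
  g
}

fast_settings <- function(X) {
  list(
    folds = 5,
    rfe = list(learner = "LASSO", subset_sizes = c(5, 10, 20), folds = 5),
    grids = fill_fast_grids(X),
    stack = list(mode = "out_of_fold", folds = 5)
  )
}
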