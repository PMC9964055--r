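test_that("single-feature merit reduces to |cor(f, y)|", {
  withr::with_seed(2, {
    X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- rnorm(50)
    sel <- cfs_select(X, y, max_features = 1)
    expect_length(sel$selected, 1L)
    expect_equal(unname(sel$scores[sel$selected]),
                 abs(cor(X[, sel$selected], y)), tolerance = 1e-12)
    # and it picked the single best-correlated feature
    expect_equal(sel$selected, names(which.max(abs(drop(cor(X, y))))))
  })
})

test_that("an exact duplicate of a selected feature is never added", {
  withr::with_seed(5, {
    x1 <- rnorm(60)
    y <- x1 + rnorm(60, sd = 0.2)
    X <- cbind(a = x1, a_copy = x1, b = rnorm(60))
    sel <- cfs_select(X, y)
    expect_false(all(c("a", "a_copy") %in% sel$selected))
    # the merit formula proves it: with k = 2 and r_ff = 1 the merit
    # collapses to the single-feature value, so the strict-increase rule
    # never admits the duplicate
    cfy <- abs(drop(cor(X, y))); names(cfy) <- colnames(X)
    cff <- abs(cor(X))
    expect_lte(cfs_merit(cfy, cff, c("a", "a_copy")),
               cfs_merit(cfy, cff, "a") + 1e-12)
  })
})

test_that("greedy CFS matches exhaustive subset search on most small problems", {
  hits <- 0
  n_trials <- 100
  for (trial in seq_len(n_trials)) {
    withr::with_seed(1000 + trial, {
      X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
      y <- drop(X %*% runif(3, -1, 1)) + rnorm(50, sd = 0.5)
    })
    cfy <- abs(drop(cor(X, y))); names(cfy) <- colnames(X)
    cff <- abs(cor(X))
    subsets <- unlist(lapply(1:3, function(k) {
      utils::combn(colnames(X), k, simplify = FALSE)
    }), recursive = FALSE)
    best_exhaustive <- max(vapply(subsets, function(s) cfs_merit(cfy, cff, s),
                                  numeric(1)))
    sel <- cfs_select(X, y)
    got <- cfs_merit(cfy, cff, sel$selected)
    if (abs(got - best_exhaustive) < 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("CFS is invariant to feature-column order", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- X[, 2] - X[, 4] + rnorm(60, sd = 0.4)
    s1 <- cfs_select(X, y)
    s2 <- cfs_select(X[, sample(6)], y)
    expect_setequal(s1$selected, s2$selected)
  })
})

test_that("RFE recovers a perfect single predictor and the known support", {
  withr::with_seed(10, {
    X <- matrix(rnorm(80 * 5), 80, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- X[, 1]
    sel <- rfe_select(X, y, learner = "MLR", subset_sizes = 1, folds = 5)
    expect_equal(sel$selected, "x1")
  })

  dat <- sparse_linear_data(n = 500, p = 22, support = 1:2, beta = c(2, 3),
                            sigma = 0.5, seed = 77)
  sel <- rfe_select(dat$X, dat$y, learner = "MLR",
                    subset_sizes = c(1, 2, 3, 5, 10), folds = 10, seed = 3)
  expect_true(all(dat$support %in% sel$selected))
  # CV error profile bottoms out at (or above) the true support size
  prof <- sel$settings$profile
  expect_gte(prof$size[which.min(prof$cv_rmse)], 2L)
})

test_that("RFE with a single feature returns it", {
  withr::with_seed(12, {
    X <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "only"))
    y <- X[, 1] + rnorm(40, sd = 0.1)
    sel <- rfe_select(X, y, learner = "MLR", subset_sizes = 1, folds = 5)
    expect_equal(sel$selected, "only")
  })
})

test_that("selectors are deterministic under a fixed seed", {
  dat <- sparse_linear_data(n = 120, p = 15, seed = 31)
  s1 <- rfe_select(dat$X, dat$y, learner = "LASSO",
                   subset_sizes = c(3, 6, 10), folds = 5, seed = 9)
  s2 <- rfe_select(dat$X, dat$y, learner = "LASSO",
                   subset_sizes = c(3, 6, 10), folds = 5, seed = 9)
  expect_identical(s1$selected, s2$selected)
  l1 <- lasso_select(dat$X, dat$y, seed = 4)
  l2 <- lasso_select(dat$X, dat$y, seed = 4)
  expect_identical(l1$selected, l2$selected)
})

test_that("consensus is the intersection across methods", {
  a <- qsrrkit:::new_selection("cfs", c("f1", "f2", "f3"),
                               setNames(3:1, c("f1", "f2", "f3")))
  b <- qsrrkit:::new_selection("rfe", c("f2", "f3", "f4"),
                               setNames(3:1, c("f2", "f3", "f4")))
  c3 <- qsrrkit:::new_selection("embedded", c("f3", "f2", "f9"),
                                setNames(3:1, c("f3", "f2", "f9")))
  expect_equal(consensus_features(list(a, b, c3)), c("f2", "f3"))
  # a feature missing from one list is excluded
  expect_false("f1" %in% consensus_features(list(a, b, c3)))
  # embedded truncation applies before intersecting
  expect_equal(consensus_features(list(a, b, c3), embedded_top_k = 1), "f3")
  d <- qsrrkit:::new_selection("cfs", "zz", c(zz = 1))
  expect_warning(out <- consensus_features(list(a, d)), "empty")
  expect_length(out, 0L)
  expect_error(consensus_features(list(a)), "two")
})
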