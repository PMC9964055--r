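test_that("a singleton grid is chosen and ties go to grid order", {
  withr::with_seed(1, {
    X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- X[, 1] + rnorm(40, sd = 0.2)
  })
  m <- grid_search(model_config("GBR",
                                grid = data.frame(nrounds = 50, max_depth = 2,
                                                  eta = 0.1), seed = 1),
                   X, y, folds = 5)
  expect_equal(m$chosen$nrounds, 50)
  # duplicated grid point: the first one must win
  g2 <- data.frame(lambda = c(0.05, 0.05))
  m2 <- grid_search(model_config("LASSO", grid = g2, seed = 1), X, y,
                    folds = 5)
  expect_equal(m2$cv_rmse, m2$grid_results$cv_rmse[1])
})

test_that("grid search agrees with an independently coded exhaustive loop", {
  withr::with_seed(21, {
    X <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("x", 1:6)))
    y <- drop(X[, 1:2] %*% c(1.5, -1)) + 0.5 * X[, 1] * X[, 2] +
      rnorm(60, sd = 0.4)
  })
  grid <- expand.grid(cost = c(1, 4), epsilon = c(0.05, 0.1, 0.2))
  grid$gamma <- 1 / (ncol(X) * mean(apply(X, 2, var)))
  cfg <- model_config("SVR_RBF", grid = grid, seed = 5)
  m <- grid_search(cfg, X, y, folds = 5)

  # oracle: direct double loop over the same folds with e1071 itself
  fold_id <- cv_folds(60, 5, seed = 5)
  oracle_rmse <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(1:5, function(f) {
      tr <- fold_id != f
      fit <- e1071::svm(x = X[tr, ], y = y[tr], type = "eps-regression",
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], epsilon = grid$epsilon[g],
                        scale = FALSE)
      sqrt(mean((y[!tr] - predict(fit, X[!tr, ]))^2))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(m$grid_results$cv_rmse, oracle_rmse, tolerance = 1e-10)
  expect_equal(unlist(m$chosen[c("cost", "epsilon")]),
               unlist(grid[which.min(oracle_rmse), c("cost", "epsilon")]))
  # best point is no worse than any other grid point, by construction
  expect_true(all(m$cv_rmse <= m$grid_results$cv_rmse + 1e-12))
})

test_that("a LASSO penalty above the shrinkage bound zeroes every coefficient", {
  withr::with_seed(31, {
    X <- scale(matrix(rnorm(80 * 10), 80, 10,
                      dimnames = list(NULL, paste0("x", 1:10))))
    attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
    y <- drop(X[, 1:3] %*% c(1, -2, 0.5)) + rnorm(80, sd = 0.3)
  })
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  m <- grid_search(model_config("LASSO",
                                grid = data.frame(lambda = lambda_max * 1.05),
                                seed = 1), X, y, folds = 5)
  b <- as.numeric(coef(m$fit, s = m$fit$lambda[1]))[-1]
  expect_true(all(b == 0))
})

test_that("predictions honour each learner's degenerate contracts", {
  withr::with_seed(41, {
    X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "d")))
    beta <- c(2, -1, 0.5)
    y_lin <- drop(X %*% beta) + 1
  })
  # MLR interpolates noiseless linear data
  mlr <- grid_search(model_config("MLR", seed = 1), X, y_lin, folds = 5)
  expect_lt(max(abs(predict_model(mlr, X) - y_lin)), 1e-8)
  out <- fit_predict(mlr, X, transform = "log")
  expect_equal(out$.pred_min, exp(out$.pred), tolerance = 1e-12)

  # RF on constant y predicts that constant
  rf_reg <- qsrrkit:::learner_registry()$RF
  fit <- rf_reg$fit(X, rep(3.5, 30), list(num_trees = 100, mtry = 2), seed = 1)
  expect_equal(unique(rf_reg$predict(fit, X)), 3.5, tolerance = 1e-12)

  # SVR prediction at a training point stays within the epsilon tube when
  # the kernel sees the points as essentially independent (well separated)
  svr_reg <- qsrrkit:::learner_registry()$SVR_RBF
  two_X <- rbind(c(0, 0, 0), c(50, 50, 50))
  colnames(two_X) <- c("a", "b", "d")
  fit1 <- svr_reg$fit(two_X, c(5, 8),
                      list(cost = 10, gamma = 0.5, epsilon = 0.1), seed = 1)
  expect_lte(abs(svr_reg$predict(fit1, two_X[1, , drop = FALSE]) - 5),
             0.1 + 1e-6)

  # missing feature names are reported
  expect_error(predict_model(mlr, X[, 1:2]), "d")
})

test_that("embedded importances rank drivers and respect top_k", {
  withr::with_seed(51, {
    X <- matrix(rnorm(300 * 8), 300, 8, dimnames = list(NULL, paste0("x", 1:8)))
    y <- 2 * X[, 1] + rnorm(300, sd = 0.5)
  })
  # LASSO with exactly three nonzero coefficients -> list of length 3
  withr::with_seed(52, {
    y3 <- drop(X[, 1:3] %*% c(3, 2, 1.5)) + rnorm(300, sd = 0.3)
  })
  lasso <- grid_search(model_config("LASSO",
                                    grid = data.frame(lambda = 0.25),
                                    seed = 1), X, y3, folds = 5)
  sel <- embedded_importances(lasso, top_k = 20)
  expect_true(all(sel$selected %in% paste0("x", 1:3)))
  expect_lte(length(sel$selected), 3L)

  # RF puts the true driver first
  rf <- grid_search(model_config("RF",
                                 grid = data.frame(num_trees = 300, mtry = 3),
                                 seed = 2), X, y, folds = 5)
  sel_rf <- embedded_importances(rf, top_k = 5)
  expect_equal(sel_rf$selected[1], "x1")
  # importances are sorted non-increasing
  expect_true(all(diff(unname(sel_rf$scores)) <= 1e-12))

  mlr <- grid_search(model_config("MLR", seed = 1), X[, 1:3], y, folds = 5)
  expect_error(embedded_importances(mlr), "embedded")
})

test_that("grid search is deterministic and guards degenerate inputs", {
  withr::with_seed(61, {
    X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- X[, 1] + rnorm(50, sd = 0.3)
  })
  g <- data.frame(nrounds = c(50, 100), max_depth = 2, eta = 0.1)
  m1 <- grid_search(model_config("GBR", grid = g, seed = 7), X, y, folds = 5)
  m2 <- grid_search(model_config("GBR", grid = g, seed = 7), X, y, folds = 5)
  expect_identical(m1$chosen, m2$chosen)
  expect_identical(m1$grid_results, m2$grid_results)
  expect_identical(predict_model(m1, X), predict_model(m2, X))

  expect_error(grid_search(model_config("MLR", seed = 1),
                           matrix(rnorm(100), 10, 10,
                                  dimnames = list(NULL, paste0("x", 1:10))),
                           rnorm(10), folds = 5),
               "identifiable")
})
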