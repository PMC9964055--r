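# Base-learner registry. Each learner wraps an established implementation
# (lm, glmnet, e1071, ranger, xgboost) behind a uniform fit/predict/
# importance/default-grid interface so grid search, RFE and stacking can
# treat them interchangeably.

svr_gamma_scale <- function(X) {
  v <- mean(apply(X, 2L, var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

learner_registry <- function() {
  list(
    MLR = list(
      fit = function(X, y, params, seed) {
        df <- as.data.frame(X)
        df$.y <- y
        stats::lm(.y ~ ., data = df)
      },
      predict = function(fit, X) {
        unname(stats::predict(fit, newdata = as.data.frame(X)))
      },
      importance = function(fit, X, y, seed) {
        b <- stats::coef(fit)[-1L]
        b[is.na(b)] <- 0
        abs(stats::setNames(b, colnames(X)))
      },
      default_grid = function(X) tibble::tibble(.dummy = 1),
      embedded = FALSE
    ),
    LASSO = list(
      fit = function(X, y, params, seed) {
        glmnet::glmnet(X, y, alpha = 1, lambda = params$lambda,
                       standardize = FALSE)
      },
      predict = function(fit, X) {
        drop(stats::predict(fit, newx = X, s = fit$lambda[1L]))
      },
      importance = function(fit, X, y, seed) {
        b <- as.numeric(stats::coef(fit, s = fit$lambda[1L]))[-1L]
        abs(stats::setNames(b, colnames(X)))
      },
      default_grid = function(X) {
        tibble::tibble(lambda = 10^seq(-4, 1, length.out = 25))
      },
      embedded = TRUE
    ),
    SVR_RBF = list(
      fit = function(X, y, params, seed) {
        e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   cost = params$cost, gamma = params$gamma,
                   epsilon = params$epsilon, scale = FALSE)
      },
      predict = function(fit, X) {
        unname(stats::predict(fit, newdata = X))
      },
      importance = function(fit, X, y, seed) {
        permutation_importance(
          function(M) unname(stats::predict(fit, newdata = M)),
          X, y, n_shuffles = 10, seed = seed
        )
      },
      default_grid = function(X) {
        g0 <- svr_gamma_scale(X)
        tidyr::expand_grid(cost = c(0.25, 0.5, 1, 2, 4, 8),
                           gamma = g0 * c(0.25, 0.5, 1, 2, 4),
                           epsilon = c(0.01, 0.1, 0.2))
      },
      embedded = FALSE
    ),
    RF = list(
      fit = function(X, y, params, seed) {
        mtry <- min(max(1L, as.integer(round(params$mtry))), ncol(X))
        ranger::ranger(
          x = as.data.frame(X), y = y,
          num.trees = params$num_trees %||% 500,
          mtry = mtry, importance = "impurity",
          seed = seed, num.threads = 1L
        )
      },
      predict = function(fit, X) {
        stats::predict(fit, data = as.data.frame(X), num.threads = 1L)$predictions
      },
      importance = function(fit, X, y, seed) {
        imp <- fit$variable.importance
        out <- stats::setNames(numeric(ncol(X)), colnames(X))
        out[names(imp)] <- imp
        out
      },
      default_grid = function(X) {
        p <- ncol(X)
        tibble::tibble(
          num_trees = 500,
          mtry = unique(pmax(1L, as.integer(c(floor(p / 3), floor(sqrt(p)),
                                              floor(p / 2)))))
        )
      },
      embedded = TRUE
    ),
    GBR = list(
      fit = function(X, y, params, seed) {
        dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
        xgboost::xgb.train(
          params = list(max_depth = as.integer(params$max_depth),
                        eta = params$eta,
                        objective = "reg:squarederror",
                        nthread = 1L, seed = seed),
          data = dtrain,
          nrounds = as.integer(params$nrounds),
          verbose = 0
        )
      },
      predict = function(fit, X) {
        unname(stats::predict(fit, newdata = X))
      },
      importance = function(fit, X, y, seed) {
        out <- stats::setNames(numeric(ncol(X)), colnames(X))
        imp <- tryCatch(xgboost::xgb.importance(model = fit),
                        error = function(e) NULL)
        if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
        out
      },
      default_grid = function(X) {
        tidyr::expand_grid(nrounds = seq(100, 1000, by = 150),
                           max_depth = 1:3,
                           eta = c(0.01, 0.05, 0.1))
      },
      embedded = TRUE
    )
  )
}

#' Permutation importance of features under a fitted prediction function
#'
#' Mean increase in RMSE over seeded shuffles of one feature at a time;
#' the importance measure used inside RFE for learners without native
#' coefficients (kernel SVR).
#'
#' @param predict_fun Function mapping a matrix to predictions.
#' @param X Feature matrix the model was trained on.
#' @param y Targets.
#' @param n_shuffles Shuffles per feature.
#' @param seed Integer seed.
#' @return Named numeric vector of importances (>= 0 after flooring at 0).
#' @export
permutation_importance <- function(predict_fun, X, y, n_shuffles = 10,
                                   seed = 1L) {
  base <- rmse(y, predict_fun(X))
  with_seed(derive_seed(seed, "perm_imp"), {
    imp <- vapply(seq_len(ncol(X)), function(j) {
      deltas <- vapply(seq_len(n_shuffles), function(s) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        rmse(y, predict_fun(Xp)) - base
      }, numeric(1))
      mean(deltas)
    }, numeric(1))
    pmax(stats::setNames(imp, colnames(X)), 0)
  })
}
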