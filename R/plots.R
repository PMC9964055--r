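# ggplot2 displays for the main result types. Every plot draws from a
# tibble the package also exposes, so tests assert the numbers, not pixels.

#' @method autoplot qsrr_run
#' @export
autoplot.qsrr_run <- function(object, minutes = TRUE, ...) {
  df <- object$predictions
  if (minutes) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$observed_min,
                                          y = .data$predicted_min))
    labs <- ggplot2::labs(x = "Observed retention (min)",
                          y = "Predicted retention (min)",
                          title = "Stacked ensemble: external test set")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$observed,
                                          y = .data$predicted))
    labs <- ggplot2::labs(x = "Observed (modeling scale)",
                          y = "Predicted (modeling scale)",
                          title = "Stacked ensemble: external test set")
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::facet_wrap(~ph, labeller = ggplot2::label_both) +
    labs +
    ggplot2::theme_minimal()
}

#' Residuals of the stacked model on the external set, per pH
#'
#' @param run A `qsrr_run`.
#' @param minutes Plot back-transformed errors in minutes (default) or
#'   modeling-scale residuals.
#' @return A ggplot object.
#' @export
plot_residuals <- function(run, minutes = TRUE) {
  stopifnot(inherits(run, "qsrr_run"))
  df <- run$predictions
  if (minutes) {
    df$res <- df$predicted_min - df$observed_min
    ylab <- "Prediction error (min)"
  } else {
    df$res <- df$residual
    ylab <- "Residual (modeling scale)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed_min, y = .data$res)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::facet_wrap(~ph, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Observed retention (min)", y = ylab,
                  title = "Stacked ensemble residuals") +
    ggplot2::theme_minimal()
}

#' @method autoplot qsrr_ranks
#' @export
autoplot.qsrr_ranks <- function(object, ...) {
  df <- object
  df$model <- factor(df$model, levels = df$model[order(df$mean_rank)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$mean_rank)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Mean rank across pH (lower is better)",
                  title = "Model ranking by external RMSE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot qsrr_ad_report
#' @export
autoplot.qsrr_ad_report <- function(object, ...) {
  long <- object |>
    dplyr::select("compound_id", dplyr::starts_with("distance_pH")) |>
    tidyr::pivot_longer(-"compound_id", names_to = "ph",
                        values_to = "distance",
                        names_prefix = "distance_pH")
  thr <- object |>
    dplyr::select(dplyr::starts_with("threshold_pH")) |>
    dplyr::slice(1L) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "ph",
                        values_to = "threshold",
                        names_prefix = "threshold_pH")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$compound_id,
                                     y = .data$distance)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~ph, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "Mean 5-NN distance (standardized space)",
                  title = "Applicability domain: external compounds vs threshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' @method tidy qsrr_model
#' @export
tidy.qsrr_model <- function(x, ...) {
  x$grid_results
}

#' @method glance qsrr_model
#' @export
glance.qsrr_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(algorithm = x$algorithm,
                   n_features = length(x$feature_names),
                   cv_rmse = x$cv_rmse, cv_r2 = x$cv_r2),
    tibble::as_tibble(x$chosen[setdiff(names(x$chosen), ".dummy")])
  )
}
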