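# ggplot2 views of the main result types.

#' Plot dissolution profiles
#'
#' @param ds A dissolution dataset.
#' @return A ggplot: Q (%) against time, one curve per formulation.
#' @export
plot_profiles <- function(ds) {
  ds <- validate_dissolution_data(ds)
  ggplot2::ggplot(ds, ggplot2::aes(x = .data$t_min, y = .data$Q_pct,
                                   colour = .data$formulation_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Time [min]", y = "Drug released [%]",
                  colour = "Formulation") +
    ggplot2::theme_minimal()
}

#' @rdname collective_sensitivity
#' @param object A `sensitivity_ranking`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sensitivity_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$input, -.data$mean_score),
    y = .data$mean_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Input", y = "Mean sensitivity score") +
    ggplot2::theme_minimal()
}

#' @rdname mlp_train
#' @param object An `mlp_trace`.
#' @exportS3Method ggplot2::autoplot
autoplot.mlp_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("epoch", "train_rmse", "test_rmse")],
    cols = c("train_rmse", "test_rmse"),
    names_to = "set", values_to = "rmse")
  df <- df[is.finite(df$rmse), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$rmse,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Epoch (log scale)", y = "RMSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname crossval_fit
#' @param object A `dissolution_cv`.
#' @exportS3Method ggplot2::autoplot
autoplot.dissolution_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$held_out_formulation)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Observed Q [%]", y = "Predicted Q [%]",
                  colour = "Held-out") +
    ggplot2::theme_minimal()
}

#' @rdname evolve_direct
#' @param object A `gp_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.gp_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$best_rmse)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Generation", y = "Best RMSE") +
    ggplot2::theme_minimal()
}
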