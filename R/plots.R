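#' Concentration-time plot
#'
#' Semi-log concentration-time curves by arm, one panel per drug, from a
#' long-format record table or simulated profile tibble.
#'
#' @param data Tibble with `drug`, `time`, `group`, `id` and either `dv`
#'   (records) or `conc` (profiles).
#' @return A ggplot object.
#' @export
plot_concentration <- function(data) {
  ycol <- if ("conc" %in% names(data)) "conc" else "dv"
  df <- data[!is.na(data[[ycol]]) & data[[ycol]] > 0, ]
  if ("evid" %in% names(df)) df <- df[df$evid == 0L, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data[[ycol]],
                                   colour = .data$group,
                                   group = interaction(.data$id, .data$group))) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~drug, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (pg/mL)", colour = NULL)
}

#' Plot a visual predictive check
#'
#' Observed 5th/50th/95th percentiles (points/lines) over the 95%
#' simulation bands of the same percentiles (ribbons), per arm.
#'
#' @param object A `pk_vpc` from [vpc_bands()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_vpc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, group = .data$stat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med), colour = "steelblue",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.9) +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(title = paste("VPC:", attr(object, "drug")),
                  x = "Time (h)", y = "Concentration (pg/mL)")
}

#' Plot the cross-validation curve of a LASSO fit
#'
#' Mean cross-validated squared error against log10(lambda), with the
#' lambda-min choice marked.
#'
#' @param object A `pk_lasso` from [lasso_lambda_min()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_lasso <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda, cvm = object$cvm)
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$lambda), .data$cvm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_vline(xintercept = log10(object$lambda_min), linetype = 2) +
    ggplot2::labs(x = "log10(lambda)", y = "CV mean squared error",
                  title = paste("LASSO CV curve:", object$response))
}
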