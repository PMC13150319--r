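#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a bivariate line fit
#'
#' Points plus the fitted line (SMA or OLS), axis labels taken from the
#' fit.
#'
#' @param object A `conduit_lf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conduit_lf <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept) +
    ggplot2::labs(
      x = object$labels[["x"]], y = object$labels[["y"]],
      title = sprintf("%s fit: slope %.2f (%.2f-%.2f), r2 = %.2f",
                      object$method, object$slope, object$slope_ci[1],
                      object$slope_ci[2], object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Observed versus baseline-predicted tip conduit counts
#'
#' One panel of points per record: observed tip counts (black) against
#' basal counts, with each scenario's predictions overlaid in log10
#' space. Baselines sitting above the observed cloud indicate
#' overprediction, the signature of absent furcation.
#'
#' @param object A `furcation_comparison`.
#' @param data Optional branch table supplying the observed points (only
#'   needed for the observed layer's basal counts; inferred from
#'   predictions otherwise).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.furcation_comparison <- function(object, data = NULL, ...) {
  preds <- object$predictions
  obs <- dplyr::distinct(preds, .data$species_id, .data$n_tip_obs)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = preds,
      ggplot2::aes(x = .data$species_id, y = .data$log10_pred,
                   colour = .data$kind),
      alpha = 0.5, size = 1
    ) +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$species_id, y = log10(.data$n_tip_obs)),
      colour = "black", size = 1.5
    ) +
    ggplot2::labs(x = NULL, y = "log10 N_tip (observed black)",
                  colour = "baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
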