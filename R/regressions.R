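#' Tip-versus-base conduit-number allometry
#'
#' The central furcation test: SMA regression of log10 tip conduit count on
#' log10 basal conduit count. Furcation is a multiplicative hypothesis —
#' if conduits multiply as they narrow distally, tip counts grow faster
#' than base counts and the log-log slope exceeds 1; no furcation predicts
#' a slope of exactly 1 (isometry). The returned fit carries the
#' slope-equals-1 test in `slope1_test`.
#'
#' @param data A branch table (see [as_branch_table()]).
#' @param alpha CI level is `1 - alpha`.
#' @return An `sma_fit` with `labels` set and `slope1_test` attached
#'   (output of [test_slope()] at `b0 = 1`).
#' @export
number_allometry <- function(data, alpha = 0.05) {
  data <- as_branch_table(data, attr(data, "provenance") %||% "user")
  x <- log10(data$n_base)
  y <- log10(data$n_tip)
  fit <- fit_sma(x, y, alpha = alpha)
  fit$labels <- c(x = "log10 N_base", y = "log10 N_tip")
  fit$slope1_test <- test_slope(x, y, b0 = 1)
  fit
}

#' Segment-length effect on tip conduit number
#'
#' Multiple regression of log10 tip count on log10 basal count plus
#' (log10) segment length. If conduits furcate, longer segments host more
#' branching events, so length should add predictive power (positive,
#' significant coefficient); under the constant-number null it should not.
#'
#' @param data A branch table.
#' @param log_length Enter segment length as log10 cm (default, consistent
#'   with log-transforming all variables) or raw cm.
#' @param alpha CI level is `1 - alpha`.
#' @return A `conduit_mlr`; the length term is named `log10_L_segment`
#'   (or `L_segment_cm` when `log_length = FALSE`).
#' @export
length_effect <- function(data, log_length = TRUE, alpha = 0.05) {
  data <- as_branch_table(data, attr(data, "provenance") %||% "user")
  L <- segment_length(data)
  if (any(L <= 0)) stop("non-positive segment length", call. = FALSE)
  X <- data.frame(log10_N_base = log10(data$n_base))
  if (log_length) {
    X$log10_L_segment <- log10(L)
  } else {
    X$L_segment_cm <- L
  }
  fit_ols(log10(data$n_tip), X, alpha = alpha)
}

#' Tip-to-base conduit widening regression
#'
#' OLS regression of log10 mean lumen diameter on log10 distance from the
#' shoot apex, pooling both measurements of every branch (the apical
#' section at its own apex distance and the basal section at its), giving
#' `2 n` points. Hydraulic-optimality models predict a slope near 0.2:
#' conduits widen tip-to-base just fast enough to keep whole-path
#' resistance roughly independent of path length.
#'
#' @param data A branch table.
#' @param alpha CI level is `1 - alpha`.
#' @return An `ols_fit` on the pooled points.
#' @export
widening_regression <- function(data, alpha = 0.05) {
  data <- as_branch_table(data, attr(data, "provenance") %||% "user")
  x <- log10(c(data$dist_tip_cm, data$dist_base_cm))
  y <- log10(c(data$d_tip_um, data$d_base_um))
  fit <- fit_line_ols(x, y, alpha = alpha)
  fit$labels <- c(x = "log10 distance from apex (cm)",
                  y = "log10 mean lumen diameter (um)")
  fit
}
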