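#' Standardized major axis (model II) regression
#'
#' Fits the SMA line, the symmetric line-fitting method appropriate when
#' neither variable causes the other (both are outcomes of a shared
#' process, here conduit counts laid down concurrently by the cambium).
#' The slope is `sign(r) * sd(y) / sd(x)` and the intercept passes the line
#' through the bivariate mean. Equivalently, the SMA line minimizes the
#' summed areas of the right triangles formed between each point and the
#' line.
#'
#' Confidence intervals use the standard SMA construction: the slope CI is
#' `b * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = F(1 - alpha; 1, n - 2) * (1 - r^2) / (n - 2)`, and the intercept CI
#' is t-based on `var(a) = s2_res / n + xbar^2 * b^2 (1 - r^2) / (n - 2)`
#' where `s2_res` is the residual variance of `y - b x` on `n - 2` degrees
#' of freedom. The association p-value is the two-sided test of `r = 0`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite, each with
#'   nonzero variance.
#' @param alpha CI level is `1 - alpha` (default 0.05).
#' @return An object of class `c("sma_fit", "conduit_lf")`: a list with
#'   `slope`, `intercept`, `slope_ci`, `intercept_ci`, `r`, `r2`, `pvalue`
#'   (association), `pvalue_intercept` (two-sided test of intercept = 0),
#'   `n`, `method = "SMA"`, `alpha`, and the data.
#' @seealso [test_slope()] for testing the slope against a hypothesized
#'   value, [fit_line_ols()] for the ordinary least-squares line.
#' @export
fit_sma <- function(x, y, alpha = 0.05) {
  check_bivariate(x, y)
  n <- length(x)
  r <- stats::cor(x, y)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  b <- sign2(r) * sy / sx
  a <- mean(y) - b * mean(x)

  Bq <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  lo <- b * (sqrt(Bq + 1) - sqrt(Bq))
  hi <- b * (sqrt(Bq + 1) + sqrt(Bq))
  slope_ci <- sort(c(lo, hi))

  res <- y - b * x
  s2_res <- sum((res - mean(res))^2) / (n - 2)
  var_b <- b^2 * (1 - r^2) / (n - 2)
  se_a <- sqrt(s2_res / n + mean(x)^2 * var_b)
  tq <- stats::qt(1 - alpha / 2, n - 2)
  intercept_ci <- c(a - tq * se_a, a + tq * se_a)
  p_int <- 2 * stats::pt(-abs(a / se_a), n - 2)

  t_r <- r * sqrt((n - 2) / (1 - r^2))
  pvalue <- 2 * stats::pt(-abs(t_r), n - 2)

  structure(list(
    slope = b, intercept = a,
    slope_ci = slope_ci, intercept_ci = intercept_ci,
    r = r, r2 = r^2, pvalue = pvalue, pvalue_intercept = p_int,
    n = n, method = "SMA", alpha = alpha,
    x = x, y = y, labels = c(x = "x", y = "y")
  ), class = c("sma_fit", "conduit_lf"))
}

#' Test an SMA slope against a hypothesized value
#'
#' The SMA slope equals `b0` exactly when the residual scores `y - b0 x`
#' and axis scores `y + b0 x` are uncorrelated, so the test is the
#' two-sided test of zero correlation between those scores on `n - 2`
#' degrees of freedom. Under the no-furcation null the log-log slope of
#' tip on base conduit counts is 1.
#'
#' @param x,y Numeric vectors as in [fit_sma()].
#' @param b0 Hypothesized slope (nonzero; default 1).
#' @return A list with `statistic` (t), `df`, `p.value`, `r_scores` (the
#'   residual-axis correlation) and `b0`.
#' @export
test_slope <- function(x, y, b0 = 1) {
  check_bivariate(x, y)
  if (!is.finite(b0) || b0 == 0) stop("b0 must be nonzero", call. = FALSE)
  n <- length(x)
  rs <- suppressWarnings(stats::cor(y - b0 * x, y + b0 * x))
  if (!is.finite(rs)) rs <- 0  # degenerate scores: slope matches b0 exactly
  tt <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  list(statistic = tt, df = n - 2, p.value = min(p, 1), r_scores = rs,
       b0 = b0)
}

#' Ordinary least-squares line with SMA-compatible reporting
#'
#' Bivariate OLS fit (via [stats::lm()]) packaged with the same fields as
#' [fit_sma()] so the two line-fitting methods are interchangeable
#' downstream. Used for the conduit-widening regression, where distance
#' from the apex is the natural predictor.
#'
#' @inheritParams fit_sma
#' @return An object of class `c("ols_fit", "conduit_lf")`.
#' @export
fit_line_ols <- function(x, y, alpha = 0.05) {
  check_bivariate(x, y)
  n <- length(x)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, level = 1 - alpha))
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  r <- stats::cor(x, y)
  structure(list(
    slope = unname(cf[2]), intercept = unname(cf[1]),
    slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
    r = r, r2 = sm$r.squared,
    pvalue = unname(sm$coefficients[2, 4]),
    pvalue_intercept = unname(sm$coefficients[1, 4]),
    n = n, method = "OLS", alpha = alpha,
    x = x, y = y, labels = c(x = "x", y = "y"), lm = fit
  ), class = c("ols_fit", "conduit_lf"))
}

#' Multiple linear regression with per-predictor inference
#'
#' Least-squares fit of a response on a predictor matrix (via
#' [stats::lm()]), with t-based confidence intervals and p-values per
#' coefficient. Errors if the design is rank-deficient, naming the
#' collinear columns.
#'
#' @param y Numeric response vector.
#' @param X Numeric matrix or data frame of predictors with column names.
#' @param alpha CI level is `1 - alpha`.
#' @return An object of class `"conduit_mlr"`: coefficients table
#'   (`coefficients`, a tibble), `r2`, `n`, `alpha`, and the underlying
#'   `lm` fit.
#' @export
fit_ols <- function(y, X, alpha = 0.05) {
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X))
  if (length(y) <= ncol(X) + 1) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  dat <- cbind(data.frame(.y = y), X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (fit$rank < ncol(X) + 1) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  ci <- suppressWarnings(stats::confint(fit, level = 1 - alpha))
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, 1]),
    std.error = unname(sm$coefficients[, 2]),
    statistic = unname(sm$coefficients[, 3]),
    p.value = unname(sm$coefficients[, 4]),
    conf.low = unname(ci[, 1]),
    conf.high = unname(ci[, 2])
  )
  coefs$term[coefs$term == "(Intercept)"] <- "intercept"
  structure(list(
    coefficients = coefs, r2 = sm$r.squared, n = length(y),
    alpha = alpha, lm = fit
  ), class = "conduit_mlr")
}

check_bivariate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y (degenerate input)", call. = FALSE)
  }
  invisible(TRUE)
}

# sign() that treats r = 0 as positive so a slope is always defined
sign2 <- function(r) if (r < 0) -1 else 1

#' @export
print.conduit_lf <- function(x, ...) {
  cat(sprintf("%s fit (n = %d)\n", x$method, x$n))
  cat(sprintf("  slope     %.4f  [%.4f, %.4f]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.4f  [%.4f, %.4f]\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  r2 = %.3f, P = %s\n", x$r2, format_pvalue(x$pvalue)))
  invisible(x)
}

#' @export
print.conduit_mlr <- function(x, ...) {
  cat(sprintf("Multiple regression (n = %d, r2 = %.3f)\n", x$n, x$r2))
  print(x$coefficients)
  invisible(x)
}
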