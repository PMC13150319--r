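#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bivariate line fit
#'
#' @param x A `conduit_lf` (SMA or OLS line fit).
#' @param ... Unused.
#' @return Tibble with one row per term (`slope`, `intercept`).
#' @export
tidy.conduit_lf <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf.low = c(x$slope_ci[1], x$intercept_ci[1]),
    conf.high = c(x$slope_ci[2], x$intercept_ci[2]),
    p.value = c(x$pvalue, x$pvalue_intercept)
  )
}

#' Glance at a bivariate line fit
#'
#' @param x A `conduit_lf`.
#' @param ... Unused.
#' @return One-row tibble: `r`, `r.squared`, `p.value`, `nobs`, `method`.
#' @export
glance.conduit_lf <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r2, p.value = x$pvalue,
                 nobs = x$n, method = x$method)
}

#' Tidy a multiple regression fit
#'
#' @param x A `conduit_mlr`.
#' @param ... Unused.
#' @return The per-term coefficient tibble (estimate, SE, t, p, CI).
#' @export
tidy.conduit_mlr <- function(x, ...) {
  x$coefficients
}

#' Glance at a multiple regression fit
#'
#' @param x A `conduit_mlr`.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `nobs`.
#' @export
glance.conduit_mlr <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n)
}

#' Tidy a phylogenetic RMA fit
#'
#' @param x A `phylo_rma_fit`.
#' @param ... Unused.
#' @return Tibble with rows `slope` and `intercept`.
#' @export
tidy.phylo_rma_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' Glance at a phylogenetic RMA fit
#'
#' @param x A `phylo_rma_fit`.
#' @param ... Unused.
#' @return One-row tibble: `lambda`, `logLik`, `nobs`.
#' @export
glance.phylo_rma_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, logLik = x$loglik, nobs = x$n)
}

#' Tidy a furcation comparison
#'
#' @param x A `furcation_comparison`.
#' @param ... Unused.
#' @return The per-record prediction tibble.
#' @export
tidy.furcation_comparison <- function(x, ...) {
  x$predictions
}

#' Glance at a furcation comparison
#'
#' @param x A `furcation_comparison`.
#' @param ... Unused.
#' @return The per-scenario summary tibble.
#' @export
glance.furcation_comparison <- function(x, ...) {
  x$summary
}
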