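#' Default furcation baseline set
#'
#' The 3–30 cm fixed-internode sweep (3 cm steps), geometric contraction
#' with `lambda = 0.7`, da Vinci area conservation, and Murray's law.
#'
#' @param L_b_grid Internode lengths for the fixed sweep, cm.
#' @param lambda_len Geometric contraction factor.
#' @return List of [furcation_scenario()] objects.
#' @export
default_scenarios <- function(L_b_grid = seq(3, 30, by = 3),
                              lambda_len = 0.7) {
  c(
    lapply(L_b_grid, function(lb) furcation_scenario("fixed", L_b = lb)),
    list(furcation_scenario("geometric", lambda_len = lambda_len),
         furcation_scenario("davinci"),
         furcation_scenario("murray"))
  )
}

#' Run the full furcation analysis
#'
#' End-to-end orchestration: load or accept a branch table, run the three
#' regressions (tip-vs-base conduit-number SMA, segment-length multiple
#' regression, tip-to-base widening), optionally the phylogenetic RMA
#' against a user-supplied chronogram, and compare observed tip counts
#' with every furcation baseline. Re-running on identical inputs yields
#' an identical report.
#'
#' @param data A branch table, or `NULL` to read from `input`.
#' @param input Path to a canonical branch CSV (used when `data` is
#'   `NULL`).
#' @param tree Optional [ape::phylo] chronogram or path to a Newick file.
#' @param scenarios List of furcation scenarios (default
#'   [default_scenarios()]).
#' @param alpha CI level is `1 - alpha` for all fits.
#' @return A `furcation_report`: list with `data`, `validation`,
#'   `number_allometry`, `length_effect`, `widening`, `phylo_rma` (or
#'   `NULL`), `comparison`, `provenance`, `version`.
#' @export
run_furcation_analysis <- function(data = NULL, input = NULL, tree = NULL,
                                   scenarios = default_scenarios(),
                                   alpha = 0.05) {
  if (is.null(data) && is.null(input)) {
    stop("configuration error: supply `data` or `input`", call. = FALSE)
  }
  if (is.null(data)) data <- read_branch_table(input)
  data <- as_branch_table(data, attr(data, "provenance") %||% "user")
  report_validation <- validate_branches(data)
  if (any(report_validation$severity == "error")) {
    stop("validation failure: ",
         sum(report_validation$severity == "error"),
         " record-level error(s); see validate_branches()", call. = FALSE)
  }
  if (is.character(tree)) tree <- read_chronogram(tree)

  res <- list(
    data = data,
    validation = report_validation,
    number_allometry = number_allometry(data, alpha = alpha),
    length_effect = length_effect(data, alpha = alpha),
    widening = widening_regression(data, alpha = alpha),
    phylo_rma = if (!is.null(tree)) phylo_number_allometry(data, tree),
    comparison = compare_scenarios(data, scenarios),
    provenance = attr(data, "provenance"),
    version = as.character(utils::packageVersion("conduitr"))
  )
  class(res) <- "furcation_report"
  res
}

#' Regression summary table
#'
#' One row per fitted model — the conduit-number SMA, the multiple
#' regression with segment length, and the widening OLS — with slope and
#' intercept estimates, confidence intervals, r-squared and p-values.
#'
#' @param report A `furcation_report`.
#' @return A tibble.
#' @export
regression_table <- function(report) {
  stopifnot(inherits(report, "furcation_report"))
  na <- report$number_allometry
  le <- report$length_effect
  wd <- report$widening
  cf <- le$coefficients
  base_row <- cf[cf$term == "log10_N_base", ]
  int_row <- cf[cf$term == "intercept", ]
  len_row <- cf[grepl("L_segment", cf$term), ]
  tibble::tibble(
    response = c("log10 N_tip", "log10 N_tip", "log10 diameter"),
    predictors = c("log10 N_base",
                   "log10 N_base + segment length",
                   "log10 distance from apex"),
    method = c("SMA", "OLS", "OLS"),
    slope = c(na$slope, base_row$estimate, wd$slope),
    slope_lo = c(na$slope_ci[1], base_row$conf.low, wd$slope_ci[1]),
    slope_hi = c(na$slope_ci[2], base_row$conf.high, wd$slope_ci[2]),
    intercept = c(na$intercept, int_row$estimate, wd$intercept),
    intercept_lo = c(na$intercept_ci[1], int_row$conf.low,
                     wd$intercept_ci[1]),
    intercept_hi = c(na$intercept_ci[2], int_row$conf.high,
                     wd$intercept_ci[2]),
    r2 = c(na$r2, le$r2, wd$r2),
    p = c(na$pvalue, base_row$p.value, wd$pvalue),
    p_length = c(NA_real_, len_row$p.value, NA_real_)
  )
}

#' Write a furcation report to disk
#'
#' Emits the regression summary CSV, the per-branch prediction CSV, and a
#' JSON report (fits, scenario summaries, provenance). Byte-identical
#' across runs on identical inputs.
#'
#' @param report A `furcation_report`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "furcation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    regressions = file.path(dir, "regressions.csv"),
    predictions = file.path(dir, "predictions.csv"),
    report = file.path(dir, "report.json")
  )
  readr::write_csv(regression_table(report), paths[["regressions"]])
  readr::write_csv(report$comparison$predictions, paths[["predictions"]])
  fit_json <- function(f) {
    list(slope = f$slope, intercept = f$intercept,
         slope_ci = f$slope_ci, intercept_ci = f$intercept_ci,
         r2 = f$r2, p = f$pvalue, n = f$n, method = f$method)
  }
  jsonlite::write_json(list(
    provenance = report$provenance,
    version = report$version,
    number_allometry = c(fit_json(report$number_allometry),
                         list(p_slope_eq_1 =
                                report$number_allometry$slope1_test$p.value)),
    length_effect = list(coefficients = report$length_effect$coefficients,
                         r2 = report$length_effect$r2,
                         n = report$length_effect$n),
    widening = fit_json(report$widening),
    phylo_rma = if (!is.null(report$phylo_rma)) {
      list(slope = report$phylo_rma$slope,
           intercept = report$phylo_rma$intercept,
           lambda = report$phylo_rma$lambda,
           loglik = report$phylo_rma$loglik,
           n = report$phylo_rma$n)
    },
    scenario_summary = report$comparison$summary
  ), paths[["report"]], auto_unbox = TRUE, digits = NA, dataframe = "rows",
  null = "null")
  invisible(paths)
}

#' @export
print.furcation_report <- function(x, ...) {
  cat("Furcation analysis of", nrow(x$data), "branches (",
      x$provenance, ")\n\n", sep = "")
  print(regression_table(x))
  cat(sprintf("\nSMA slope = 1 test: P = %s\n",
              format_pvalue(x$number_allometry$slope1_test$p.value)))
  if (!is.null(x$phylo_rma)) {
    cat("\n")
    print(x$phylo_rma)
  }
  cat("\n")
  print(x$comparison$summary)
  invisible(x)
}

#' Display-format a p-value
#'
#' Values below the conventional 2.2e-16 floor print as "< 2.2e-16".
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", format(signif(p, 2)))
}
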