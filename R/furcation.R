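#' Define a furcation baseline scenario
#'
#' A furcation scenario predicts, from each branch's basal measurements,
#' the tip conduit count expected if conduits branched along the stem the
#' way classical network models assume:
#'
#' * `"fixed"` — a branching event every `L_b` cm of path, each parent
#'   splitting into `b` daughters, so `N_tip = N_base * b^(L/L_b)`.
#' * `"geometric"` — internode lengths contract by a factor `lambda_len`
#'   per level from base to tip (distalmost internode `L_n`), the number
#'   of levels coming from the finite geometric series of internode
#'   lengths; daughters per parent again `b`.
#' * `"davinci"` — conservation of summed conduit cross-sectional area:
#'   `N_tip = R^2 * N_base` with `R = d_base / d_tip`.
#' * `"murray"` — conservation of the summed cube of conduit radii
#'   (minimum pumping work subject to volume cost): `N_tip = R^3 * N_base`.
#'
#' @param kind One of `"fixed"`, `"geometric"`, `"davinci"`, `"murray"`.
#' @param b Branching ratio, daughters per parent conduit (integer >= 2,
#'   default 2, symmetric bifurcation).
#' @param L_b Fixed internode length in cm (`kind = "fixed"` only).
#' @param lambda_len Per-level internode length reduction factor in (0, 1)
#'   (`kind = "geometric"` only; default 0.7).
#' @param L_n Distalmost internode length in cm (default 1).
#' @return A `furcation_scenario` list with a `p` field (radius-moment
#'   exponent, 2 for da Vinci, 3 for Murray) for conservation kinds.
#' @export
furcation_scenario <- function(kind = c("fixed", "geometric", "davinci",
                                        "murray"),
                               b = 2, L_b = NULL, lambda_len = 0.7,
                               L_n = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(b), b >= 2, b == round(b))
  sc <- list(kind = kind, b = b, L_b = NULL, lambda_len = NULL, L_n = L_n,
             p = NULL)
  if (kind == "fixed") {
    if (is.null(L_b) || !is.numeric(L_b) || L_b <= 0) {
      stop("kind = \"fixed\" needs L_b > 0 (cm)", call. = FALSE)
    }
    sc$L_b <- L_b
  }
  if (kind == "geometric") {
    if (!is.numeric(lambda_len) || lambda_len <= 0 || lambda_len >= 1) {
      stop("lambda_len must lie in (0, 1)", call. = FALSE)
    }
    if (L_n <= 0) stop("L_n must be > 0", call. = FALSE)
    sc$lambda_len <- lambda_len
  }
  if (kind == "davinci") sc$p <- 2
  if (kind == "murray") sc$p <- 3
  structure(sc, class = "furcation_scenario")
}

#' @export
print.furcation_scenario <- function(x, ...) {
  cat("furcation scenario:", x$kind)
  if (x$kind == "fixed") cat(sprintf(" (b = %d, L_b = %g cm)", x$b, x$L_b))
  if (x$kind == "geometric") {
    cat(sprintf(" (b = %d, lambda = %g, L_n = %g cm)", x$b, x$lambda_len,
                x$L_n))
  }
  if (!is.null(x$p)) cat(sprintf(" (R^%d conservation)", x$p))
  cat("\n")
  invisible(x)
}

#' Branching events under fixed internode spacing
#'
#' With one furcation event every `L_b` cm, a segment of length
#' `L_segment` hosts `n = L_segment / L_b` events. `n` is kept continuous;
#' the predictors never round it.
#'
#' @param L_segment Segment length(s), cm, > 0 (0 allowed: no events).
#' @param L_b Internode length, cm, > 0.
#' @return Numeric vector of event counts.
#' @export
n_events_fixed <- function(L_segment, L_b) {
  stopifnot(all(L_segment >= 0), L_b > 0)
  L_segment / L_b
}

#' Basal internode length under geometric contraction
#'
#' If internode lengths shrink by `lambda_len` per level down to a
#' distalmost internode of `L_n` cm, the finite geometric series fixes the
#' basal (longest) internode at `L_0 = (1 - lambda) * L_segment +
#' lambda * L_n`.
#'
#' @param L_segment Segment length(s), cm, must exceed `L_n`.
#' @param lambda_len Contraction factor in (0, 1).
#' @param L_n Distalmost internode length, cm (default 1).
#' @return `L_0` in cm.
#' @export
l0_geometric <- function(L_segment, lambda_len, L_n = 1) {
  stopifnot(lambda_len > 0, lambda_len < 1, L_n > 0)
  if (any(L_segment <= L_n)) {
    stop("L_segment must exceed L_n (no room for contraction)",
         call. = FALSE)
  }
  (1 - lambda_len) * L_segment + lambda_len * L_n
}

#' Branching events under geometric internode contraction
#'
#' Inverts the finite geometric series
#' `L_segment = L_0 * sum_{k=0}^{n} lambda^k` with `L_0` from
#' [l0_geometric()], giving the continuous level count
#' `n = log_lambda(1 - L_segment (1 - lambda) / L_0) - 1`. At the returned
#' `n` the distalmost internode is exactly `L_0 * lambda^n = L_n`.
#'
#' @inheritParams l0_geometric
#' @return Continuous event count `n >= 0`.
#' @export
n_events_geometric <- function(L_segment, lambda_len, L_n = 1) {
  L0 <- l0_geometric(L_segment, lambda_len, L_n)
  arg <- 1 - L_segment * (1 - lambda_len) / L0
  if (any(arg <= 0)) stop("log argument <= 0 in geometric inversion",
                          call. = FALSE)
  log(arg) / log(lambda_len) - 1
}

# Core predictor: all products in log10 space; raw counts materialized
# only when they fit comfortably in a double (< 1e15).
materialize_pred <- function(log10_pred) {
  ifelse(log10_pred < 15, 10^log10_pred, NA_real_)
}

#' Predicted tip count under fixed internode spacing
#'
#' `N_tip = N_base * b^n` with `n = L_segment / L_b`. Computed in log10
#' space; `n_tip_pred` is `NA` (with `log10_pred` still exact) when the
#' prediction exceeds 1e15.
#'
#' @param n_base Basal conduit count(s).
#' @param L_segment Segment length(s), cm.
#' @param L_b Internode length, cm.
#' @param b Branching ratio (default 2).
#' @return Tibble with `n_events`, `log10_pred`, `n_tip_pred`.
#' @export
predict_fixed <- function(n_base, L_segment, L_b, b = 2) {
  stopifnot(all(n_base >= 1))
  n <- n_events_fixed(L_segment, L_b)
  lp <- log10(n_base) + n * log10(b)
  tibble::tibble(n_events = n, log10_pred = lp,
                 n_tip_pred = materialize_pred(lp))
}

#' Predicted tip count under geometric internode contraction
#'
#' Levels from [n_events_geometric()] substituted into
#' `N_tip = N_base * b^n`.
#'
#' @inheritParams predict_fixed
#' @param lambda_len Contraction factor in (0, 1).
#' @param L_n Distalmost internode length, cm.
#' @return Tibble with `n_events`, `log10_pred`, `n_tip_pred`.
#' @export
predict_geometric <- function(n_base, L_segment, lambda_len = 0.7,
                              L_n = 1, b = 2) {
  stopifnot(all(n_base >= 1))
  n <- ifelse(L_segment == L_n, 0,
              n_events_geometric(pmax(L_segment, L_n + 1e-12), lambda_len,
                                 L_n))
  lp <- log10(n_base) + n * log10(b)
  tibble::tibble(n_events = n, log10_pred = lp,
                 n_tip_pred = materialize_pred(lp))
}

#' Predicted tip count under radius-moment conservation
#'
#' With `R = d_base / d_tip` (equal to the radius ratio),
#' `N_tip = R^p * N_base`: `p = 2` conserves summed cross-sectional area
#' (da Vinci's rule), `p = 3` conserves the summed cube of radii
#' (Murray's law). When the tip is as wide as or wider than the base
#' (`R <= 1`) the prediction is still computed and the row is flagged
#' `no_widening`.
#'
#' @param n_base Basal conduit count(s).
#' @param d_base_um,d_tip_um Mean lumen diameters, micrometers, > 0.
#' @param p Radius-moment exponent, 2 or 3.
#' @return Tibble with `R`, `log10_pred`, `n_tip_pred`, `no_widening`.
#' @export
predict_conservation <- function(n_base, d_base_um, d_tip_um, p) {
  stopifnot(all(n_base >= 1), all(d_base_um > 0), all(d_tip_um > 0),
            p %in% c(2, 3))
  R <- d_base_um / d_tip_um
  lp <- log10(n_base) + p * log10(R)
  tibble::tibble(R = R, log10_pred = lp,
                 n_tip_pred = materialize_pred(lp),
                 no_widening = R <= 1)
}

#' Per-branch predictions for one scenario
#'
#' Applies a [furcation_scenario()] to every record of a branch table and
#' compares with the observed tip counts.
#'
#' @param data A branch table.
#' @param scenario A `furcation_scenario`.
#' @return Tibble with one row per record: `species_id`, `kind`, `params`
#'   (compact label), `n_events` (NA for conservation kinds), `n_tip_obs`,
#'   `log10_pred`, `n_tip_pred`, `log10_ratio` = log10(pred / observed).
#' @export
predict_scenario <- function(data, scenario) {
  stopifnot(inherits(scenario, "furcation_scenario"))
  data <- as_branch_table(data, attr(data, "provenance") %||% "user")
  L <- segment_length(data)
  pred <- switch(scenario$kind,
    fixed = predict_fixed(data$n_base, L, scenario$L_b, scenario$b),
    geometric = predict_geometric(data$n_base, L, scenario$lambda_len,
                                  scenario$L_n, scenario$b),
    davinci = predict_conservation(data$n_base, data$d_base_um,
                                   data$d_tip_um, p = 2L),
    murray = predict_conservation(data$n_base, data$d_base_um,
                                  data$d_tip_um, p = 3L)
  )
  params <- switch(scenario$kind,
    fixed = sprintf("b=%d, L_b=%g", scenario$b, scenario$L_b),
    geometric = sprintf("b=%d, lambda=%g, L_n=%g", scenario$b,
                        scenario$lambda_len, scenario$L_n),
    davinci = "p=2", murray = "p=3")
  tibble::tibble(
    species_id = data$species_id,
    kind = scenario$kind,
    params = params,
    n_events = if ("n_events" %in% names(pred)) pred$n_events else NA_real_,
    n_tip_obs = data$n_tip,
    log10_pred = pred$log10_pred,
    n_tip_pred = pred$n_tip_pred,
    log10_ratio = pred$log10_pred - log10(data$n_tip)
  )
}

#' Fixed-spacing predictions over a grid of internode lengths
#'
#' One prediction per (record, `L_b`) pair; the default grid is the
#' 3-to-30 cm sweep in 3 cm steps. Shorter internodes mean more branching
#' events and larger overpredictions.
#'
#' @param data A branch table.
#' @param L_b_values Numeric vector of internode lengths, cm.
#' @param b Branching ratio.
#' @return Tibble as in [predict_scenario()], plus an `L_b` column.
#' @export
sweep_fixed <- function(data, L_b_values = seq(3, 30, by = 3), b = 2) {
  purrr::map_dfr(L_b_values, function(lb) {
    out <- predict_scenario(data, furcation_scenario("fixed", b = b,
                                                     L_b = lb))
    out$L_b <- lb
    out
  })
}

#' Compare observed tip counts with furcation baselines
#'
#' Runs every scenario over the branch table and summarises, per scenario,
#' the fraction of records the baseline overpredicts (strictly
#' `pred > observed`; ties, within 1e-12 in log10, do not count) and the
#' median log10
#' prediction/observation ratio. If stem conduits do not furcate, every
#' baseline should overpredict.
#'
#' @param data A branch table.
#' @param scenarios List of [furcation_scenario()] objects.
#' @return A `furcation_comparison`: list with `predictions` (per record
#'   per scenario) and `summary` (per scenario: `kind`, `params`, `n`,
#'   `frac_over`, `median_log10_ratio`).
#' @export
compare_scenarios <- function(data, scenarios) {
  stopifnot(is.list(scenarios))
  if (length(scenarios) == 0) {
    preds <- tibble::tibble(species_id = character(), kind = character(),
                            params = character(), n_events = numeric(),
                            n_tip_obs = numeric(), log10_pred = numeric(),
                            n_tip_pred = numeric(), log10_ratio = numeric())
  } else {
    preds <- purrr::map_dfr(scenarios, ~ predict_scenario(data, .x))
  }
  summary <- preds |>
    dplyr::group_by(.data$kind, .data$params) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_over = mean(.data$log10_ratio > 1e-12),
      median_log10_ratio = stats::median(.data$log10_ratio),
      .groups = "drop"
    )
  structure(list(predictions = preds, summary = summary),
            class = "furcation_comparison")
}

#' @export
print.furcation_comparison <- function(x, ...) {
  cat("Furcation baseline comparison\n")
  print(x$summary)
  invisible(x)
}
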