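#' Configuration of the synthetic branch generator
#'
#' The generator emulates the measurement design the analysis assumes:
#' terminal branches 0.6–7.7 m long sampled once near the apex and once at
#' the base, mean lumen diameters following a `distance^0.2` widening
#' power law with lognormal noise, basal conduit counts spread over
#' orders of magnitude, and tip counts equal to base counts up to small
#' multiplicative noise (the no-furcation null) unless a furcation
#' scenario is injected.
#'
#' @param n_species Number of branches (one per species; default 112).
#' @param length_range_cm Range of apex-to-base distances, cm, drawn
#'   log-uniformly (default 60–770).
#' @param tip_offset_range_cm Range of apex-to-tip distances, cm, drawn
#'   uniformly (default 5–30).
#' @param widening_exponent Widening power-law exponent `b` in
#'   `D = 10^ref * distance^b` (default 0.2).
#' @param widening_ref_log10 log10 diameter (um) at 1 cm from the apex
#'   (default 1.2, putting generated diameters roughly in 10–300 um).
#' @param sigma_d SD of log10 diameter noise, applied independently at tip
#'   and base (default 0.25).
#' @param log10_nbase_range Range of log10 basal conduit counts, drawn
#'   uniformly (default 1.5–4.0).
#' @param sigma_n SD of log10 multiplicative noise on the tip count about
#'   its null/scenario value (default 0.06).
#' @param scenario `NULL` for the no-furcation null, or a
#'   [furcation_scenario()] whose prediction replaces the null tip count.
#' @param seed Integer seed; mandatory, every draw is a pure function of
#'   the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 112,
                       length_range_cm = c(60, 770),
                       tip_offset_range_cm = c(5, 30),
                       widening_exponent = 0.2,
                       widening_ref_log10 = 1.2,
                       sigma_d = 0.25,
                       log10_nbase_range = c(1.5, 4.0),
                       sigma_n = 0.06,
                       scenario = NULL,
                       seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("seed is mandatory for the generator", call. = FALSE)
  }
  stopifnot(n_species >= 1,
            length(length_range_cm) == 2, diff(length_range_cm) >= 0,
            length(tip_offset_range_cm) == 2,
            diff(tip_offset_range_cm) >= 0,
            tip_offset_range_cm[2] < length_range_cm[1],
            sigma_d >= 0, sigma_n >= 0,
            length(log10_nbase_range) == 2, diff(log10_nbase_range) >= 0)
  if (!is.null(scenario)) stopifnot(inherits(scenario, "furcation_scenario"))
  structure(list(
    n_species = as.integer(n_species),
    length_range_cm = length_range_cm,
    tip_offset_range_cm = tip_offset_range_cm,
    widening_exponent = widening_exponent,
    widening_ref_log10 = widening_ref_log10,
    sigma_d = sigma_d,
    log10_nbase_range = log10_nbase_range,
    sigma_n = sigma_n,
    scenario = scenario,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a branch measurement table
#'
#' Draws one branch per species under the config's measurement model:
#' `dist_base ~ logUniform(length_range)`,
#' `dist_tip ~ Uniform(tip_offset_range)`; diameters
#' `10^(ref + b log10(dist) + eps)` with `eps ~ N(0, sigma_d)`
#' independently at the two sections; `n_base = round(10^U(range))`; and
#' `n_tip = round(n_base * 10^eta)` with `eta ~ N(0, sigma_n)` under the
#' null, or `round(pred * 10^eta)` with `pred` the scenario's predicted
#' tip count when a furcation scenario is injected. Counts are floored at
#' 1. Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return A branch table; the config (including seed) is attached as the
#'   `"sim_config"` attribute and echoed in `"provenance"`.
#' @export
simulate_branches <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  out <- with_local_seed(cf$seed, {
    n <- cf$n_species
    dist_base <- 10^stats::runif(n, log10(cf$length_range_cm[1]),
                                 log10(cf$length_range_cm[2]))
    dist_tip <- stats::runif(n, cf$tip_offset_range_cm[1],
                             cf$tip_offset_range_cm[2])
    dia <- function(dist) {
      10^(cf$widening_ref_log10 +
            cf$widening_exponent * log10(dist) +
            stats::rnorm(n, 0, cf$sigma_d))
    }
    d_tip <- dia(dist_tip)
    d_base <- dia(dist_base)
    n_base <- pmax(1, round(10^stats::runif(n, cf$log10_nbase_range[1],
                                            cf$log10_nbase_range[2])))
    eta <- stats::rnorm(n, 0, cf$sigma_n)
    if (is.null(cf$scenario)) {
      center <- n_base
    } else {
      tmp <- tibble::tibble(
        species_id = sprintf("sp%03d", seq_len(n)),
        n_base = n_base, n_tip = n_base,
        d_base_um = d_base, d_tip_um = d_tip,
        dist_base_cm = dist_base, dist_tip_cm = dist_tip
      )
      center <- predict_scenario(tmp, cf$scenario)$n_tip_pred
      if (any(!is.finite(center))) {
        stop("scenario prediction overflows double precision; ",
             "use milder scenario parameters", call. = FALSE)
      }
    }
    n_tip <- pmax(1, round(center * 10^eta))
    tibble::tibble(
      species_id = sprintf("sp%03d", seq_len(n)),
      n_base = n_base, n_tip = n_tip,
      d_base_um = d_base, d_tip_um = d_tip,
      dist_base_cm = dist_base, dist_tip_cm = dist_tip,
      branched = FALSE
    )
  })
  out <- as_branch_table(out, provenance = sprintf("simulated(seed=%d)",
                                                   cf$seed))
  attr(out, "sim_config") <- cf
  out
}

#' Simulate a pure-birth ultrametric tree
#'
#' Yule (pure-birth) tree via [ape::rphylo()], rescaled to unit
#' root-to-tip depth. Deterministic given the seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric [ape::phylo] with tip labels `t1...tn` and
#'   depth 1.
#' @export
simulate_tree <- function(n_tips, seed) {
  stopifnot(n_tips >= 2)
  tree <- with_local_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate correlated Brownian traits on a tree
#'
#' Draws a bivariate trait matrix from the matrix normal with row
#' covariance `lambda_transform(phylo_vcv(tree), lambda)` and column
#' covariance `rate_matrix`, about a fixed root mean — the model the
#' phylogenetic RMA assumes, used for lambda-recovery checks.
#'
#' @param tree An [ape::phylo] object.
#' @param rate_matrix 2x2 positive-definite evolutionary rate matrix.
#' @param lambda Pagel's lambda used to generate (default 1).
#' @param seed Integer seed.
#' @param root Numeric root state, length 2 (default c(0, 0)).
#' @return Tibble with `species`, `x`, `y`.
#' @export
simulate_bm_traits <- function(tree, rate_matrix, lambda = 1, seed,
                               root = c(0, 0)) {
  stopifnot(is.matrix(rate_matrix), all(dim(rate_matrix) == 2))
  ev <- eigen(rate_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("rate_matrix must be positive-definite",
                         call. = FALSE)
  C <- lambda_transform(phylo_vcv(tree), lambda)
  n <- nrow(C)
  A <- t(chol(C))          # A A' = C
  B <- chol(rate_matrix)   # B' B = rate_matrix
  Z <- with_local_seed(seed, matrix(stats::rnorm(n * 2), n, 2))
  X <- A %*% Z %*% B
  tibble::tibble(species = tree$tip.label,
                 x = root[1] + X[, 1], y = root[2] + X[, 2])
}

# Run code under a temporary RNG state so generators are pure functions
# of their seed and never disturb the caller's stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
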