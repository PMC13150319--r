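#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian trait evolution the expected covariance between two tips
#' is the shared root-to-MRCA path length, and each tip's variance is its
#' root-to-tip depth. Delegates to [ape::vcv()].
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @return Symmetric positive-definite matrix, tips in `tree$tip.label`
#'   order.
#' @export
phylo_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label) > 0) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` is full Brownian covariance, `lambda = 0` makes
#' species independent.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Signal parameter in \[0, 1\].
#' @return Transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  out <- lambda * C
  diag(out) <- diag(C)
  out
}

#' Phylogenetic reduced major axis regression
#'
#' RMA (model II) regression of one trait on another, accounting for
#' phylogenetic non-independence under Brownian motion with Pagel's lambda
#' estimated by maximum likelihood (a single lambda common to both
#' traits). With covariance `C_lambda`, the phylogenetic (GLS) trait means
#' are `a = (1' C^-1 1)^-1 1' C^-1 T`, the evolutionary covariance matrix
#' is `V = (T - 1 a')' C^-1 (T - 1 a') / (n - 1)`, and the RMA slope is
#' `sign(V_xy) * sqrt(V_yy / V_xx)` with intercept `a_y - slope * a_x`.
#' The profiled bivariate Brownian log-likelihood
#' `-(1/2) [m(n-1) + n log|V| + m log|C_lambda| + n m log 2 pi]` (m = 2)
#' is maximized over lambda on \[0, 1\] by an 11-point grid pre-scan
#' followed by bounded scalar optimization (tolerance 1e-8).
#'
#' Tips without trait data are pruned; trait values without a matching tip
#' are dropped. Species labels are normalized with [normalize_species()]
#' before matching.
#'
#' @param x,y Named numeric vectors (names are species labels), or
#'   unnamed vectors in tip order.
#' @param tree An ultrametric [ape::phylo] chronogram.
#' @param fix_lambda Optional fixed lambda in \[0, 1\]; skips estimation.
#' @return An object of class `"phylo_rma_fit"`: `slope`, `intercept`,
#'   `lambda`, `loglik`, `n`, `means` (GLS trait means), `V` (evolutionary
#'   covariance), `pruned_tips`, `trait_names`.
#' @export
fit_phylo_rma <- function(x, y, tree, fix_lambda = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(x)) && length(x) == length(tree$tip.label)) {
    names(x) <- tree$tip.label
  }
  if (is.null(names(y)) && length(y) == length(tree$tip.label)) {
    names(y) <- tree$tip.label
  }
  names(x) <- normalize_species(names(x))
  names(y) <- normalize_species(names(y))
  tips <- normalize_species(tree$tip.label)
  keep <- tips[tips %in% names(x) & tips %in% names(y) &
                 is.finite(x[tips]) & is.finite(y[tips])]
  pruned <- setdiff(tips, keep)
  if (length(keep) < 4) {
    stop("need at least 4 tree tips with trait data", call. = FALSE)
  }
  if (length(pruned) > 0) {
    tree <- ape::drop.tip(tree, tree$tip.label[!(tips %in% keep)])
  }
  ord <- normalize_species(tree$tip.label)
  T_mat <- cbind(x = unname(x[ord]), y = unname(y[ord]))
  C <- phylo_vcv(tree)
  n <- nrow(C)

  # For an ultrametric tree the diagonal of C is constant, so
  # C_lambda = lambda C + (1 - lambda) d I shares C's eigenvectors and
  # every likelihood evaluation is O(n) after one eigendecomposition.
  d0 <- C[1, 1]
  ultra <- max(abs(diag(C) - d0)) <= 1e-8 * d0
  if (ultra) {
    eig <- eigen(C, symmetric = TRUE)
    U <- eig$vectors
    ev <- eig$values
    Tt <- crossprod(U, T_mat)       # U' T
    ot <- drop(crossprod(U, rep(1, n)))
    profile <- function(lam) {
      e <- lam * ev + (1 - lam) * d0
      w <- 1 / e
      s11 <- sum(w * ot * ot)
      sT <- colSums(w * ot * Tt)    # 1' C^-1 T
      a <- sT / s11
      R <- Tt - outer(ot, a)        # rotated residuals
      Vm <- crossprod(R, w * R) / (n - 1)
      list(a = a, V = Vm, logdetC = sum(log(e)))
    }
  } else {
    profile <- function(lam) {
      Cl <- lambda_transform(C, lam)
      ch <- chol(Cl)
      one <- rep(1, n)
      Ci1 <- backsolve(ch, forwardsolve(t(ch), one))
      CiT <- backsolve(ch, forwardsolve(t(ch), T_mat))
      s11 <- sum(one * Ci1)
      a <- drop(crossprod(T_mat, Ci1)) / s11
      R <- sweep(T_mat, 2, a)
      CiR <- backsolve(ch, forwardsolve(t(ch), R))
      Vm <- crossprod(R, CiR) / (n - 1)
      list(a = a, V = Vm, logdetC = 2 * sum(log(diag(ch))))
    }
  }
  m <- 2
  loglik_at <- function(lam) {
    pr <- profile(lam)
    dV <- determinant(pr$V, logarithm = TRUE)$modulus
    -0.5 * (m * (n - 1) + n * as.numeric(dV) + m * pr$logdetC +
              n * m * log(2 * pi))
  }

  if (!is.null(fix_lambda)) {
    if (fix_lambda < 0 || fix_lambda > 1) {
      stop("fix_lambda must lie in [0, 1]", call. = FALSE)
    }
    lam_hat <- fix_lambda
  } else {
    grid <- seq(0, 1, by = 0.1)
    ll <- vapply(grid, loglik_at, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(loglik_at, c(lo, hi), maximum = TRUE,
                           tol = 1e-8)
    lam_hat <- opt$maximum
    # the optimum can sit exactly on a boundary the optimizer cannot reach
    for (cand in c(0, 1)) {
      if (loglik_at(cand) > loglik_at(lam_hat)) lam_hat <- cand
    }
  }

  pr <- profile(lam_hat)
  V <- pr$V
  slope <- sign(V[1, 2]) * sqrt(V[2, 2] / V[1, 1])
  if (V[1, 2] == 0) slope <- sqrt(V[2, 2] / V[1, 1])
  intercept <- pr$a[2] - slope * pr$a[1]
  structure(list(
    slope = unname(slope), intercept = unname(intercept),
    lambda = lam_hat, loglik = loglik_at(lam_hat), n = n,
    means = stats::setNames(as.numeric(pr$a), c("x", "y")), V = V,
    pruned_tips = pruned, trait_names = c("x", "y")
  ), class = "phylo_rma_fit")
}

#' Phylogenetically informed conduit-number allometry
#'
#' Convenience wrapper: log10 tip and base conduit counts from a branch
#' table, matched to a user-supplied chronogram by species label, fed to
#' [fit_phylo_rma()].
#'
#' @param data A branch table.
#' @param tree An ultrametric [ape::phylo] chronogram whose tip labels
#'   match `species_id` (spaces/underscores equivalent).
#' @param log10 Log10-transform counts first (default TRUE, matching the
#'   non-phylogenetic analysis).
#' @param fix_lambda Optional fixed lambda.
#' @return A `phylo_rma_fit`.
#' @export
phylo_number_allometry <- function(data, tree, log10 = TRUE,
                                   fix_lambda = NULL) {
  data <- as_branch_table(data, attr(data, "provenance") %||% "user")
  x <- data$n_base
  y <- data$n_tip
  if (log10) {
    x <- base::log10(x)
    y <- base::log10(y)
  }
  names(x) <- names(y) <- data$species_id
  fit_phylo_rma(x, y, tree, fix_lambda = fix_lambda)
}

#' @export
print.phylo_rma_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic RMA (n = %d tips)\n", x$n))
  cat(sprintf("  slope %.4f, intercept %.4f\n", x$slope, x$intercept))
  cat(sprintf("  lambda = %.6g, logLik = %.3f\n", x$lambda, x$loglik))
  if (length(x$pruned_tips) > 0) {
    cat("  pruned", length(x$pruned_tips), "tip(s) without trait data\n")
  }
  invisible(x)
}

#' Serialize a phylogenetic RMA fit to JSON
#'
#' @param fit A `phylo_rma_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylo_rma <- function(fit, path) {
  jsonlite::write_json(list(
    slope = fit$slope, intercept = fit$intercept, lambda = fit$lambda,
    loglik = fit$loglik, n = fit$n, pruned_tips = fit$pruned_tips
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
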