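test_that("the Brownian covariance matrix reads off the topology", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tree)
  expect_equal(unname(diag(C)), c(2, 2, 2))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)

  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  Cs <- phylo_vcv(star)
  expect_equal(unname(Cs), diag(4))

  dup <- tree
  dup$tip.label <- c("A", "A", "C")
  expect_error(phylo_vcv(dup), "duplicate")
})

test_that("covariance matrices are positive-definite across random trees", {
  for (i in 1:25) {
    tree <- simulate_tree(sample(5:60, 1), seed = 500 + i)
    expect_silent(chol(phylo_vcv(tree)))
  }
})

test_that("the lambda transform scales only off-diagonals", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tree)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(unname(lambda_transform(C, 0)), diag(diag(C)))
  expect_equal(lambda_transform(C, 0.5)["A", "B"], 0.5)
  expect_equal(unname(diag(lambda_transform(C, 0.5))), c(2, 2, 2))
  expect_error(lambda_transform(C, 1.2), "lambda")
})

test_that("star-tree phylogenetic RMA equals ordinary SMA", {
  n <- 40
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:n, ":1", collapse = ","), ");"))
  set.seed(61)
  x <- setNames(rnorm(n), star$tip.label)
  y <- setNames(1.7 * x + rnorm(n, sd = 0.6), star$tip.label)
  pf <- fit_phylo_rma(x, y, star, fix_lambda = 1)
  sf <- fit_sma(unname(x), unname(y))
  expect_equal(pf$slope, sf$slope, tolerance = 1e-10)
  expect_equal(pf$intercept, sf$intercept, tolerance = 1e-10)
})

test_that("estimates match the independent reference implementation", {
  skip_if_not_installed("phytools")
  tree <- simulate_tree(60, seed = 17)
  V <- matrix(c(1, 0.7, 0.7, 1.5), 2)
  tt <- simulate_bm_traits(tree, V, lambda = 0.5, seed = 18)
  x <- setNames(tt$x, tt$species)
  y <- setNames(tt$y, tt$species)
  mine <- fit_phylo_rma(x, y, tree)
  ref <- phytools::phyl.RMA(x, y, tree, method = "lambda")
  expect_equal(mine$slope, unname(ref$RMA.beta[2]), tolerance = 1e-4)
  expect_equal(mine$intercept, unname(ref$RMA.beta[1]), tolerance = 1e-4)
  expect_equal(mine$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(mine$loglik, ref$logL, tolerance = 1e-6)
})

test_that("the lambda optimum beats every gridded alternative", {
  tree <- simulate_tree(50, seed = 23)
  V <- matrix(c(1, 0.5, 0.5, 1), 2)
  tt <- simulate_bm_traits(tree, V, lambda = 0.7, seed = 24)
  x <- setNames(tt$x, tt$species)
  y <- setNames(tt$y, tt$species)
  fit <- fit_phylo_rma(x, y, tree)
  for (lam in seq(0, 1, length.out = 101)) {
    expect_gte(fit$loglik + 1e-8,
               fit_phylo_rma(x, y, tree, fix_lambda = lam)$loglik)
  }
})

test_that("slope is invariant to tip permutation and swaps reciprocally", {
  tree <- simulate_tree(40, seed = 29)
  V <- matrix(c(1, 0.6, 0.6, 1), 2)
  tt <- simulate_bm_traits(tree, V, lambda = 0.8, seed = 30)
  x <- setNames(tt$x, tt$species)
  y <- setNames(tt$y, tt$species)
  fit <- fit_phylo_rma(x, y, tree)
  perm <- sample(length(x))
  fit_p <- fit_phylo_rma(x[perm], y[perm], tree)
  expect_equal(fit_p$slope, fit$slope, tolerance = 1e-10)
  # axis swap at fixed lambda
  f_xy <- fit_phylo_rma(x, y, tree, fix_lambda = 0.4)
  f_yx <- fit_phylo_rma(y, x, tree, fix_lambda = 0.4)
  expect_equal(f_yx$slope, 1 / f_xy$slope, tolerance = 1e-10)
})

test_that("tips without trait data are pruned, few tips rejected", {
  tree <- simulate_tree(20, seed = 35)
  V <- diag(2)
  tt <- simulate_bm_traits(tree, V, lambda = 1, seed = 36)
  x <- setNames(tt$x, tt$species)[1:15]
  y <- setNames(tt$y, tt$species)[1:15]
  fit <- fit_phylo_rma(x, y, tree)
  expect_equal(fit$n, 15)
  expect_length(fit$pruned_tips, 5)
  expect_error(fit_phylo_rma(x[1:3], y[1:3], tree), "at least 4")
})

test_that("species-label normalization bridges spaces and underscores", {
  tree <- simulate_tree(10, seed = 41)
  tree$tip.label <- paste("Genus species", 1:10)
  V <- diag(2)
  tt <- simulate_bm_traits(tree, V, lambda = 1, seed = 42)
  x <- setNames(tt$x, paste0("Genus_species_", 1:10))
  y <- setNames(tt$y, paste0("Genus_species_", 1:10))
  expect_equal(fit_phylo_rma(x, y, tree)$n, 10)
})
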