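test_that("fixed-spacing event counts are simple arithmetic", {
  expect_equal(n_events_fixed(30, 3), 10)
  expect_equal(n_events_fixed(100, 30), 10 / 3)
  expect_equal(n_events_fixed(770, 3), 770 / 3, tolerance = 1e-12)
  expect_error(n_events_fixed(10, 0))
})

test_that("fixed-spacing predictions double per event and guard overflow", {
  p <- predict_fixed(100, 60, 6, b = 2)
  expect_equal(p$n_events, 10)
  expect_equal(p$n_tip_pred, 102400)

  # zero segment length: no events, identity
  expect_equal(predict_fixed(77, 0, 5)$n_tip_pred, 77)

  # 100 doublings: exact in log10 space, raw count not materialized
  p2 <- predict_fixed(100, 300, 3)
  expect_equal(p2$log10_pred, 2 + 100 * log10(2), tolerance = 1e-12)
  expect_true(is.na(p2$n_tip_pred))
})

test_that("geometric basal internode follows the series closed form", {
  expect_equal(l0_geometric(100, 0.7), 30.7)
  expect_equal(l0_geometric(770, 0.7), 231.7)
  # lambda -> 0 limit: single internode spanning the segment
  expect_equal(l0_geometric(50, 1e-9), 50, tolerance = 1e-6)
  expect_error(l0_geometric(0.5, 0.7), "exceed")
})

test_that("geometric inversion reproduces the worked case", {
  n <- n_events_geometric(100, 0.7)
  expect_equal(n, 9.60051361, tolerance = 1e-7)
  L0 <- l0_geometric(100, 0.7)
  # distalmost internode is exactly L_n = 1 cm
  expect_equal(L0 * 0.7^n, 1, tolerance = 1e-10)
  # two-internode case by construction: L_segment = L0 (1 + lambda)
  lam <- 0.7
  Ls <- (1 / (1 - lam^2)) * (1 + lam) * lam  # solves L0 = 1/(1+lam)...
  # simpler: choose L0 = 1/lam so internodes are L0 and 1; then
  # L_segment = L0 (1 + lam)
  L0b <- 1 / lam
  Lsb <- L0b * (1 + lam)
  expect_equal(n_events_geometric(Lsb, lam), 1, tolerance = 1e-9)
})

test_that("series closed form equals direct internode summation", {
  set.seed(202)
  for (i in 1:200) {
    lam <- runif(1, 0.3, 0.95)
    n <- sample(1:40, 1)
    L0 <- runif(1, 0.5, 50)
    closed <- L0 * (1 - lam^(n + 1)) / (1 - lam)
    expect_equal(closed, sum_internodes(L0, lam, n),
                 tolerance = 1e-12)
  }
  # and the inversion satisfies the closed form for random draws
  for (i in 1:200) {
    lam <- runif(1, 0.3, 0.95)
    Ls <- runif(1, 5, 770)
    L0 <- l0_geometric(Ls, lam)
    n <- n_events_geometric(Ls, lam)
    expect_equal(L0 * (1 - lam^(n + 1)) / (1 - lam), Ls,
                 tolerance = 1e-9)
  }
})

test_that("geometric predictions exceed fixed spacing at L_b = L_0", {
  n_base <- 100
  for (Ls in c(40, 100, 500)) {
    L0 <- l0_geometric(Ls, 0.7)
    pg <- predict_geometric(n_base, Ls, 0.7)
    pf <- predict_fixed(n_base, Ls, L0)
    expect_gt(pg$log10_pred, pf$log10_pred)
  }
  # degenerate identity at L_segment = L_n
  expect_equal(predict_geometric(50, 1, 0.7, L_n = 1)$n_tip_pred, 50)
})

test_that("conservation predictions follow the radius-moment exponent", {
  p2 <- predict_conservation(500, 40, 20, p = 2)
  p3 <- predict_conservation(500, 40, 20, p = 3)
  expect_equal(p2$n_tip_pred, 2000)
  expect_equal(p3$n_tip_pred, 4000)
  # R = 1 identity for both exponents
  expect_equal(predict_conservation(123, 30, 30, 2)$n_tip_pred, 123)
  expect_equal(predict_conservation(123, 30, 30, 3)$n_tip_pred, 123)
  # no-widening records are flagged, not dropped
  pn <- predict_conservation(10, 20, 25, 2)
  expect_true(pn$no_widening)
  expect_lt(pn$n_tip_pred, 10)
})

test_that("Murray exceeds da Vinci exactly when conduits widen", {
  set.seed(33)
  nb <- sample(10:1000, 50)
  db <- runif(50, 10, 100)
  dt <- runif(50, 10, 100)
  m <- predict_conservation(nb, db, dt, 3)
  v <- predict_conservation(nb, db, dt, 2)
  widen <- db / dt > 1
  expect_equal(m$log10_pred[widen] > v$log10_pred[widen],
               rep(TRUE, sum(widen)))
  expect_equal(m$log10_pred[!widen] < v$log10_pred[!widen],
               rep(TRUE, sum(!widen)))
})

test_that("predict_fixed is monotone in its drivers", {
  base <- predict_fixed(100, 120, 12)$log10_pred
  expect_gt(predict_fixed(100, 120, 6)$log10_pred, base)   # shorter L_b
  expect_gt(predict_fixed(100, 240, 12)$log10_pred, base)  # longer L
  expect_gt(predict_fixed(200, 120, 12)$log10_pred, base)  # more at base
})

test_that("the fixed sweep yields one prediction per record per L_b", {
  d <- simulate_branches(sim_config(seed = 6))
  sw <- sweep_fixed(d)
  expect_equal(nrow(sw), 112 * 10)
  expect_true(all(is.finite(sw$log10_pred)))
  # predictions decrease with internode length for every record
  by_sp <- split(sw, sw$species_id)
  for (sp in by_sp[1:5]) {
    expect_true(all(diff(sp$log10_pred[order(sp$L_b)]) < 0))
  }
  # a one-value grid duplicates predict_scenario
  one <- sweep_fixed(d, L_b_values = 9)
  direct <- predict_scenario(d, furcation_scenario("fixed", L_b = 9))
  expect_equal(one$log10_pred, direct$log10_pred)
})

test_that("scenario comparison summarises overprediction", {
  # observed tip counts set exactly to the da Vinci prediction: ties are
  # excluded, so the overprediction fraction is zero
  tbl <- make_branch_tbl()
  tbl$d_base_um <- c(40, 60, 90)
  tbl$d_tip_um <- c(20, 30, 45)  # R = 2 everywhere
  tbl$n_tip <- 4 * tbl$n_base    # exactly the da Vinci prediction
  cmp <- compare_scenarios(tbl,
                           list(furcation_scenario("davinci")))
  expect_equal(cmp$summary$frac_over, 0)

  # empty scenario list -> empty tables
  cmp0 <- compare_scenarios(tbl, list())
  expect_equal(nrow(cmp0$predictions), 0)
  expect_equal(nrow(cmp0$summary), 0)
})

test_that("scenario constructor validates parameters", {
  expect_error(furcation_scenario("fixed"), "L_b")
  expect_error(furcation_scenario("geometric", lambda_len = 1.2),
               "lambda")
  expect_error(furcation_scenario("fixed", L_b = 5, b = 1.5))
  expect_equal(furcation_scenario("murray")$p, 3)
  expect_equal(furcation_scenario("davinci")$p, 2)
})
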