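# Shared fixtures and independent oracles.

# Small deterministic branch table: three unbranched records with widening.
make_branch_tbl <- function() {
  tibble::tibble(
    species_id = c("Acacia_sp", "Quercus_sp", "Pinus_sp"),
    n_base = c(120, 4500, 300),
    n_tip = c(118, 4600, 295),
    d_base_um = c(45.5, 80.25, 30.125),
    d_tip_um = c(20.1, 35.5, 15.75),
    dist_base_cm = c(150.5, 620.75, 95.25),
    dist_tip_cm = c(12.5, 25.125, 8.5)
  )
}

# Triangle-area oracle for the SMA slope: the SMA line minimizes the
# summed areas of right triangles between points and the line; with the
# intercept profiled out (a = ybar - b xbar) the objective reduces to
# sum((y - ybar - b (x - xbar))^2) / (2 |b|), minimized numerically.
# Independent of the closed-form estimator it checks.
sma_slope_oracle <- function(x, y, interval_mag = c(1e-4, 1e4)) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  obj <- function(b) sum((yc - b * xc)^2) / (2 * abs(b))
  pos <- stats::optimize(obj, interval_mag, tol = 1e-12)
  neg <- stats::optimize(obj, -rev(interval_mag), tol = 1e-12)
  if (pos$objective <= neg$objective) pos$minimum else neg$minimum
}

# Direct summation of geometrically contracting internode lengths
# L0, lambda L0, ..., lambda^n L0 for integer n (no closed form).
sum_internodes <- function(L0, lambda, n) {
  sum(L0 * lambda^(0:n))
}

# Path where the deposited empirical dataset (Dataset S1 of the study)
# would live if a user downloads it; absent in a clean checkout.
dataset_s1_path <- function() {
  system.file("extdata", "dataset_s1.csv", package = "conduitr")
}
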