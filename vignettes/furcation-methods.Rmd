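---
title: "Testing xylem conduit furcation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing xylem conduit furcation: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conduitr)
```

## The scientific question

Water moves from roots to leaves through xylem conduits. Two architectures
can keep conductance per unit leaf area constant as path length grows: the
conduits can *furcate* — each parent dividing into several narrower
daughters distally, as in leaf venation and animal vasculature — or they
can stay constant in number and *widen* tip-to-base. The two make sharply
different predictions about the relationship between the number of
functional conduits at the base (`N_base`) and tip (`N_tip`) of a long
unbranched branch carrying all of its leaves at the distal end:

* no furcation: `N_tip = N_base` — a log-log slope of exactly 1;
* furcation: tip counts grow faster than base counts — a slope above 1,
  and longer branches (more branching events) carry disproportionately
  more tip conduits.

`conduitr` estimates that relationship, quantifies the accompanying
tip-to-base widening, repeats the central fit with phylogenetic
correction, and computes what `N_tip` *would be* under four classical
furcation baselines so that observation and assumption can be compared
directly.

## Estimators

### SMA for the count allometry

Neither count causes the other — both respond to the leaf area the branch
supplies and are laid down concurrently by the cambium — so the symmetric
model II (standardized major axis) estimator is used rather than OLS:
`b = sign(r) · s_y / s_x`, with the line through the bivariate mean. The
slope CI uses the standard F-based construction
`b(√(B+1) ± √B)`, `B = F_{1−α;1,n−2}(1−r²)/(n−2)`; the intercept CI is
t-based on `var(â) = s²_res/n + x̄² b²(1−r²)/(n−2)`. The slope test
against a hypothesized `b₀` exploits the fact that the SMA slope equals
`b₀` exactly when residual scores `y − b₀x` and axis scores `y + b₀x` are
uncorrelated, giving a t-test on `n − 2` degrees of freedom. The package
tests its SMA estimator against a numeric minimizer of the summed
triangle areas between points and line — the geometric definition of the
SMA fit — and against the identities `b_SMA = b_OLS/|r|` and axis-swap
reciprocity.

All variables are log10-transformed; these anatomical traits arise from
multiplicative processes and span orders of magnitude, and the furcation
hypotheses are themselves multiplicative. Natural logs are deliberately
not used anywhere on these paths.

### The segment-length regression

`log10 N_tip ~ log10 N_base + log10 L_segment` (ordinary least squares,
`L_segment = dist_base − dist_tip` in cm). Segment length enters in log10
by default, consistent with transforming every variable; a
`log_length = FALSE` flag fits raw length instead, since the choice is a
genuine ambiguity in how such models are usually reported. The furcation
signature is a positive, significant length coefficient.

### The widening regression

OLS of `log10` mean lumen diameter on `log10` distance from the shoot
apex, pooling the two measurements of every branch (each section at its
own apex distance, in cm). OLS is appropriate here — distance is the
natural predictor — and the expected slope under hydraulic optimality is
about 0.2. Distances are the section's own apex distances, not segment
midpoints.

### Phylogenetic RMA with Pagel's λ

Closely related species could share residual structure, so the central
fit is repeated under a Brownian-motion model on a user-supplied
ultrametric chronogram. With `C_λ` the Brownian covariance matrix with
off-diagonals multiplied by λ, the GLS trait means are
`â = (1ᵀC_λ⁻¹1)⁻¹ 1ᵀC_λ⁻¹T`, the evolutionary covariance
`V = (T − 1âᵀ)ᵀ C_λ⁻¹ (T − 1âᵀ)/(n−1)`, the RMA slope
`sign(V_xy)√(V_yy/V_xx)`. A single λ governs both traits and maximizes
the bivariate log-likelihood
`−½[m(n−1) + n log|V| + m log|C_λ| + nm log 2π]` (m = 2; the quadratic
form collapses to `m(n−1)` because `V` is profiled out at each λ).
Optimization is an 11-point grid pre-scan followed by bounded scalar
search on the bracketing interval (tolerance 1e-8), with the boundary
values 0 and 1 checked explicitly — the likelihood can be nearly flat
near 0. For ultrametric trees the implementation exploits the fact that
`C_λ = λC + (1−λ)·depth·I` shares `C`'s eigenvectors, so the whole λ
profile costs one eigendecomposition; non-ultrametric matrices fall back
to Cholesky solves. Tips without trait data are pruned (no imputation);
species labels are matched after whitespace/underscore normalization.
The estimator is verified against `phytools::phyl.RMA` on simulated data
and reduces exactly to ordinary SMA on a star phylogeny. Tree
construction and dating are out of scope; any user chronogram in Newick
is accepted, subject to an ultrametricity check (relative tolerance 1e-6
of depth).

## Furcation baselines

All four baselines share `N_tip = N_base · bⁿ` (b daughters per parent,
n branching events along the segment) or its conservation-law analogue,
and all arithmetic runs in log10 space, with raw counts materialized only
below 1e15 — the fixed 3 cm spacing on a 7.7 m branch implies ~77
doublings, far beyond double precision.

* **Fixed spacing.** `n = L_segment/L_b`, with `L_b` swept over 3–30 cm
  in 3 cm steps by default. `n` is kept continuous: the source equations
  yield non-integer `n` and no rounding rule, so predictions are
  real-valued (an integer display mode would round only at presentation).
* **Geometric contraction.** Internode lengths shrink by a factor λ per
  level (default 0.7, i.e. daughters 70% the length of mothers), ending
  at a distalmost internode `L_n = 1 cm`. The finite geometric series
  `L_segment = L_0 Σ λ^k` with that end condition fixes
  `L_0 = (1−λ)L_segment + λL_n` and inverts to
  `n = log_λ(1 − L_segment(1−λ)/L_0) − 1`. The printed form of this
  inversion in the source material is typographically garbled; the
  implemented form is the unique one consistent with the series and the
  end condition, and satisfies `L_0 λⁿ = L_n` exactly — both identities
  are enforced in tests over randomized draws.
* **da Vinci / Murray.** `N_tip = R^p N_base` with `R = d_base/d_tip`
  (identical to the radius ratio; per-conduit diameter distributions are
  not modeled since the data are 30-conduit means) and `p = 2`
  (cross-sectional area conserved) or `p = 3` (summed r³ conserved).
  Records with `R ≤ 1` are flagged rather than dropped.

The comparison reports, per scenario, the fraction of records
overpredicted (strict inequality; ties within 1e-12 in log10 do not
count — an exactly-constructed tie should not register as
overprediction in either direction) and the median log10
prediction/observation ratio.

Canonical units are centimeters for all lengths (the internode equations
set `L_n = 1 cm`) and micrometers for diameters; the loader converts
meters/millimeters via unit hints, avoiding unit drift between the
regression and prediction modules.

## The synthetic-data generator

The generator emulates the sampling design the analysis assumes, so every
stage of the pipeline is testable without any download:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 112 | one branch per species |
| `length_range_cm` | 60–770 | apex-to-base distance, log-uniform |
| `tip_offset_range_cm` | 5–30 | apex-to-tip distance, uniform |
| `widening_exponent` | 0.2 | `D ∝ distance^0.2` |
| `widening_ref_log10` | 1.2 | log10 μm at 1 cm (diameters ≈ 10–300 μm) |
| `sigma_d` | 0.25 | log10 diameter noise SD, independent at tip/base |
| `log10_nbase_range` | 1.5–4.0 | basal counts 30–10 000, log-uniform |
| `sigma_n` | 0.06 | log10 noise of `N_tip` about its expected value |
| `scenario` | none | inject a furcation predictor into `N_tip` |

Counts are rounded to integers with a floor of 1. Under the null,
`N_tip` centers on `N_base`; with a scenario, on that scenario's
prediction — which is how the power of the segment-length test is
measured. Every draw is a pure function of the config and seed, and the
generator restores the caller's RNG state.

Choices worth flagging:

* The branch-length and tip-offset ranges and the widening exponent
  mirror the field design the package targets. The basal-count range and
  `widening_ref_log10` are generator conventions chosen to give realistic
  magnitudes (tens to thousands of conduits; diameters tens to hundreds
  of μm); no published count range exists to copy.
* `sigma_n = 0.06` is the typed default. Note it yields a tighter
  count allometry (r² ≈ 0.99) than the r² ≈ 0.8 typical of real
  112-species campaigns; matching that r² would need σ ≈ 0.34. The
  default was kept as specified, so recovery tests characterize the
  estimator under mild noise, not field-realistic scatter.
* Diameter noise is independent at tip and base. Real branches likely
  share factors (site, wood density), inducing within-branch correlation;
  this is the simplest null consistent with pooling both points in the
  widening regression. A consequence: with `sigma_d = 0.25`, about 2% of
  simulated records have `d_tip > d_base`, so conservation baselines do
  not overpredict on *every* noisy record — the deterministic
  (noise-free) generator is the construction under which the baselines
  provably overpredict universally.
* One branch per species, so no within-species replication; `branched`
  stems (tip counts summed over daughter twigs) are supported by the
  loader but not generated.

Passing tests on these data therefore demonstrate estimator correctness
and calibration under the generator's assumptions — lognormal noise,
independence across records, exact power-law widening — not robustness
to measurement artifacts (open vessels, embolism at cut surfaces) or to
non-power-law widening, which only real data can probe.

## Numerical and degenerate-input policy

* SMA requires n ≥ 3, finite values, nonzero variance in both variables;
  zero-variance input is a hard error, not an NA.
* `test_slope` with exactly isometric data has a zero-variance residual
  score; its correlation is defined as 0 (p = 1), the correct limit.
* The geometric inversion rejects `L_segment ≤ L_n` (no room for
  contraction) and validates the log argument.
* Rank-deficient multiple-regression designs error and name the
  collinear columns.
* `r = 0` in SMA takes the positive slope branch (sign convention only;
  the association p-value is 1 there).
* Validation never mutates data: the loader returns all rows and attaches
  a structured error/warning report (tip diameter exceeding base is a
  warning — real but unusual; count/distance violations are errors).

## Problem sizes in the shipped checks

The test suite and acceptance script run, by design, at the scale of the
study they emulate: 112-branch campaigns for single fits; 300–500
replicates for CI coverage and type-I error; 150–200 replicates for
power; 50–100 replicates × 200-tip trees per λ value for λ recovery.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands (e.g. coverage SE ≈ 0.01 at 500 replicates) while keeping
a full run in tens of seconds.

## Known limitations

* The phylogenetic RMA assumes Brownian motion with a single λ for both
  traits; Ornstein–Uhlenbeck or per-trait signal are out of scope.
* Hydraulic conductance and carbon-cost accounting are not computed; the
  baselines are purely structural predictors of conduit number.
* Asymmetric branching ratios and per-conduit network simulation are not
  modeled (`b` is a single integer per scenario).
* The empirical headline numbers of the motivating field study (SMA slope
  0.99, widening slope 0.22, λ ≈ 0) are reproduced by the pipeline only
  when the user supplies that study's deposited measurement table and
  chronogram; the package does not construct or download either.
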