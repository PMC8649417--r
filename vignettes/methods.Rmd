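---
title: "Comparing patient groups on a latent trait: sum scores, IRT models, and EAP scores under DIF and missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing patient groups on a latent trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patient-reported outcome (PRO) instruments measure constructs — fatigue,
life satisfaction, physical function — that are not directly observable.
A clinical trial that compares two patient groups on such an instrument
must first turn item responses into scores, and the scoring choice is not
innocuous. `grmmeans` implements a Monte Carlo laboratory for studying
three widely used strategies for testing a two-group mean difference:

1. **Sum score**: add up the numeric responses per person (listwise
   deletion of persons with missing responses), compare groups with a
   two-sided Welch *t*-test, and standardize the mean difference by the
   pooled SD.
2. **IRT model**: fit a multigroup graded response model (GRM) by marginal
   maximum likelihood with all item parameters constrained equal across
   groups, the reference group fixed at N(0,1), and the focal group's
   latent mean and variance free; test the equal-means constraint with a
   1-df likelihood ratio test.
3. **IRT-EAP**: score each person by the posterior mean of the latent
   trait (expected a posteriori) under pre-calibrated item parameters and
   a standard normal prior, then proceed as in the sum-score approach.

Each strategy is run with and without a differential item functioning
(DIF) prescreening step, giving six analysis arms per simulated data set.

## The model

For person $i$ and item $j$ with $V$ ordered categories, the GRM specifies
cumulative category response functions

$$P(u_{ij} \ge v) = \frac{\exp\{a_j(\theta_i - b_{j,v})\}}
  {1 + \exp\{a_j(\theta_i - b_{j,v})\}}, \qquad v = 1, \dots, V-1,$$

with discrimination $a_j > 0$ and strictly increasing thresholds
$b_{j,1} < \dots < b_{j,V-1}$. Category probabilities are differences of
consecutive cumulative curves. We work throughout in the pure logistic
metric: the scaling constant $D = 1.7$ enters only the documented
conversion from a logistic discrimination to a standardized factor
loading (`a_to_loading()`), never data generation or estimation — under
that convention the high-discrimination range 1.7–3.5 corresponds to
loadings 0.71–0.90 and the low range 0.5–1.0 to 0.28–0.51.

Item parameters are estimated by maximizing the marginal likelihood

$$L(\beta) = \prod_{i=1}^{N} \int \Big(\prod_{j} P(u_{ij}\mid\theta)\Big)
  f(\theta)\, d\theta,$$

with $f(\theta)$ the group's normal prior. The integral is discretized on
61 equally spaced nodes on $[-6, 6]$ with weights proportional to the
prior density, renormalized. This grid matches a 2001-node brute-force
evaluation to far better than $10^{-6}$ relative error on the test-suite
toy sets, which is the package's accuracy contract for likelihoods and
EAP moments.

## Estimation: EM with SQUAREM acceleration

`fit_grm_multigroup()` runs a Bock–Aitkin EM: the E-step computes, per
unique response pattern, posterior weights over the quadrature nodes and
accumulates expected item-category counts; the M-step maximizes each
item's expected complete-data log-likelihood by a safeguarded Newton
ascent in the parameterization (log $a$, $b_1$, log threshold
increments), which enforces ordered thresholds by construction, and
updates the focal group's mean and variance in closed form. Stopping
follows an absolute change in marginal log-likelihood below $10^{-5}$,
capped at 500 EM map applications; non-converged fits are flagged but
retained, and the caller decides.

Plain EM converges slowly on flat likelihoods (small samples, low
discriminations, missing responses), so the EM map is wrapped in SQUAREM
extrapolation: two EM applications, a quadratic step along the observed
trajectory, one stabilizing EM application, and a monotone fallback to
the plain iterate whenever extrapolation fails to improve the
likelihood. This cuts typical fits from several hundred EM cycles to a
few dozen without changing the fixed point; the test suite checks
agreement between the accelerated and plain paths.

Two numerical conventions matter in small samples. Response categories
with zero pooled observations are merged into their lower neighbor (the
upper neighbor for an empty bottom category) for the duration of the fit,
which keeps small-$n$ fits alive; the fit records which items were
collapsed. Likelihood-ratio statistics that come out slightly negative
from convergence noise are clipped to zero, with a diagnostics flag when
the deficit exceeds $10^{-4}$.

Starting values are $a = 1$, thresholds at normal quantiles of the pooled
upper-cumulative category proportions, and focal moments $(0, 1)$; nested
refits warm-start from the parent model, which is what makes the
DIF-scan loops affordable.

## The simulated world

The generator reproduces a 2^7 × 2 factorial design: sample size per
group (100/400), test length (5/20 items), discrimination (high: $a \sim
U(1.7, 3.5)$; low: $a \sim U(0.5, 1.0)$), categories (2/5), threshold
location (homogeneous/diverse), DIF (present/absent), missingness
(present/absent), and true focal mean (0 for Type I error, 0.5 — also the
true effect size in z-metric — for power). The full study design uses 450
replications per cell; reduced-replication runs are labeled as such in
the outputs.

* **Item banks.** 10,000 items per type × discrimination level.
  Dichotomous thresholds are N(0.1, SD 1.3) truncated to $[-2.5, 2.4]$
  (we read the "1.3²"-style notation as a variance, i.e. SD 1.3, which is
  the reading consistent with the companion N(−1, 1) and the increment
  algebra). Polytomous first thresholds are N(−1, 1) truncated to
  $[-3.5, 0.5]$, with three successive increments N(0.8, SD 0.2)
  truncated to $[0.4, 1.2]$. Truncation is by rejection sampling — the
  regions retain most of the mass, so this is exact and cheap. Note that
  these distributions bound the largest polytomous threshold in
  $[-2.3, 4.1]$; about 11% of bank items have a largest threshold below
  0.1, which the tests acknowledge by asserting the algebraic bounds.
* **Item draws.** Diverse mode samples items without replacement.
  Homogeneous mode draws a benchmark and requires every threshold of the
  remaining items to lie within ±0.25 of the benchmark's corresponding
  threshold (the per-threshold reading of the window), redrawing the
  benchmark when too few qualify, up to 1000 restarts.
* **DIF.** 40% of the drawn items (2 of 5, 8 of 20) are flagged; flagged
  items lose $U(0, 0.3)$ of discrimination and gain one shared
  $U(0.5, 0.7)$ shift on all thresholds in the focal group — the minimal
  reading of "differences in the thresholds" that keeps category ordering
  intact, logged per item. The focal group is thereby disadvantaged.
* **Missingness.** 20% of items become missingness-eligible; 30% of the
  pooled subjects are sampled without replacement with probability
  given by a logistic transform of their standardized mean response on
  the non-eligible items, and their eligible-item responses are deleted.
  Selection depends only on responses that remain observed, so the
  mechanism is missing at random with an exact 30% quota.
* **DIF magnitude at the test level.** The differential test functioning
  (DTF) effect size is the mean focal-sample difference between expected
  test scores under focal vs reference parameters, standardized by the
  SD of the reference-parameter expected test scores in that sample.
  The cited scale-level index admits more than one standardizer; this
  choice was validated before freezing against the generator's published
  summary behavior (mean ≈ −0.22 with interquartile range ≈ (−0.25,
  −0.20) across proportionally mixed DIF cells), which the alternative
  (model-implied observed-score SD) fails to reproduce.

What the generator does **not** emulate: non-normal trait distributions,
more than two groups, DIF proportions other than 40%, MNAR or MCAR
missingness, local dependence, and multidimensionality. A green test
therefore certifies behavior inside this stated world only.

## DIF prescreening

The prescreening pipeline is the all-others-as-anchors (AOAA)
likelihood-ratio scan with rank-based anchor selection:

1. **Scan**: each item in turn gets group-specific parameters while all
   others stay invariant; the LRT against the all-invariant model has df
   equal to the item's parameter count.
2. **Anchors**: `round(0.2 J)` items (minimum 1). If enough items are
   non-significant at α = 0.05, take those with the largest
   constrained-fit discriminations (the constrained fit is the stated
   source of the ranking); otherwise take the smallest scan statistics.
   Ties break by item id.
3. **Retest**: each non-anchor is retested against the anchor-fixed
   metric. The general model holds only anchors invariant, with all
   non-anchors free in both compared models, so each retest isolates one
   item — the standard anchored-LRT construction.

Clean items (anchors plus retest-survivors) feed the sum-score and EAP
arms; flagged items remain in the IRT-model arm with free parameters. No
multiplicity correction is applied, matching the screening convention at
α = 0.05 per item.

## Evaluation and the tree summaries

`summarize_study()` computes, per design cell × method × prescreening
arm: the rejection rate (Type I error where the true focal mean is 0,
power where it is 0.5) and the mean absolute error of the standardized
effect size against the true value. `fit_tree()` then fits a display
regression tree to each expanded table: exact MSE-optimal binary splits
over the categorical design features, maximum depth 4, complexity
parameter 0 (any strictly positive SSE reduction qualifies; a constant
outcome yields a single leaf), minimum 20 cases to split and 7 per
child — the conventional recursive-partitioning defaults. Ties break by
predictor declaration order then level-subset order, so the rendered
tree is deterministic, and every node is annotated with its outcome mean
(the root mean is exactly the table-wide average).

## Reproducibility choices

One master seed drives everything. Per-replication seeds derive from
(condition id, replication index) through two multiplicative-congruential
scrambles bounded below $2^{31}$, so any single replication can be
reproduced in isolation and results are independent of execution order.
All six analysis arms of a replication see the identical data set, making
method contrasts paired. Replications whose data generation is
infeasible (homogeneous draws with no qualifying neighbors) are redrawn
under a derived retry seed and counted in the diagnostics.

## Scaled-down defaults in tests

The packaged test suite and acceptance checks run the Monte Carlo
criteria at reduced replication counts (e.g. 25–100 instead of 450 per
cell, and 40–80 instead of 200 for the screening calibration
properties) to stay within a desk-scale compute budget; tolerances for
the stochastic checks are ±3 Monte-Carlo standard errors of the scaled
run. One acceptance check (the 400-per-group IRT-model power average)
uses a tolerance floor of 0.03 alongside the ±3 SE band because the
target is printed to two decimals and the scaled run's rejection rates
are discrete in steps of 1/80 — a floor fixed a priori, not fitted.

## Known limitations

* The EM estimator assumes normal latent priors in both groups; Ramsay
  or Davidian-curve alternatives are out of scope.
* Wald-type mean tests, multiple imputation for sum scores, and DIF
  methods other than the IRT-LRT family (ordinal regression, MIMIC,
  Mantel–Haenszel) are deliberately not implemented.
* Non-convergence is flagged, logged, and retained rather than redrawn;
  with 100-per-group low-discrimination dichotomous cells a small
  fraction of fits touch the iteration cap, and their clipped LRTs are
  carried into the summaries.
* Tree topologies beyond the first couple of splits are sensitive to
  Monte Carlo noise at reduced replications; root and near-root means
  are the stable quantities.
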