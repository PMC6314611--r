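---
title: "Methods: calibrated maximum-entropy niche models, transfers and extrapolation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated maximum-entropy niche models, transfers and extrapolation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nichecal` implements a complete presence-background ecological niche
modelling (ENM) workflow of the kind used to map climatic suitability for
disease vectors such as ticks: occurrence cleaning, accessible-area
definition, candidate-model calibration and selection, replicate final
models, transfer to future climate scenarios, and extrapolation-risk
analysis. This vignette documents the model, the statistical procedures, the
tunable parameters and their defaults, the design choices that were open,
and what the synthetic validation data can and cannot show.

## The model

The core is a regularized maximum-entropy (MaxEnt-style) presence-background
model. Given presence records and a background sample of available
environments, the model estimates a density over background cells

$$ q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{\sum_{x' \in \text{bg}} \exp(\lambda \cdot f(x'))} $$

where $f(x)$ are *features*: transformations of the raw variables after
scaling each variable to $[0,1]$ by its background range. The five classic
feature classes are supported — linear ($z$), quadratic ($z^2$), product
($z_i z_j$), threshold (step functions at 10 evenly spaced knots per
variable), and hinge (forward and reverse ramps at 15 presence-quantile
knots per variable). Every generated feature is itself rescaled to $[0,1]$
using its background range, which makes the L1 penalties comparable across
classes.

Coefficients maximize the penalized log-likelihood

$$ \sum_{i \in \text{presences}} \log q_\lambda(x_i) \;-\; \sum_j \beta_j |\lambda_j|, \qquad
   \beta_j = \beta_{\text{mult}} \times b_{c(j)}(n) \times \frac{s_j}{\sqrt{n}} $$

with $b_{c}(n)$ the published class-specific base penalty interpolated by
presence count $n$ (linear/quadratic/product share one table; thresholds are
penalized more, hinges at a flat 0.5) and $s_j$ the feature's standard
deviation over the presences (floored at 0.01 so no feature is ever entirely
unpenalized). The objective is convex; it is solved by a proximal-Newton
scheme — the log-partition term is locally replaced by its exact quadratic
model and the L1-penalized quadratic subproblem is solved by cyclic
coordinate descent with soft-thresholding, followed by a backtracking line
search on the true objective. Convergence is declared when the
Karush-Kuhn-Tucker conditions hold within `tol = 1e-5` (on the per-presence
objective scale). Feature sets containing near-duplicate columns (adjacent
hinge knots) make the optimum nearly flat; the solver then stops once the
objective stalls (relative decrease below 1e-9 over three consecutive outer
steps) and reports the achieved KKT state through the `converged` flag
rather than iterating indefinitely.

Two output scales are provided. *Raw* output is $q_\lambda$ itself, which
sums to 1 over the background (audited to $10^{-6}$ after every fit).
*Cloglog* output, the default for all thresholding, is
$1 - \exp(-e^{H} \cdot \text{raw})$ with $H$ the entropy of the background
distribution — the MaxEnt 3.4 convention. At projection time, *clamping*
pins variable values outside the training background range to the boundary
before feature expansion and records the affected cells.

## Candidate calibration and selection

Calibration evaluates a grid of candidate configurations — feature-class
combination x regularization multiplier x variable set. The multiplier grid
`0.1-1 by 0.1; 1-6 by 1; 8; 10` parses to 17 unique values; all 31 non-empty
class combinations and any number of variable sets can be crossed with it.
Each candidate is fit on the calibration half of the occurrences (a random
equal split; odd counts favour calibration) and assessed three ways:

1. **Partial-ROC significance.** The ROC is built with fractional predicted
   area on the x-axis and test sensitivity on the y-axis. The partial AUC is
   integrated over the fixed domain $x \in [1-E, 1]$ — the region where the
   null (diagonal) classifier attains sensitivity $\ge 1-E$ — and divided by
   the analytic null area $(1-(1-E)^2)/2$. Bootstrap draws of half the test
   points (500 by default) give a ratio distribution; `proc_p` is the
   fraction of ratios $\le 1$. Fixing the integration domain matters: if the
   domain is instead taken where the *empirical* curve reaches sensitivity
   $1-E$, the ratio exceeds 1 almost surely under pure noise at realistic
   test sizes, and every candidate appears "significant". With the fixed
   domain the test is calibrated (type-I error compatible with
   $\alpha = 0.05$ in the package's null simulations) provided the expected
   number of test points in the E-tail, $n_{\text{test}} \cdot E$, is at
   least a handful; below that no bootstrap construction is informative
   because the tail is empty with probability $(1-E)^{n}$.
2. **Omission at the E-adjusted threshold.** The threshold is the
   $\lceil E \cdot n_{\text{cal}} \rceil$-th smallest calibration
   suitability; the omission rate is the fraction of evaluation
   suitabilities strictly below it (ties retained). Note a small-sample
   subtlety: unless $n_{\text{cal}}$ is a multiple of $1/E$, the threshold
   excludes more than a fraction $E$ of the calibration data, and even a
   perfect model then fails $rate \le E$ *in expectation*. This is a
   property of the published protocol, not of the implementation; it is why
   real studies at these sample sizes report only a few percent of
   candidates passing, and why an empty selection is an expected outcome
   that the pipeline reports cleanly rather than treating as an error.
3. **AICc.** Raw scores are renormalized over the calibration grid;
   $\ln L = \sum \ln \hat p$ at the occurrence cells (calibration plus
   evaluation, the convention of current calibration tooling;
   configurable to calibration-only); $k$ is the number of nonzero
   coefficients; the small-sample correction diverges at $k \ge n-1$.

Selection applies the three filters sequentially: keep `proc_p < alpha`,
then omission $\le$ 0.05, then $\Delta$AICc $\le 2$ within the survivors
(ties kept). The selected set is order-invariant, its minimum
$\Delta$AICc is 0, and its omission bound holds by construction.

## Variable-set reduction

Nested variable sets are produced by a sequential jackknife: the
contribution of a variable is the drop in regularized training gain (mean
presence log-density relative to a uniform background, minus the penalty)
when it is left out and the model refit. The lowest contributor is removed
(ties broken alphabetically) and the procedure repeats, snapshotting the
surviving set at each requested target size. Contributions are re-estimated
after every removal, so the sets are strictly nested by construction.

## Final models, transfers, agreement

Final models refit each selected configuration on bootstrap resamples of the
calibration presences (10 replicates by default; seeds derived from the
master seed). The cellwise median across all replicates of all selected
models is the consensus suitability surface, and the cellwise max-minus-min
is its uncertainty surface. The median surface is thresholded at the
E-adjusted value to give binary suitable/unsuitable maps; transfers apply
identical prediction math to each scenario stack with clamping. For each
emissions scenario the per-GCM binary futures are compared with the single
present-day binary: classes 1-4 count GCMs agreeing on newly suitable area,
classes 5-8 count GCMs agreeing on loss, 0 is no change signal. Scenarios
are never pooled.

## Extrapolation risk (MOP)

Mobility-oriented parity standardizes variables by the calibration mean/sd
and computes, for each projection cell, the mean Euclidean distance to its
nearest 10% (configurable) of calibration cells. Novelty is the excess of
that distance over the calibration cloud's own internal scale — the maximum
of the same statistic across the calibration cells themselves — so
conditions no more unusual than the cloud is internally score a similarity
of 1, and a projection region identical to the calibration region is
maximally similar everywhere. Strict extrapolation is flagged on the raw
scale wherever any variable leaves the calibration min-max range; per-GCM
strict masks are summed into an agreement count. The reference fraction
(0.1) and the Euclidean metric are declared defaults; distances for clouds
beyond 10,000 cells use a seeded subsample (exact mode available).

## Synthetic validation data

The simulator generates what the workflow needs and nothing more: Gaussian
process-like climate layers (smoothed white noise plus a north-south
gradient, standardized; the kernel sd in cells is the smoothness knob, and
the default 1/6 degree cell size matches a 10-arc-minute climatology grid), a
virtual species whose truth suitability is a product of Gaussian responses
on 2-3 variables (rescaled to maximum 1), occurrences sampled
cell-proportionally to truth with within-cell jitter and lognormal
coordinate-uncertainty radii (median 5 km, 10% above the 10 km filter
cutoff, so the uncertainty filter is exercised in both directions), and
future scenarios built as the present stack plus per-scenario mean shifts
plus smooth pseudo-GCM perturbation fields.

What this does *not* emulate: real covariance between bioclimatic variables,
sampling bias, spatially structured observation error, or any tick biology
(hosts, phenology). Passing the truth-recovery tests shows the machinery is
correct, not that any particular real-world map is.

## Demonstration scale

The packaged demonstration (`demo_config()`) uses a 60 x 60 grid, six
variables (two of which drive the species), 800 sampled occurrences, two
pseudo-GCMs x two scenarios, combinations {l, q, lq, lqp} x multipliers
{0.5, 1, 2} x two variable sets. After the uncertainty filter and 50-km
rarefaction roughly 170 records remain, giving calibration/evaluation halves
of ~85 each — the size regime of a realistic rarefied occurrence
compilation, and large enough that the E = 5% threshold excludes close to
(rather than well over) 5% of the calibration data. Even so, the omission
filter remains a near-boundary test by design (see above), and some seeds
legitimately select nothing; the pipeline then stops with a diagnostic
report.

## Numerical choices and degenerate inputs

* Earth radius 6,371.0088 km everywhere; great-circle math by haversine
  (agrees with a law-of-cosines oracle within 1 m under 1,000 km).
* Thinning is deterministic greedy deletion (most neighbours first, then
  summed inverse-distance crowding, then later input position), with a
  repair pass guaranteeing maximality; results are verified against a
  brute-force validator in the tests.
* Cell addressing uses half-open intervals from the upper-left corner;
  records on nodata cells or off-grid are excluded with logged counts.
* Constant variables are excluded from feature specs with a warning; a
  constant suitability grid makes the partial ROC undefined and the
  candidate non-significant; zero raw scores at occurrences push AICc to
  infinity rather than producing NaN.
* The count of active (nonzero) coefficients typically shrinks as the
  regularization multiplier grows, and the package's validation dataset
  exhibits a cleanly monotone path across all 17 multipliers; this is,
  however, a typical rather than provable property of L1 paths — with
  correlated features a coefficient can leave and re-enter the support as
  the penalty changes, and we have observed single-step swaps on other
  synthetic datasets.
* All stage seeds derive deterministically from one master seed, so any
  stage can be re-run in isolation and full runs are bitwise reproducible.
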