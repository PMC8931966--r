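---
title: "Modelling RMST difference curves with pseudo-values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RMST difference curves with pseudo-values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmstpv)
```

## The problem

When survival curves cross — an extreme form of non-proportional hazards —
no single hazard ratio summarises the treatment effect usefully. The
restricted mean survival time, $\mathrm{RMST}(\tau) = \int_0^\tau S(t)\,dt$,
is the expected lifetime over the horizon $[0, \tau]$ and remains
interpretable in exactly those situations. Rather than fixing one horizon,
`rmstpv` estimates the *difference curve*
$D(t) = \mathrm{RMST}_1(t) - \mathrm{RMST}_0(t)$ across the whole
follow-up, with covariate adjustment, pointwise confidence intervals, and a
simultaneous confidence band whose joint coverage refers to the entire
curve.

## The estimator

**Pseudo-values.** The RMST at a restriction time $\tau$ is estimated by
integrating the Kaplan–Meier curve. For each subject $i$ the jackknife
pseudo-value
$$\hat\theta_{\tau i} = n\,\widehat{\mathrm{RMST}}(\tau)
  - (n-1)\,\widehat{\mathrm{RMST}}^{-i}(\tau)$$
converts the censored functional estimate into one regression-ready
response per subject: with no censoring it is exactly $\min(T_i, \tau)$,
and its sample mean always equals the full-sample Kaplan–Meier RMST.
Validity requires censoring independent of both event times and
covariates. Pseudo-values are computed on a grid of $M$ restriction times
$\tau_1 < \dots < \tau_M$ placed at quantiles of the observed event times
(default $M = 16$ between the 0.01 and 0.99 quantiles), giving $M$
responses per subject.

Rather than refitting the Kaplan–Meier estimator $n$ times per grid point,
`pseudo_values()` exploits the product-limit structure: removing one
subject rescales each factor of the product by a closed-form ratio over
that subject's risk period, so all $n$ leave-one-out integrals at one
$\tau$ follow from two prefix sums over the event-time segments
($O(K + n)$ per grid point after sorting). The test suite verifies exact
agreement (to $10^{-9}$) with naive leave-one-out refitting on random
censored samples with ties.

**Regression.** The expanded $n \times M$-row data are modelled with an
identity link,
$$\mathrm{RMST}(t \mid Z) = \text{baseline}(t) + \sum_k \beta_k(t) Z_k,$$
where the baseline and each time-varying coefficient are either step
functions in the restriction times (dummy coding, $M-1$ indicators) or
natural cubic splines $\sum_j \delta_j B_j(t)$ with boundary knots at the
grid extremes and interior knots at equally spaced quantiles of the grid.
With the identity link a covariate coefficient *is* an RMST difference; a
time-constant difference is implausible (every difference curve starts at
0), so covariates enter with time interactions by default.

With an independence working correlation the estimating equations are the
least-squares normal equations on the expanded data, solved in closed
form. Within-subject correlation of the $M$ pseudo-values is handled by
the cluster-robust sandwich covariance
$(Z'Z)^{-1}\left[\sum_i U_i U_i'\right](Z'Z)^{-1}$ with $U_i$ the score
summed within subject. Theory for pseudo-value estimating functions shows
this sandwich is (slightly) conservative; no correction is applied. The
"naive" model-based covariance $\hat\phi (Z'Z)^{-1}$ with
$\hat\phi = RSS/(N-p)$ is reported alongside and enters the QIC penalty.

**Model selection.** The spline dimension is chosen by
$$\mathrm{QIC} = SS + 2\,\mathrm{tr}(N^{-1}V),$$
with $SS$ the residual sum of squares, $N$ the naive and $V$ the robust
covariance; lower is better and ties break toward the smaller df. The
quadratic quasi-likelihood kernel is $QL = -SS/2$; we state this
explicitly because sign conventions for quasi-likelihood information
criteria vary across software, and writing the criterion as a penalized
sum of squares makes "lower = better" unambiguous. Under independence and
homoscedasticity the trace is approximately the parameter count, and
`qic(fit, penalty = "2p")` exposes that simplification.

**The difference curve and its band.** For a covariate $A$ the curve is a
linear contrast $D(t) = c(t)'\beta$ collecting $A$'s main effect, its
time-interaction terms at $t$, and (for models with effect modifiers,
e.g. a treatment-by-age interaction) the interaction terms at fixed
modifier values. The robust variance is the quadratic form
$c(t)' \hat V c(t)$. The simultaneous band replaces the pointwise 1.96 by
the max-$t$ critical value $u_{level}$: the level-quantile of
$\max_t |c(t)'(\beta^* - \hat\beta)| / se(t)$ over an equally spaced time
grid, with $\beta^*$ drawn from $N(\hat\beta, \hat V)$. The supremum over
$[a, b] = [\tau_1, \tau_M]$ is approximated on the grid; no extrapolation
beyond the grid range is permitted for the band.

## Numerical choices

* **Critical value by Monte Carlo.** $u_{level}$ is computed from draws of
  correlated standard normals with the contrast correlation matrix
  (eigendecomposition square root, chunked to bound memory). Defaults:
  100 grid points, $10^5$ draws, seed 20220318; the global RNG stream is
  saved and restored so band computation never perturbs simulations. With
  $2\times 10^5$ draws the critical value is stable to about $\pm 0.005$
  across seeds. The value is floored at the pointwise normal quantile, so
  the band always contains the pointwise interval; a one-point grid uses
  the exact quantile 1.959964. For dummy-time baselines the band is a step
  band evaluated at the restriction times only.
* **Ties and extensions.** At tied times events precede censorings (the
  standard Kaplan–Meier risk-set convention). When a restriction time
  exceeds the largest follow-up time and the curve has not reached zero,
  the survival curve is extended at its last value with a warning; the
  same extension applies inside leave-one-out fits, where the removed
  subject may carry the largest observation.
* **Degenerate grids.** Quantile grids collapse duplicates (heavily tied
  data) with a warning; a rank-deficient design names the collinear terms;
  grid times with zero contrast variance are dropped from the supremum
  with a warning.
* **Censoring calibration.** Papers in this area typically state only a
  censoring *fraction*. `calibrate_censoring()` solves for the exponential
  rate (or uniform upper bound) whose marginal censoring probability over
  the arm mixture equals the target, by root-finding on an analytically
  integrated probability (the exponential case is integrated on the
  censoring-quantile scale so arbitrarily extreme rates remain stable).

## What the simulations emulate

The generator produces two-arm right-censored samples from Weibull and
piecewise-exponential laws whose survival curves cross at various
probability levels — the regime in which an RMST difference curve is most
informative — plus exponential or uniform censoring at a stated marginal
fraction. Two study designs are built in:

* `run_table1_cell()`: Weibull event times with rate
  $\exp(\beta_b Z)$ and shape $\delta \in \{0.5, 1, 2\}$, 25% exponential
  censoring, restriction at the 75th or 90th percentile; compares the
  single-restriction-time estimator against the 16-time vector estimator
  (spline baseline, QIC df in 3–12, evaluated at $\tau$). Replicates whose
  largest observed event time falls short of $\tau$ are excluded and
  counted; vector-method replicates whose last restriction time falls
  short of $\tau$ are evaluated in (linear) extrapolation and counted
  separately. Both estimators are essentially unbiased away from the
  extrapolation regime.
* `run_table2_scenario()`: five crossing-hazards scenarios with 20%
  uniform censoring and balanced arms; per replicate, 16 quantile
  restriction times, QIC df in 4–12, and a simultaneous band on 10 equally
  spaced times over the grid range; reports the fraction of replicates
  whose band covers the true difference curve everywhere, the mean band
  length, and the mean absolute deviation from the truth. True curves come
  from closed forms (incomplete gamma for Weibull, exact segment
  integrals for piecewise-exponential), cross-checked against quadrature
  to $10^{-8}$.

Two printed Weibull parameter pairs are convention-ambiguous; the shipped
scenarios read scenario 1 as (rate, shape) of $e^{-\lambda t^\delta}$ and
scenarios 2, 4, 5 as (shape, scale), the reading under which the five
survival-curve patterns display the intended crossings. Scenario 3 is
exponential/piecewise-exponential and unambiguous, and is therefore the
one used for quantitative verification.

The generator draws i.i.d. subjects with completely independent censoring
and covariates known exactly; real data feature covariate-dependent
censoring, measurement error and non-random accrual, none of which these
studies probe. Passing simulations therefore demonstrate correctness of
the estimator and calibration of the band *under the stated sampling
assumptions*, not robustness to their violation.

## Design choices where the design was open

* **Working correlation: independence.** It makes the identity-link
  estimator a single closed-form solve and costs little efficiency here;
  the sandwich remains valid regardless.
* **Quantile-based restriction grids.** $M = 16$ between the 0.01 and
  0.99 event-time quantiles by default; an alternative heuristic
  (roughly 10 events per grid point) can be mimicked by choosing $M$
  accordingly. Results are insensitive to $M$ beyond about 10.
* **Bernoulli vs balanced arms.** `simulate_sample()` draws arm labels
  Bernoulli(allocation) by default (matching a randomized-allocation
  model); the band study uses exactly balanced groups.
* **Per-replicate seeds.** A master seed plus a fixed-stride offset per
  replicate keeps studies reproducible and trivially parallelizable.
* **Problem sizes.** The shipped verification runs use 500 replicates per
  study cell, 20,000 band draws per replicate inside studies, and
  $5\times 10^5$ draws where a critical value is compared against an
  analytic limit; these sizes give Monte-Carlo standard errors a factor
  of ~3 below the effects being checked.

## Known limitations

* The sandwich covariance is asymptotically conservative for
  pseudo-values, yet in finite samples with many coefficients (e.g. a
  df-12 spline and its interactions at 400 subjects) the usual
  small-sample downward bias of cluster-robust variances partly offsets
  that conservativeness: in the crossing-hazards band study the
  standardized estimation errors have standard deviation ≈ 1.04 and the
  empirical simultaneous coverage of the 95% band sits a few points below
  nominal (≈ 0.89–0.91 at 200–400 per group). Smoothing bias near sharp
  bends of $D(t)$ contributes at the larger sample size, where bands
  narrow but the spline bias does not. No degrees-of-freedom correction
  is applied; users comparing software should expect such corrections to
  widen bands by roughly $\sqrt{n/(n-p)}$.
* QIC with the trace penalty is dominated by the residual sum of squares
  and tends to select the largest candidate df in the band-study regime;
  the selection range is therefore part of the study conditions.
* Left truncation, interval censoring, time-dependent covariates, and
  competing risks are out of scope; only the difference curve (not bands
  for the RMST curves themselves) is banded.
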