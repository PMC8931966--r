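# rmstpv — RMST difference curves from pseudo-value regression

`rmstpv` estimates how the difference in **restricted mean survival time**
(RMST) between groups evolves over follow-up. The RMST at horizon τ,
RMST(τ) = ∫₀^τ S(t) dt, is the expected lifetime capped at τ — a
time-scale summary that stays interpretable when hazards are
non-proportional or survival curves cross, precisely where a single
hazard ratio misleads.

The package is aimed at biostatisticians analysing trials or cohorts with
crossing or converging survival curves who want a covariate-adjusted
difference curve D(t) = RMST₁(t) − RMST₀(t) with honest *simultaneous*
uncertainty for the whole curve, and at methodologists who want the
accompanying simulation machinery.

## Method in brief

1. **Jackknife pseudo-values.** At a grid of restriction times
   τ₁ < … < τ_M (quantiles of the observed event times, default M = 16),
   each subject receives the pseudo-value
   θ̂_{τi} = n·RMST̂(τ) − (n−1)·RMST̂^(−i)(τ), where RMST̂ integrates the
   Kaplan–Meier curve and RMST̂^(−i) omits subject i. A closed-form
   incremental algorithm avoids the n leave-one-out refits and is
   test-verified against them to 1e-9.
2. **Identity-link GEE.** The n×M expanded responses are regressed on a
   baseline time curve (restriction-time indicators or a natural cubic
   spline) plus covariate main effects and time-varying interactions.
   With an independence working correlation the solution is closed-form
   least squares; within-subject correlation is absorbed by the
   cluster-robust **sandwich covariance**. The spline dimension is chosen
   by QIC = SS + 2·tr(N⁻¹V).
3. **Simultaneous band.** D(t) = c(t)'β̂ with robust variance
   c(t)'V̂c(t); the max-t critical value u (Monte Carlo over the contrast
   correlation) replaces 1.96 so the band covers the entire curve at the
   nominal level.

## Worked example

Simulate a two-arm trial with crossing survival curves (arm 0 exponential
with mean 12; arm 1 piecewise exponential, high early hazard 0.25 then
1/35 after t = 2; 20% uniform censoring), then fit the whole pipeline:

```r
library(rmstpv)
sc  <- builtin_scenario(3)
smp <- simulate_sample(sc, n = 400, seed = 2026, balanced = TRUE)
smp
#> <survival_sample> n = 400, events = 332 (83.0%), covariates: Z

res <- fit_rmst_curve(smp, "Z", df_range = 4:12)
res$curve
#> <rmst_curve> D(t) for 'Z' at 16 times; 95% simultaneous band (u = 2.592)
#>         time      estimate           se        ci_lo         ci_hi ...
#> 1 0.04177086 -0.0003768819 0.0003207774 -0.001005594  0.0002518303
#> 2 0.52044595 -0.0105788048 0.0075935166 -0.025461824  0.0043042144
#> ...
#> 8 4.25036622 -0.6714930329 0.1499128601 -0.965316839 -0.3776692264

plot(res$curve)
```

Reading the output: at t ≈ 4.25 the high early hazard of arm 1 has cost
its patients about 0.67 expected lifetime units out of the first 4.25
(pointwise 95% CI −0.97 to −0.38). The simultaneous band uses the
critical value u = 2.59 instead of 1.96, so statements like "arm 1 is
behind from t ≈ 1.4 through t ≈ 10" hold jointly over the whole follow-up
at the 95% level. Later in follow-up the sign flips as arm 1's flat
late hazard pays off — the regime a single-τ comparison would miss.

The same machinery handles effect modification, e.g. a
treatment-by-biomarker model whose difference curve is requested at a
fixed modifier value:

```r
cv <- difference_curve(fit, "A", at = list(Age = 60))
```

A thin command-line wrapper (`inst/cli/rmstpv.R`) exposes `fit` and
`simulate` subcommands over YAML configs; `cmd_fit()`/`cmd_simulate()`
are the equivalent R entry points.

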