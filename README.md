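# oxkin

Kinetic analysis of lipid-oxidation curves from microplate
spectrophotometry, and quantitative scoring of antioxidant combinations.

## The problem

Oxidative stability assays based on conjugated autoxidizable trienes track
the loss of absorbance at 273 nm as the lipid substrate (typically a
tung-oil nanoemulsion) oxidises. An effective antioxidant lengthens the
induction period — the lag phase before oxidation accelerates — and slows
the subsequent decay. Screening *combinations* of antioxidants requires
turning each well's absorbance trace into a small set of interpretable
kinetic parameters, plus a principled score of whether two antioxidants
together outperform the sum of their parts.

`oxkin` implements that workflow:

1. **Reduction.** Raw absorbance A(t) is mapped to the dimensionless scale
   A\* = (A − A∞)/(A₀ − A∞), running from 1 (unoxidised) to 0 (plateau).
2. **Weibull fit.** A\*(t) = exp[−(t/α)^β] is fitted by nonlinear least
   squares (replicates pooled). α (hours) is the characteristic time — A\*
   has dropped 63% at t = α regardless of β; β (dimensionless) is the
   shape — β = 1 is first-order kinetics with rate 1/α, β > 1 the sigmoidal,
   auto-accelerated decay typical of an induction period.
3. **Lag phase.** The oxidation rate is the Weibull density
   f(t) = (β/α)(t/α)^(β−1) exp[−(t/α)^β]. The lag phase LagP is the first
   (rising-branch) time at which f(t) reaches 5×10⁻³ h⁻¹, solved by a
   bracketed root finder; its confidence interval comes from Monte-Carlo
   propagation of the fitted parameter uncertainty (10,000 draws).
4. **Combination factor.** For a pair of antioxidants,
   CF = LagP(combo) / [LagP(A) + LagP(B)]. CF > 1 is synergy, CF < 1
   antagonism, CF = 1 additivity; the antioxidant efficiency AE is the
   combination's absolute LagP in hours. Ratio series are further typed
   T1–T4 (monotone rise, rise-then-decline, rising AE with flat CF,
   monotone decline).

Supporting modules provide a synthetic plate-assay generator with the same
statistical structure, summary-statistic hypothesis tests (one-way ANOVA
with Tukey HSD compact letters, paired/independent t-tests computed from
means, SDs and n), CSV readers for long and wide plate-reader exports, and
an end-to-end pipeline with a reproducible manifest.

## Worked example

Simulate a triplicate condition (α = 26.5 h, β = 5.1, instrument noise
0.01 AU), reduce each replicate with estimated endpoints, fit, and extract
the lag phase and a combination factor against two solo lag phases of
4.0 h and 3.1 h:

```r
library(oxkin)

spec <- simulation_spec(26.5, 5.1, noise_sd = 0.01,
                        condition_label = "aTOH:CA 1:3")
cur <- generate_curve(spec, seed = 42)
curves <- lapply(1:3, function(k) {
  cv <- cur[cur$replicate == k, ]
  ep <- estimate_endpoints(cv)
  reduced_curve(cv$time_h, reduce_absorbance(cv$absorbance, ep$a0, ep$a_inf),
                replicate = k)
})
fit <- fit_weibull(curves)
fit
#> Weibull oxidation kinetics fit (pooled replicates)
#>   alpha = 26.4 h   [26.4, 26.5]
#>   beta  = 5.1     [5.06, 5.15]
#>   RMSE (A*) = 0.006399   adj. R2 = 0.9998   n = 171

lag <- lagp_confidence_monte_carlo(fit, mc_iterations = 10000, seed = 42)
lag
#> Lag phase: 10.9 h  [10.8, 11] (95% MC, 10000 iterations)

cf <- combination_factor(lag$value, 4.0, 3.1)
classify_interaction(cf)
#> CF = 1.531 -> synergistic
```

The fitted α and β recover the generating values; the lag phase of 10.9 h
is the time at which the fitted oxidation-rate curve first reaches the
5×10⁻³ h⁻¹ threshold, and CF = 1.53 > 1 says the combination protects
longer than its components' lag phases add up to.

The full pipeline over a plate (`run_pipeline()`, or the thin CLI at
`inst/cli/oxkin`) emits per-condition fit tables, per-combination
interaction calls, ratio-series trend types and a quadrant table of CF
versus AE.

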