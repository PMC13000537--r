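# cortcurve

Model-based summary indicators of the salivary cortisol stress response
that remain comparable when data from acute stress studies with different
saliva sampling schedules are combined.

## The problem

Laboratory acute stress tests (TSST, gTSST, SECPT, MAST) measure the
cortisol response with a handful of saliva samples, but every study uses
its own sampling schedule. The conventional summary indicators are
computed directly from the raw samples:

- **AUCg / AUCi** — trapezoidal area under the cortisol–time curve with
  respect to ground / with respect to increase,
- **reactivity** — cortisol at the expected peak time minus the baseline,
- **max increase** — the largest excursion above baseline (non-negative).

Because the trapezoid stops at the last sample, observation-based AUCs are
mechanically coupled to sampling duration: when studies with 40-, 60- and
80-minute schedules are pooled, AUCg correlates with study design rather
than biology. cortcurve addresses this by fitting each individual's
response curve and computing all indicators from the fitted curve on a
common 0–80 min grid.

## The model

The structural response is a scaled, shifted gamma-density kernel

```
g(t) = A · f(t; α, β) + b0 + b1 (t − dT),   f = gamma density (shape α, rate β)
```

with amplitude `A` (nmol/L·min), baseline `b0` (nmol/L), optional slow
drift `b1` and time shift `dT`. Two fitting strategies are provided:

- **Amplitude scaling model (ASM)** — `fit_asm()`: one population-average
  curve is fitted to stress-condition responders (baseline fixed to the
  sample mean at t = 0); per individual only the amplitude is re-estimated
  by the closed-form least-squares scalar on baseline-normalized data.
- **Multilevel model (MM)** — `fit_mlm()`: a nonlinear mixed-effects model
  with log-normal random effects on α, β, A and normal effects on b0
  (optionally b1, dT), covariate effects on any parameter, a constant
  residual error model, and empirical-Bayes shrinkage of individual
  estimates toward the population mean. Estimation is a
  stochastic-approximation EM (SAEM) with a deterministic Laplace-EM
  alternative.

A stochastic simulator (`simulate_cohort()`) generates virtual cohorts
with red synthesis noise (Ornstein–Uhlenbeck deviations, Euler–Maruyama
integration on a 1-min grid) plus white measurement noise, and
schedule tools (`downsample()`, `build_combined_dataset()`,
`jitter_schedules()`) recreate realistic sparse and heterogeneous
sampling, so every indicator can be validated against "true" values from
the noise-resolved trajectories.

## Worked example

```r
library(cortcurve)

co  <- simulate_cohort(sim_config(n = 500, seed = 1))
sch <- sampling_schedule(c(0, 15, 25, 40, 60, 80))
d   <- downsample(co, sch)

fit <- fit_asm(d)
fit
#> Amplitude scaling model
#> Population-average cortisol response curve (4-parameter)
#> Cortisol response curve: g(t) = A * f(t - dT) + b0 + b1 (t - dT)
#>   alpha = 2.59, beta = 0.08956 /min, A = 265.8, b0 = 5.743 nmol/L
#>   fitted on 2544 samples from 424 participants; sigma = 4.239 nmol/L, BIC = 14599.6
#>   500 individual series; amplitude A: median 181.3 [IQR 53.6, 315.8]

head(indicators_model(fit), 3)
#>   participant_id condition method     AUCg      AUCi reactivity max_increase
#> 1       sim00001    stress    ASM 579.5538 172.02149  4.7013832      4.70068
#> 2       sim00002    stress    ASM 912.2717 539.52317 14.7452808     14.74307
#> 3       sim00003    stress    ASM 489.9835 -16.21106 -0.4430515      0.00000

truth <- true_indicators(co)
rank_accuracy(indicators_model(fit), truth)
#>      indicator method       r_s       mae       bias   n
#> 1         AUCg    ASM 0.9501558 55.051210 -4.0328525 500
#> 2         AUCi    ASM 0.9239159 59.408005 -1.4434248 500
#> 3   reactivity    ASM 0.9276472  1.744294  0.7372364 500
#> 4 max_increase    ASM 0.9312173  1.939578  1.5887877 500
```

The fitted population curve peaks about 18 min post-onset roughly
7 nmol/L above baseline; each individual's four indicators are computed
from their rescaled curve over the common 0–80 min window. Participant 3
illustrates a decliner: its amplitude is negative, so reactivity is
negative and max increase clamps at zero. The rank agreement with the
simulator's ground truth (Spearman r ≈ 0.92–0.95 here) is
the accuracy measure used throughout the evaluation tools. The
observation-based counterparts come from `indicators_obs(d)`; the
duration-confounding diagnostic is `duration_bias()`.

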