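---
title: "Model-based cortisol stress-response indicators: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based cortisol stress-response indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortcurve)
```

## The structural model

cortcurve models the salivary cortisol trajectory after an acute
laboratory stressor as a scaled gamma-density kernel around a baseline:

$$ g(t) = A \, f(t - dT;\ \alpha, \beta) + b_0 + b_1 (t - dT), $$

where $f$ is the gamma probability density with shape $\alpha$ (unitless)
and rate $\beta$ (1/min), $A$ scales the response magnitude
(nmol/L·min), $b_0$ is the pre-stressor baseline (nmol/L), $b_1$ permits
a slow linear drift (diurnal decline, nmol/L per min) and $dT$ shifts the
response onset (min). The density is defined as zero for $t - dT \le 0$:
the modelled response begins at (shifted) stressor onset, and before it
the curve is exactly the baseline plus drift. For $\alpha > 1$ the kernel
peaks at $(\alpha - 1)/\beta$ minutes, so e.g. $\alpha = 3.2$,
$\beta = 0.115$ places the peak near 19 min — typical TSST timing.

Both fitted models exist to *inter- and extrapolate* each individual's
sparse samples onto a common grid, so that the four standard summary
indicators — AUCg, AUCi, reactivity, maximum increase — can be computed
over a fixed 0–80 min window regardless of the sampling schedule that
produced the data.

## Preprocessing conventions

`correct_baseline()` averages all samples taken from −20 to +2 min
(closed interval) into one corrected baseline at $t = 0$; series without
such a sample cannot be baseline-corrected and are excluded with a typed
record (`exclusions()`), never dropped silently. `filter_window()` keeps
samples in $[0, 80]$ min. `flag_outliers()` marks values more than 5
pooled SDs from the pooled mean (computed over the whole dataset being
cleaned; apply per study by splitting first — the reference population is
a documented choice, and raw rather than log cortisol is used).
`classify_responder()` calls a series a responder when cortisol rises at
least 1.5 nmol/L from the corrected baseline to the maximum within
15–45 min (both ends included, by plain reading of the window).
`stratified_split()` partitions participants 80/20 within each study.

## The amplitude scaling model

`fit_asm()` assumes a common response *shape* and individual *magnitude*.
The population-average curve is fitted by pooled nonlinear least squares
(Levenberg–Marquardt, with $\alpha, \beta$ on the log scale to keep them
positive) to stress-condition responders only, with $b_0$ fixed to the
mean cortisol of the fitting sample at $t = 0$ rather than estimated.
Model selection between the four-parameter curve and the extension with
$dT$ and $b_1$ uses BIC ($k \ln N - 2 \ln L$ with a Gaussian residual
likelihood; ties within $10^{-9}$ go to the simpler model); on data whose
generating process has neither term, the four-parameter curve wins.

Per individual, three steps: (1) subtract the observed baseline from all
values; (2) regress the normalized post-baseline values on the
unit-amplitude population shape, giving the closed form
$A_i = \sum_j y_j f(t_j) / \sum_j f(t_j)^2$ (the baseline sample is
excluded from the loss — its normalized value is 0 and $f(0) = 0$ for
$\alpha > 1$, so this is a clarity choice, not a numerical one);
(3) shift the curve back up by the observed baseline. $A_i$ is
deliberately unconstrained in sign so declining control-condition
profiles are representable; the responder restriction applies only to
the population fit.

Because every ASM curve differs only by $A_i$ and its baseline, ASM-based
reactivity is evaluated at the *population* peak time for all
individuals, which makes it exactly proportional to $A_i$ — and therefore
perfectly rank-correlated with ASM-based AUCi. The package treats this as
a feature to be asserted (the two indicators carry identical rank
information under this model), not an accident.

## The nonlinear multilevel model

`fit_mlm()` drops the common-shape assumption. On a transformed scale
$\varphi = (\log\alpha, \log\beta, \log A, b_0, \ldots)$ each subject's
parameters are

$$ \varphi_i = X_i \theta + \eta_i, \qquad \eta_i \sim N(0,
\mathrm{diag}(\omega)), \qquad y_{ij} = g(t_{ij}; \psi(\varphi_i)) +
\varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, a^2). $$

Log-normal families for $\alpha, \beta, A$ are the conventional
positivity-preserving choice; $b_0$ (and optional $b_1$, $dT$) are
normal. The residual model is "constant" (one additive SD $a$).
Covariates (gender; dummy-coded stress-test design with TSST-stress as
reference) enter $X_i$ on the transformed scale, so effects on log-scale
parameters are multiplicative on the natural scale. A covariate effect is
*retained* only when its Wald $p < .05$, its coefficient of variation
($100\,SE/|\hat\theta|$) is at most 25%, and adding it does not increase
BIC (`evaluate_covariate()`).

By default random effects are placed on $(\alpha, \beta, A, b_0)$ with
$b_1 = dT = 0$ fixed: typical acute-stress schedules have 2–6 samples
per series, which cannot support six random effects, and the selected
population model carries neither extra term. The full six-parameter
model remains available through `mlm_spec()`.

### Estimation

Two estimators share initialization (a pooled population fit seeds the
fixed effects; per-subject baselines and closed-form amplitudes seed the
random effects) and all post-processing:

- **SAEM** (default): the E-step draws from each subject's conditional
  posterior $p(\varphi_i \mid y_i)$ by random-walk Metropolis, proposing
  joint steps preconditioned with a per-subject Laplace posterior
  Cholesky factor (refreshed every 25 iterations) and adapting the global
  scale toward 25% acceptance during burn-in. Sufficient statistics are
  smoothed with step size 1 for the first 300 iterations and $1/(k-300)$
  for the next 300; the M-step is least squares for $\theta$ and moment
  updates for $\omega$ and $a^2$. The whole E-step is vectorized across
  subjects (one curve evaluation per proposal for the entire dataset), and
  the fit is exactly reproducible from its seed.
- **Laplace-EM** (`method = "laplace"`): the E-step is a damped
  Gauss–Newton search for each subject's posterior mode with a Gaussian
  curvature approximation; deterministic and roughly five times faster.
  For models that are *linear* in the random effects this is exact
  maximum likelihood (the test suite verifies agreement with a
  closed-form marginal-likelihood oracle to $10^{-3}$ on such a
  submodel). For the full nonlinear model with very few samples per
  subject, first-order methods of this family carry a small bias in the
  shape parameters; the SAEM E-step removes it, which is why SAEM is the
  default for inference while Laplace-EM is the documented choice for
  cohort-scale indicator extraction, where only the rank ordering of
  empirical-Bayes estimates matters.

After either estimator, a final Gauss–Newton pass yields the
empirical-Bayes (MAP) individual parameters, the Laplace marginal
log-likelihood and BIC, and fixed-effect standard errors from the
EM observed-information identity
$I(\theta) = \sum_i B_i^\top (\Omega^{-1} - \Omega^{-1} S_i \Omega^{-1})
B_i$ with $S_i$ the subject's posterior covariance — the full
cross-parameter form, since dropping the off-diagonal blocks understates
the uncertainty of correlated shape parameters.

Shrinkage is inherent: subjects with fewer or less informative samples
have flatter likelihoods, so their MAP estimates sit closer to the
population mean. The acceptance suite verifies this with a 2-sample
versus 13-sample subject sharing identical true parameters. The 2-sample
subject is sampled at {0, 5} min: a deliberately uninformative design,
because a single sample *at the peak* already identifies the amplitude
almost as well as a dense schedule, leaving the contrast to be decided by
noise. The comparison metric is the $\omega$-standardized distance of the
shrunken $(\log\alpha, \log\beta, \log A)$ estimates from the population
mean: those are the coordinates whose data information scales with
post-baseline sampling density, whereas $b_0$ is pinned by the baseline
sample in *both* designs and would only add noise to the contrast.

## Model-based indicators

`indicators_model()` evaluates a fitted curve on a 1-min grid over
0–80 min and computes: AUCg by the trapezoid on that grid (the analytic
gamma-CDF integral serves as the test oracle; at 1-min resolution the two
agree to well under 0.5%), AUCi = AUCg − c(0)·80, reactivity =
c(t_peak) − c(0), and max increase = max(0, max c − c(0)). The curve's
own value at $t = 0$ is the baseline — for ASM this coincides with the
observed baseline by construction; for MM it is the fitted value, which
treats the measured baseline as one more noisy observation. Peak search
runs on a 0.1-min grid with ties to the earliest time; flat curves give
reactivity and max increase 0 without error. Observation-based
counterparts (`indicators_obs()`) use the raw samples; OBS reactivity
takes the sample nearest to the nominal peak (default 25 min — the
midpoint of the 15–45 min responder window — with ties to the earlier
sample; linear interpolation is available as an option).

## The cohort simulator

`simulate_cohort()` generates the synthetic cohorts used for validation.
Per virtual individual, parameters are drawn independently:
$\alpha \sim \mathrm{LogN}(\log 3.2, 0.18)$,
$\beta \sim \mathrm{LogN}(\log 0.115, 0.18)$,
$A \sim \mathrm{LogN}(\log 200, 0.7)$ (males ×1.2),
$b_0 \sim N(5.5, 1.3)$ truncated at 0.5 (males +0.5), with a 20%
non-responder fraction whose amplitude is $N(0, 10)$ so flat and
declining profiles occur. These values were chosen once so that the
population response peaks 19–25 min post-onset with a median increase
near 6 nmol/L over a baseline near 5.5 nmol/L — the regime of a typical
TSST cohort — and were not revisited afterwards.

Noise has the stated two components. *Red* synthesis noise is a zero-mean
Ornstein–Uhlenbeck deviation $R$ around the structural curve,
$dR = -\theta R\,dt + \sigma_{red}\,dW$, integrated by Euler–Maruyama on
the 1-min grid from $R(-20) = 0$ (the 20-min burn-in approaches the
stationary law before the stressor); defaults $\theta = 0.1$/min,
$\sigma_{red} = 0.45$ give a stationary SD of ~1 nmol/L with a 10-min
correlation time. The deviation form (rather than an OU process that
*tracks* the curve) keeps the structural mean undistorted and degenerates
exactly to the deterministic curve when $\sigma_{red} = 0$. *White*
measurement noise ($\sigma_{white} = 1$ nmol/L) is added independently
per sample. "True" indicators come from the red-only trajectories —
ground truth free of measurement error; true reactivity is evaluated at
each individual's structural peak time (evaluating at the trajectory's own
argmax would make it identical to max increase).

What the simulator does *not* emulate: anticipatory cortisol rises before
stressor onset, assay floor/ceiling effects, inter-study assay
differences, diurnal drift (unless $b_1$ is configured), and
non-gamma-shaped individual responses. Passing validation on these
cohorts therefore demonstrates schedule-robustness of the indicator
machinery under the stated generative assumptions, not correctness on
every real-world dataset.

Schedule tools recreate the designs under study: `default_schedule_sets()`
ships single-factor sets (duration 40/60/80 min with shared early
timepoints; frequency 3/5/9 samples over 0–80; peak timepoint 15/25/35
with and without recovery samples), a 12-schedule representative set and
a 5-schedule high-variability set including the very sparse {0, 30}
design. The exact member schedules are the package's own documented
defaults honouring those structural constraints. `jitter_schedules()`
adds per-individual timing noise around the two study archetypes
(medium: 0, 21.7 (1.5), 43.9 (2.2), 66.1 (2.6), 80; high: 0, 31.8 (5.0),
60.4 (5.6) — mean (SD) minutes, rounded to the 1-min grid with bounded
redraws to keep orderings strict).

## Evaluation machinery

Rank-order accuracy is the Spearman correlation between estimated and
true indicators (`rank_accuracy()`, which also reports MAE and bias as
true-minus-estimated means); stability is the mean pairwise Spearman
across schedules in a set (`stability()`). Methods are compared with
paired t-tests on raw coefficient vectors across schedules
(deliberately untransformed), exact sign-flip permutation tests across
the ten combined-data replicates (all $2^{10}$ assignments enumerated;
with ten uniformly positive differences the two-sided p is exactly
2/1024), and Fisher-Z tests per schedule using the independent-samples
approximation $Z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)
/\sqrt{2/(n-3)}$ — the two accuracies share the truth variable, so a
dependent-correlations correction is available via the `r12` argument.
Fisher-Z averaging (`fisher_average()`) summarizes accuracy across
schedules; `duration_bias()` is the Spearman correlation of indicator
values with allocated sampling duration; `obs_truncated()` implements the
harmonized OBS variant cut at the latest timepoint common to all
schedules. The significance threshold is .05 two-sided throughout, with
no multiplicity correction.

## Numerical choices and degenerate inputs

- Random-effect variances are floored at $10^{-4}$ and the residual
  variance at $10^{-8}$; zero-variance cohorts shrink everyone to the
  population mean rather than erroring.
- Subjects with fewer than two samples are excluded from `fit_mlm()`
  with a typed record.
- The permutation test enumerates at most $2^{20}$ assignments; longer
  vectors are rejected rather than silently approximated.
- Constant vectors make Spearman correlations undefined: `NA` with a
  warning, so a fully harmonized duration analysis signals rather than
  fabricates a zero.
- Simulated observed values are truncated at 0 nmol/L on downsampling
  (white noise can otherwise produce tiny negatives; assays cannot).

## Problem sizes used by the shipped checks

The test suite exercises the combined-data experiment at n = 2000 with
ten replicate allocations, parameter recovery at n = 200 (six samples
per subject) and shrinkage over 20 seeds; `scripts/acceptance.R` runs
the same pipeline with n = 1000 for the combined-data block and n = 200
elsewhere. These are the package's chosen desk-scale problem sizes; all
conclusions asserted at these sizes are qualitative orderings and
tolerance checks, not printed-coefficient reproductions.

## Known limitations

The gamma kernel couples reactivity- and recovery-phase steepness
through $\alpha$, so individual recovery dynamics cannot vary
independently of the rise; recovery-specific indicators are out of
scope. The multilevel model conditions individual estimates on gender
and stress-test covariates, so downstream analyses must not re-test
those variables on MM-derived indicators. ASM reactivity and AUCi are
rank-identical by construction and should not be treated as independent
measures. The estimators assume the constant error model; heteroscedastic
alternatives are not implemented.
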