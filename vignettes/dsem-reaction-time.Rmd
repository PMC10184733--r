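---
title: "Modeling trial-level reaction time: mean, inertia, trend, and variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trial-level reaction time: mean, inertia, trend, and variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`dsemrt` fits a two-level dynamic structural equation model (DSEM) of
trial-level reaction time. Within person $i$, the natural log of RT on
trial $t$ follows an AR(1) regression with a linear practice trend and a
person-specific residual variance:

$$
\log RT_{t,i} = \mu_i + \phi_i \,\log RT_{t-1,i} + \beta_{t,i}\, t
  + \varepsilon_{t,i}, \qquad \varepsilon_{t,i} \sim N(0, \psi_i).
$$

Between persons, the four components — mean level $\mu_i$ (log-seconds),
inertia $\phi_i$ (unitless lag-1 autoregression), trend $\beta_{t,i}$
(log-seconds per trial), and residual variance $\psi_i$, modeled
log-linearly to keep it positive — are jointly normal around
covariate-implied means:

$$
\begin{aligned}
\mu_i &= \gamma_{00} + \gamma_{01}\mathrm{FA}_i + \gamma_{02}\mathrm{Age}_i + u_{0i}\\
\phi_i &= \gamma_{10} + \gamma_{11}\mathrm{FA}_i + \gamma_{12}\mathrm{Age}_i + u_{1i}\\
\beta_{t,i} &= \gamma_{20} + \gamma_{21}\mathrm{FA}_i + \gamma_{22}\mathrm{Age}_i + u_{2i}\\
\psi_i &= \exp(\omega_0 + \omega_1\mathrm{FA}_i + \omega_2\mathrm{Age}_i + u_{3i})
\end{aligned}
\qquad \mathbf u_i \sim \mathrm{MVN}(\mathbf 0, \tau).
$$

The scientific question this setup serves is whether white-matter
microstructure (fractional anisotropy, FA, a unitless scalar per tract)
predicts not just slower mean responses but *less consistent* ones — the
neural-noise idea that degraded axonal signal transfer shows up as
trial-to-trial variability. Because the covariates come from a scan that
only a fraction of the cohort received, FA and age are modeled jointly as
bivariate normal ("joint likelihood"), so unscanned persons still inform
the behavioral side of the model instead of being listwise-deleted.

Key assumptions: log-RT residuals are conditionally normal; dynamics are
first-order and linear in the raw lagged outcome; person effects are
jointly normal; covariate missingness is unrelated to the missing values
themselves (the two-stage design makes this plausible by construction);
trial series are equally spaced in trial number (the trend uses the trial
index, not clock time).

## The synthetic cohort

The raw study data sit behind a data-sharing agreement, so the package
ships a generator (`default_population()`, `simulate_dataset()`) whose
defaults are calibrated to the published unconditional estimates of a
large lifespan simple-RT study:

| quantity | value | units |
|---|---|---|
| mean log-RT $\gamma_{00}$-implied | $-0.908$ | log-seconds |
| mean inertia | $0.036$ | — |
| mean trend | $-0.001$ | log-seconds/trial |
| mean log residual variance | $-3.292$ | log(log-seconds$^2$) |
| $\tau$ diagonal | $0.083,\ 0.008,\ 1.9\times10^{-5},\ 0.424$ | component$^2$ |
| trials per person | 50 | — |
| covariate-observed fraction | $708/2681 \approx 0.264$ | — |
| age–FA correlation | $-0.470$ | — |

Covariate effects are back-transformed from the published standardized
effects (for the mean: FA $-0.149$, age $0.351$; for log variance: FA
$-0.197$, age $0.272$; smaller values for inertia and trend) using age SD
18 years and tract-FA SD 0.03, with the residual $\tau$ deflated by the
reported between-person $R^2$ (0.201, 0.010, 0.012, 0.169). Intercepts are
chosen so the component means land on the unconditional values at the
covariate means (age 54, FA 0.40). Residual correlations among the $u$'s
are set once to the reported qualitative pattern — $\mu$, $\phi$, $\psi$
mutually positive (the $\mu$–$\psi$ residual correlation at the reported
0.263), all negative with the trend, $\pm 0.2$ where no value is printed.
With these settings the generator reproduces the published *marginal*
$\mu$–$\psi$ correlation (draws give $\approx 0.40$ against the reported
0.397) without it ever being targeted directly.

What the generator deliberately does **not** emulate: the 3-second
response deadline (no censoring of slow trials — the timeout handling in
the source task is unstated, so the generator stays uncensored by
default), the skewed intertrial-interval structure, heavy non-normal RT
tails, and any age trend in the number of usable trials. Tests passing on
this cohort therefore certify the estimator under the model's own
assumptions, not robustness to those real-data features.

Other generator choices: trial indices are 1-based and uncentered (the
trend coefficient multiplies the raw index; centering would only shift
the interpretation of $\mu_i$); the first trial is drawn from the local
stationary AR(1) distribution when $|\phi_i| < 1$ (mean
$(\mu_i + \beta_{t,i})/(1-\phi_i)$, variance $\psi_i/(1-\phi_i^2)$), else
from $N(\mu_i, \psi_i$); exemplar series (`make_exemplars()`) raise one
component by $+2$ between-person SDs with shared innovations so the
contrast is visible by eye — the offset is configurable.

## Estimation

`dsem_fit()` runs a centered (hierarchical) Gibbs sampler written in
C++ (RcppArmadillo), with every block conjugate except two:

- person effects: the mean-type components $(\mu_i, \phi_i, \beta_{t,i})$
  are exact multivariate-normal draws given $\log\psi_i$; $\log\psi_i$
  uses a per-person adaptive random-walk Metropolis step (target
  acceptance 0.44, adaptation frozen after burn-in);
- fixed effects: one conjugate multivariate-normal block for all
  $\gamma/\omega$ rows attached to random components, a pooled conjugate
  block for rows whose component is constrained fixed, and a small
  adaptive Metropolis step for the $\omega$ row when $\psi$ carries no
  random effect;
- $\tau$: conjugate inverse-Wishart; exogenous covariate mean/covariance:
  conjugate normal–inverse-Wishart (Jeffreys); missing covariates and
  missing trials: exact conditional-normal draws.

Two sampler design points deserve explanation because they were genuinely
open:

**Prior on $\tau$.** The components live on scales four orders of
magnitude apart, which rules out any fixed-scale inverse-Wishart. A
scale-free $|\tau|^{-(d+1)/2}$ prior is conjugate but places a density
spike at singular $\tau$; in long runs a chain can sit in a spurious
near-zero-variance mode for a weakly identified component (we observed a
chain pinned at $\tau_\phi \approx 10^{-4}$ while its twin sat at the
data-supported $10^{-2}$). The package therefore uses the flat prior —
uniform over positive-definite matrices, the default convention of the
commercial DSEM software this model class is associated with — whose
conditional is $\mathrm{IW}(S, n - d - 1)$ and which removes the singular
spike. The cost is a mild upward bias in weakly identified variance
components at small $n$; the recovery suite quantifies it (a few percent
of the generating SD at 200 persons).

**Funnel traversal.** Centered Gibbs mixes geometrically slowly between
small-$\tau$ and moderate-$\tau$ states. Each iteration therefore adds one
*group scale move* per random component: propose $s = e^{\sigma z}$,
rescale that component's person deviations and the matching row/column of
$\tau$ jointly, and accept by Metropolis (the prior and Jacobian terms
reduce to $(d{+}1)\log s$ under the flat prior, the likelihood supplies
the rest). With the move in place the potential scale reduction for every
monitored parameter sits at $\approx 1.003$ where plain Gibbs left values
above 3.

Fixed-effect priors default to $N(0, 10^2)$ and are configurable
(`dsem_prior()`), which the calibration check uses. Covariates are
centered internally for conditioning and all reported coefficients are
back-transformed to raw scale per draw. Chains (default 2) get
overdispersed initializations from jittered per-person least squares;
seeds govern everything, so a rerun is byte-identical.

The sampler fits the raw-lag parameterization exactly as the within-person
equation above is written. The latently centered alternative (lag and
trend removed before the autoregression, making residuals shift-invariant)
is implemented in `conditional_loglik()` for likelihood evaluation and
comparison, but not in the sampler, where centering breaks the conjugate
person-level blocks; `dsem_fit()` refuses it loudly. Covariate blocks
require all four random effects active: with a deterministic (fixed)
component, a missing covariate would no longer have a normal conditional,
and the study's conditional models are full-random anyway.

Numerical floors: $\psi$ is floored at $10^{-12}$ during evaluation;
$\tau$ draws get $10^{-12}$ added to the diagonal and the partition
inverses a matching absolute ridge, so chains survive visits to
effectively-zero variance states on data that truly lack a component.
Adaptive step sizes are clamped (log-variance steps to $[10^{-3}, 5]$),
which prevents runaway adaptation along likelihood-flat directions.

## Diagnostics and model comparison

`psr()` computes the Gelman–Rubin potential scale reduction from the
post-burn-in halves of $\ge 2$ chains,
$\sqrt{(\frac{n-1}{n}W + B/n)/W}$, with the conventional `< 1.10`
convergence rule. `convergence_protocol()` implements the
iteration-doubling stability rule: fit at $N$ and $2N$ iterations with the
same seed, twice more at $2N$ with fresh seeds, compute each solution's
relative bias $|b-a|/|a|$ against the $2N$ reference, retain if every
maximum is below 5%, else double everything (up to `max_doublings`) —
exhaustion produces a non-retention report, not an error. The bias is
monitored over fixed effects, $\omega$'s, the $\tau$ diagonal and the
$\tau$ *correlations*; raw covariances are excluded, and a monitored
quantity whose reference estimate sits within 2 posterior SDs of zero is
flagged indeterminate rather than entering the retention maximum — a
ratio to a reference indistinguishable from zero measures Monte-Carlo
noise, not stability (at desk-scale cohorts such ratios fluctuate by
10%+ across seeds while every PSR sits at 1.00).

`dic()` reports the deviance information criterion with the deviance
conditional on the person effects ($p_D = \bar D - D(\hat\theta)$, person
effects at their posterior means, $\psi$ at the posterior mean of
$\log\psi$), the customary focus when the question is whether random
effects belong in the model at all. On generator output with the default
$\tau$, the four-random-effect model beats the fixed-effects model by
thousands of DIC units; with $\tau = 0$ the gap collapses to single
digits.

## Posterior summaries and inference

- `summarize_draws()`: posterior mean, SD, equal-tailed percentile
  interval.
- `standardized_within_effects()`: per person,
  $\phi_i \cdot \mathrm{SD}(y_{t-1})/\mathrm{SD}(y_t)$ (and the trend
  analogue) over that person's own series, averaged across persons, per
  draw.
- `standardized_between_effects()`: $\gamma \cdot
  \mathrm{SD}(x)/\mathrm{SD}(\text{effect})$ per draw, with the covariate
  SD from the jointly estimated exogenous model and the effect SD from the
  model-implied total (explained + residual) variance — the conventional
  SEM standardization, stated here because the source material reports
  standardized effects without printing the formula.
- `r2_between()`: $1 - \tau_{\text{cond},jj}/\tau_{\text{uncond},jj}$
  per draw-pair, clipped at zero, negative pairs flagged; computing per
  draw rather than from point estimates is what gives the $R^2$ rows their
  own credible intervals.
- `factor_scores()`: posterior means of the person effects — shrinkage
  estimates whose spread is deliberately smaller than $\tau$.
- `p_from_posterior()` and `fdr_adjust()`: two-sided normal-tail p-values
  from estimate and posterior SE, Benjamini–Hochberg adjusted. The FDR
  family defaults to the covariate tests within one model (8 tests in the
  FA+age model); the family choice is recorded in the pipeline output
  because no convention is canonical here.

`observed_variability()` and `regress_observed_on_scores()` reproduce the
two-step contamination analysis: per-person iSD and iCV computed from
log-RT (the iCV denominator is the mean *log* RT, matching the stated
computation; a raw-RT option exists since the wider literature is
ambiguous — note mean log-RT is negative for sub-second tasks, so iCV
inherits its sign), regressed on the four factor scores with standardized
coefficients. This two-step regression ignores factor-score uncertainty,
exactly as the original analysis does; treat its SEs as optimistic.

## Problem sizes and what the checks show

The validation suite runs at sizes chosen to make the full loop
repeatable on a laptop: parameter recovery uses 20 replicates of 200
persons × 50 trials with 2000 MCMC iterations per chain (2 chains);
model-comparison and diagnostic demonstrations use 100–200 persons; the
calibration check draws the mean intercept from a $N(-0.9, 0.1^2)$
calibration distribution 20 times at 40 persons × 25 trials and ranks the
truth among 99 thinned draws (the other parameters stay at fixed
generating values under diffuse priors, so the rank-uniformity statement
is approximate — it detects gross miscalibration, not fine departures).
Observed coverage of 95% intervals is 18–19 of 20 replicates for the
headline parameters, and posterior-mean bias stays within a few percent of
the generating between-person SD. At these sizes the raw-scale conditional
intercepts are extrapolations far outside the covariate range, so the bias
summaries evaluate the identified functionals instead: component means at
the covariate means, and covariate effects per predictor SD.

## Limitations

- The sampler covers the raw-lag parameterization only; latent centering
  is evaluation-only.
- Conditional (covariate) models require all four random effects.
- The flat $\tau$ prior trades a small upward variance bias for immunity
  to the singular-mode trap; at very small $n$ (tens of persons) the bias
  is visible in $\tau_\phi$.
- iCV on log scale is sign-unstable for tasks whose mean log-RT crosses
  zero; the package flags rather than reinterprets such cases.
- The generator's missingness is completely at random within the scanned
  subset, which matches the two-stage design but not attrition mechanisms
  that correlate with performance.
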