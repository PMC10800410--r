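---
title: "A two-level AR(1) model for experience-sampled stress and affect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-level AR(1) model for experience-sampled stress and affect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emadsem)
```

## The design and the data model

`emadsem` analyzes intensive longitudinal data from a fixed experience-sampling
schedule: three prompts per day (10:00, 16:00, 22:00) over 21 days, so 63
design occasions per person. Each prompt records momentary stress (a single
1-5 item), and negative and positive affect (10-item PANAS subscale means,
1-5). Trait resilience (15-item scale, 1-5) and trait loneliness (20-item
UCLA scale, 1-4 by default) are measured twice (first and last day) and
treated as stable person-level covariates, scored with `score_likert_scale()`
and combined by `make_trait_table()` as the mean of the two waves — justified
by their high retest reliability, which `retest_reliability()` estimates.

The three daily prompts are 6, 6 and 12 hours apart. `align_time_grid()`
places them on an equally spaced latent grid with a 6-hour unit — the
smallest unit that makes all design gaps integral. One phantom (never
observable) cell at the 04:00 position per night turns the overnight gap into
two unit steps, so each person spans 83 grid cells: 63 observable, 20
phantom. Phantom cells carry no observation likelihood; they exist only as
latent states so that the lag-1 autoregression always refers to a 6-hour
step. Prompts answered late are anchored to their nominal slot; the package
does no calendar arithmetic beyond this fixed schedule.

## The model

Write $y_{ti}$ for the outcome affect (negative affect in the primary
specification; `dsem_spec("pa")` swaps the two affects), $s_{ti}$ for
momentary stress and $p_{ti}$ for the opposite affect. Each time-varying
variable decomposes into a *latent* person mean plus an occasion deviation —
latent person-mean centering, estimated jointly rather than by observed
averages, so that the between-level regression on a person's typical stress
is not attenuated by sampling error in the observed mean:

$$y_{ti} = \alpha_i + d_{ti}, \qquad
  s_{ti} = \mu^{s}_i + s^c_{ti}, \qquad
  p_{ti} = \mu^{p}_i + p^c_{ti}.$$

Within person, the outcome deviation follows an AR(1) with concurrent
covariate deviations,

$$d_{ti} = \phi_i\, d_{(t-1)i} + \beta_i\, s^c_{ti} + \eta_i\, p^c_{ti}
  + e_{ti}, \qquad e_{ti} \sim N(0, \sigma^2_e),$$

and the centered covariate deviations are white noise,
$s^c_{ti} \sim N(0, \sigma^2_{str})$, $p^c_{ti} \sim N(0, \sigma^2_{cov})$:
the model assigns dynamics only to the outcome, the minimal structure
consistent with the between/within decomposition (a toggle for covariances
between the covariate deviations is deliberately not provided; they are
independent by assumption).

Between persons, the six person parameters are regressed on grand-mean
centered traits and on the centered latent means:

$$\alpha_i = \gamma_{00} + \gamma_{01}\mathrm{RES}^c_i
  + \gamma_{02}\mathrm{LON}^c_i + \gamma_{03}(\mu^s_i - \gamma_{40})
  + \gamma_{04}(\mu^p_i - \gamma_{50}) + u_{0i},$$

$\phi_i, \beta_i, \eta_i$ each on $(1, \mathrm{RES}^c, \mathrm{LON}^c)$ with
residuals $u_{1i}, u_{2i}, u_{3i}$, and $\mu^s_i = \gamma_{40} + u_{4i}$,
$\mu^p_i = \gamma_{50} + u_{5i}$. So $\gamma_{10}$ is the population mean
emotional inertia, $\gamma_{03}$ the coupling of a person's baseline affect
to their typical stress level, and $\gamma_{11}$, $\gamma_{21}$ the
cross-level moderation of inertia and stress reactivity by resilience.

### The random-effect covariance is block-structured, not free

The residuals $u_{0i},\dots,u_{5i}$ are jointly normal. Their covariance
cannot be a free 6x6 matrix: $\alpha$ is *regressed* on the latent means, so
a free covariance between $u_0$ and $u_4$ (or $u_5$) would explain exactly
the same second moment as $\gamma_{03}$ (or $\gamma_{04}$) — the pair is
unidentified, and in practice the sampler then drifts through compensating
($\gamma_{03}$, $\tau_{00}$) configurations with inflated intercept variance.
`fit_dsem()` therefore uses the standard path-model constraint: a free 4x4
covariance among the regression residuals $(u_0, u_1, u_2, u_3)$, a free 2x2
covariance between the latent-mean deviations $(u_4, u_5)$, and structural
zeros across the two blocks. `tau_structure = "diagonal"` restricts further
to independent effects and is faster mixing on small data.

## Estimation

`fit_dsem()` runs a Gibbs sampler with data augmentation. All person-level
updates are vectorized across persons (closed-form 2x2/3x3 posterior
Cholesky factors on vectors), so a chain iteration on the full 88 x 83
design costs a few milliseconds in plain R. One iteration cycles:

1. **Missing and phantom cells.** Fully missing cells (phantoms and
   unanswered prompts) get a joint draw: the covariate deviations
   $(s^c_t, p^c_t)$ from their exact bivariate conditional given the
   neighboring outcome deviations — marginalizing $d_t$, the next transition
   contributes $d_{t+1} - \phi^2 d_{t-1} - c_{t+1} =
   \phi(\beta s^c_t + \eta p^c_t) + \varepsilon$ with
   $\mathrm{Var}(\varepsilon) = \sigma^2_e(1+\phi^2)$ — and then $d_t$ from
   its AR(1) conditional given both neighbors. Note the outcome *does* feed
   back into the covariate imputation; dropping that term (imputing from the
   white-noise prior alone) is not a valid conditional and measurably biases
   the autoregression when couplings are large relative to the residual
   variance. At the series end the conditional reduces to the white-noise
   prior. Cells where only a covariate is missing but the outcome is
   observed (absent under record-level nonresponse) use the prior draw; with
   the small estimated couplings the neglected feedback there is negligible.
   Updates sweep even and odd grid positions alternately, which makes the
   cells within a half-sweep conditionally independent and the whole sweep
   vectorizable. The pre-first deviation is drawn from its stationary
   conditional $N(0, \sigma^2_w/(1-\phi_i^2))$ combined with the first
   transition, with $\phi_i$ clipped to $(-0.995, 0.995)$ inside this
   formula only — the sampler places no stationarity truncation on
   $\phi_i$ draws themselves.

2. **Person parameters.** The exact joint conditional of all six person
   parameters is not Gaussian (the likelihood is bilinear in
   $\phi_i \alpha_i$, $\beta_i \mu^s_i$, $\eta_i \mu^p_i$), so they are
   drawn in three exactly conjugate sub-blocks: $(\alpha_i, \beta_i,
   \eta_i)$, then $\phi_i$, then $(\mu^s_i, \mu^p_i)$, each conditioned on
   the others through the Gaussian conditionals of the joint MVN prior
   implied by $(\Gamma, \mathrm{T})$. The latent-mean block pools three
   information sources: the covariate observations, the outcome equation
   (through $-\beta_i \mu^s_i - \eta_i \mu^p_i$), and the between-level
   prior.

3. **Between-level coefficients.** All 16 coefficients are drawn in one
   exact conjugate MVN via generalized least squares. Linearity comes from
   reparametrizing the intercept as $\gamma_{00}^{*} = \gamma_{00} -
   \gamma_{03}\gamma_{40} - \gamma_{04}\gamma_{50}$ with uncentered latent
   means as predictors; the centered-model $\gamma_{00}$ is recovered per
   draw. The $N(0, 10^6)$ prior sits on $\gamma_{00}^{*}$ rather than
   $\gamma_{00}$, a negligible difference at that variance.

4. **Covariances and variances.** The two covariance blocks from
   inverse-Wisharts, the three within variances from inverse-gammas.

One knowing approximation remains: the stationary prior of the pre-first
deviation depends on $(\phi_i, \beta_i, \eta_i, \sigma^2)$, and that single
pseudo-datum (one of 84 per person) is ignored when those parameters are
updated, keeping the coefficient blocks conjugate. This is standard practice
and immaterial at 63 observed occasions.

### Priors, defaults and tuning parameters

* Coefficients: $N(0, 10^6)$, essentially flat (configurable via
  `dsem_priors()`).
* Random-effect covariance blocks: inverse-Wishart with scale $0.1 I$ and
  degrees of freedom 6 (4x4 block) and 4 (2x2 block) — the `tau_df = 8`
  default is quoted for the nominal 6-dimensional problem and split
  accordingly. Weakly informative: prior mean $0.1 I$, about as heavy as 8
  pseudo-persons against the 88 observed.
* Within variances: inverse-gamma(0.001, 0.001).
* Chains: the 50,000-iteration budget is read as 2 chains x 25,000 with 50%
  burn-in (`mcmc_config()` defaults); the acceptance and test runs use 2 x
  4,500 with 1,500 burn-in, which already yields potential scale reductions
  near 1.00 on this model — stated as this package's choice of problem size
  for routine verification.
* Convergence: Gelman-Rubin potential scale reduction per monitored scalar,
  threshold 1.1; a non-convergent fit carries a warning, never a silent
  flag. Singular conditionals fall back to a logged 1e-8 jitter
  (`fit$n_jitter`).
* Posterior summaries: medians and equal-tailed 95% intervals with the
  linear-interpolation (type-7) percentile convention.

## The synthetic-data generator

`simulate_study()` forward-simulates the full generative model, and its
defaults *are* the study conditions: 88 persons, 63 observable occasions on
the 83-cell grid, 10.2% record-level missingness, trait composites drawn
from N(3.13, 0.60^2) (resilience, clipped to 1-5) and N(2.26, 0.55^2)
(loneliness, clipped to 1-4; clipping is logged when it occurs). The
generating parameters default to the reported posterior medians of the
negative-affect model (`default_dsem_params("na")`), with two choices the
report leaves open:

* The off-diagonal random-effect covariances are not reported, so the
  default `tau` is diagonal (the estimator still fits the block covariance).
* The within variances of the centered stress and opposite-affect deviations
  are not reported; on the standardized scale of the reported estimates the
  natural unit is 1.0, and this choice reproduces the reported within-level
  variance explained to within 0.02 (implied 0.33 vs 0.35 reported).

Missingness is record-level MCAR, matching a design that reports only an
overall response rate; the rate is configurable for sensitivity studies.
Generator mode requires a stationary AR coefficient for every person
(`|gamma10| + 2*sqrt(tau11) < 1` at the parameter level); the rare person
whose Gaussian tail draw still crosses 1 has their random-effect vector
redrawn, a negligible truncation under the enforced margin. Simulation at
every grid cell followed by phantom deletion leaves the observed-process law
identical to direct unequal-interval simulation, which the tests check
through lag-4 dependence ($\phi^4$).

What the generator does **not** emulate: item-level responses with realistic
factor structure (scale scores are simulated directly; item-level inputs for
the scoring module are exercised with i.i.d. noise in the tests), floor/
ceiling effects and discreteness of Likert responses, diurnal cycles,
response-time-dependent missingness, or attrition mechanisms beyond MCAR.
Passing recovery tests therefore show the estimator is correct for this
generative law, not that the substantive findings would replicate under
realistic measurement artifacts.

## Post-estimation

* `standardize_estimates()` standardizes slopes per draw as
  `coefficient * SD(predictor) / SD(outcome)`: within-level slopes with the
  model-implied within SDs per person, averaged over persons (the lag slope
  standardizes to itself); between-level slopes with the person SDs of the
  predicted effect and its predictor in that draw. Intercepts are reported
  unstandardized. The exact scheme behind the published standardized table
  is not described in the source report; this one is documented here and not
  claimed to be numerically identical to any particular software's.
* `compute_r2()`: within, $1 - \sigma^2_e/\bar v$ with $\bar v$ the
  person-averaged model-implied within variance
  $(\sigma^2_e + \beta_i^2\sigma^2_{str} + \eta_i^2\sigma^2_{cov})/(1-\phi_i^2)$;
  between, $1 - \tau_{00}/\mathrm{Var}(\alpha_i)$, both per draw, summarized
  by posterior medians.
* `ci_interval_95()` renders the normal-range statement
  $\gamma_{00} \pm 1.96\sqrt{\tau_{00}}$ for person intercepts;
  `response_rate()` is the design-accounting arithmetic.
* `render_table2()` lays the 25 summary rows (16 coefficients, 6 variances,
  residual variance, two R-squared rows) out in the fixed row order, two
  decimals for display with machine-precision columns preserved.
* The two affect models are separate symmetric fits rendered jointly; there
  is no joint bivariate estimation.

## Numerical and design choices worth knowing

* Degenerate descriptive statistics (zero-variance correlations) are
  reported `NA`, never 0.
* CSV round-trips are bit-exact: scores are written with 17 significant
  digits and parsed with `strtod` rather than the reader's fast path.
* Posterior contraction in the series length follows the $1/\sqrt{nT}$ law:
  doubling the number of occasions shrinks the posterior SD of the mean
  autoregression by about $\sqrt 2$ (the tests assert this rate), not by
  half, and with heterogeneous inertia ($\tau_{11} > 0$) the between-person
  term sets a floor that longer series cannot remove.
* Exclusion of persons above the 60% missing-occasion threshold mirrors the
  study's retention rule and is opt-in (`exclude_flagged()`,
  `exclude_high_missing` in `fit_dsem()`), so the generator's attrition
  arithmetic remains testable.
* The UCLA response range is configurable (`ucla_spec(range = c(1, 5))`)
  because published descriptions of the instrument's format conflict; the
  default is the conventional 1-4. The reverse-scored set is likewise
  configuration, defaulting to the conventional 9 non-lonely items.

## Limitations

Estimates are only as exact as the chain is long; the defaults are sized for
this design and should be raised for larger panels. The white-noise
covariate model ignores any autocorrelation in stress itself; if stress is
strongly inertial, its person mean is still consistently estimated but the
within-level slope mixes concurrent and carried-over influence. Measurement
error in the scale scores is not modeled. MCAR is an assumption, not a
finding — the validity of the missing-data handling under prompt-level
nonresponse that depends on momentary state is untested by design.
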