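---
title: "Sequential-modeling multiple imputation for two-level models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential-modeling multiple imputation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcmi)
```

## The problem

Consider a two-level model for unit $i$ in cluster $j$ in which an outcome
$y$ depends on a level-1 explanatory variable $x$ and a level-2 variable
$z$ through nonlinear terms — a random slope, a cross-level interaction,
cluster-mean-centered effects, or polynomials:

$$y_{ij} = \beta_0 + \beta_1 (x_{ij} - \bar x_{\bullet j}) + \beta_2 \bar
x_{\bullet j} + \beta_3 z_j + \beta_4 (x_{ij} - \bar x_{\bullet j}) z_j +
\beta_5 \bar x_{\bullet j} z_j + u_{0j} + u_{1j} (x_{ij} - \bar x_{\bullet
j}) + e_{ij}.$$

If $x$ has missing values, a valid imputation model must reproduce the
conditional distribution of $x$ given $y$ and $z$ *implied by this
analysis model*. That distribution is not normal and not linear in $y$;
joint multivariate-normal imputation or a reversed conditional model
therefore biases $\beta$ and the slope variance $\tau_1^2$ even under MAR.

## The sequential factorization

`smcmi` specifies the joint distribution as a chain of conditional
univariate models ending in the substantive model:

$$g(y, \mathbf{x}; \gamma) \;=\; g_y(y \mid \mathbf{x}; \gamma_y)
\prod_{p=1}^{P} g_{x_p}(x_p \mid x_1, \ldots, x_{p-1}; \gamma_{x_p}).$$

Each covariate model conditions only on variables placed *earlier* in the
sequence (a triangular structure that `sequenceSpec()` enforces), and each
is either a normal multilevel model with random effects (level-1 variables)
or a normal regression at one row per cluster (level-2 variables).
Imputations drawn under this factorization are compatible with the analysis
model because $g_y$ *is* the analysis model (or nests it).

When the user does not fix the order, `defaultSequence()` places level-2
variables before level-1 variables and, within a level, orders by ascending
percentage of missing data. Models for cluster-level variables are harder
to estimate than models for level-1 variables, and placing better-observed
variables early confines the influence of any misspecified conditional
model to positions where less unexplained variation remains.

## The sampler

Each iteration of `smcImpute()`:

1. **Parameter updates.** Every model in the sequence is updated by exact
   conjugate full conditionals given the current completed data: fixed
   coefficients (multivariate normal), cluster effects $u_j$ per cluster
   (multivariate normal; vectorized closed forms for dimensions 1 and 2),
   residual variance (inverse gamma), random-effect covariance
   (inverse Wishart). Random effects are carried explicitly (data
   augmentation) rather than integrated out, which keeps every update in
   closed form.
2. **Imputation steps.** For every incomplete variable $q$ and every
   cluster $j$ with missing cells, proposals $z^*_{ijq} \sim
   N(z^{(t-1)}_{ijq}, \tau^2_{z_{ijq}})$ are drawn for the *missing* cells
   only (observed cells are never perturbed), and the MH ratio

   $$M_{jq} = \frac{L_q(\mathbf z^*_{jq} \mid \mathbf z_{j(-q)},
   \gamma)}{L_q(\mathbf z^{(t-1)}_{jq} \mid \mathbf z_{j(-q)}, \gamma)}$$

   is evaluated over the product of (a) $q$'s own conditional model,
   (b) every later model in which $q$ appears as a predictor — directly or
   through a derived term — and (c) the outcome model. All derived terms
   involving $q$ (cluster means, deviations, interactions, powers) are
   recomputed under the proposal first. The whole cluster's proposal is
   accepted with probability $\min(M_{jq}, 1)$, jointly for all its cells:
   with manifest cluster means in the model, changing one cell moves the
   mean and hence the posterior of every other cell in the cluster, so
   cell-wise acceptance would target the wrong distribution. A level-2
   variable receives a single proposed value per cluster.

After `burnIn` iterations, a completed dataset is saved every `nBetween`
iterations until `m` exist. With no missing cells the engine reduces to
pure Bayesian estimation and returns `m` copies of the input.

**Proposal adaptation.** Initial scales are half the observed-cell SD of
the variable; during burn-in a Robbins–Monro-style multiplier per
(variable, cluster) steers acceptance into a target band ([0.3, 0.6] by
default), and the scales are frozen at the end of burn-in so the sampling
phase is a valid fixed-kernel chain. `adaptProposals()` warns and does
nothing if called frozen.

**Priors.** Coefficients are flat; residual variances are inverse-gamma
$(10^{-3}, 10^{-3})$; the random-effect covariance is inverse-Wishart with
$\dim + 1$ degrees of freedom and scale $10^{-3} I$. These are weakly
informative conjugate defaults; all are exposed through `defaultPriors()`
and the config schema. The covariance is sampled as a full matrix even when
a generator sets the intercept–slope covariance to zero, because the
analysis model estimates it.

**Initialization and degenerate inputs.** Missing cells start from normal
draws with the observed-cell mean and SD (one draw per cluster for level-2
variables); a fully missing column is an error. Start values for the model
parameters come from least squares on the initialized data. Singleton
clusters are allowed — their $u_j$ conditional stays proper under the
prior. A level-2 variable must be missing for all rows of a cluster or
none; partial within-cluster missingness of a cluster-constant variable is
rejected at load time, as is any within-cluster variation in its observed
cells.

**Diagnostics.** The engine records the outcome-model parameter chain after
burn-in and reports split-chain $\hat R$ per parameter plus per-variable
mean MH acceptance rates. Non-convergence is reported, never fatal.
`rhat()` implements the textbook between/within ratio for externally
supplied chains from independently seeded runs.

## Analysis and pooling

`fitSubstantive()` fits the declared mixed model with `lme4` under ML
(REML available). ML is the default for comparability across software and
because the pooled quantities are coefficients and their large-sample
variances. Rows with any missing model variable are excluded *before*
cluster means are computed, so the same function on incomplete data is the
listwise-deletion comparator. Singular or non-converged fits are flagged,
not raised.

`rubinPool()` combines estimates as $\bar Q$ = mean, $T = \bar U + (1 +
1/m) B$, with Rubin's degrees of freedom under the Barnard–Rubin
small-sample adjustment. The complete-data degrees of freedom default to
(number of clusters − number of fixed effects), a conservative choice for
quantities that vary at the cluster level; it is configurable. When the
between-imputation variance vanishes the degrees of freedom tend to
$\nu_{com}(\nu_{com}+1)/(\nu_{com}+3)$ — the Barnard–Rubin observed-data
limit, slightly below $\nu_{com}$ itself. Intervals are symmetric about
$\bar Q$ on the $t$ scale, and `poolFits()` drops non-converged fits (with
a flag when more than 20% drop) and averages variance components across
imputations for reporting.

## What the generators emulate

`studyDesign()` encodes three data-generating processes with unit-variance
variables and a fixed slope variance $\tau_1^2 = .10$ with uncorrelated
random effects:

1. **Conflated random-coefficients design.** $x = x^{L2} + x^{L1}$ with
   $\mathrm{Var}(x^{L2}) = \rho_{Ix}$; $z$ standard normal at level 2;
   level-2 components bivariate normal with $\mathrm{Cor}(x, z) = .20$;
   outcome $y = \beta_1 x + \beta_2 z + \beta_3 xz + u_{0j} + u_{1j} x +
   e_{ij}$ with effects (.40, .20, .20).
2. **Centered design.** Same covariates; the outcome decomposes $x$ into
   manifest cluster means and deviations with effects (.40, 0, .20, .20, 0)
   and the random slope on the deviation.
3. **Quadratic design.** $z$ standard normal; $x^{L2} = \phi_0 + \phi_1 z +
   \phi_2 z^2 + \epsilon$, with $\phi$ calibrated so $x$ has mean zero, the
   linear and quadratic parts contribute fractions $(1-w, w)$ of a total
   $R^2_{xz} = .50$, and $\mathrm{Var}(x) = 1$; outcome with linear,
   interaction and quadratic effects, all .15.

Missingness is induced in $x$ through a latent propensity $r = \lambda_0 +
\lambda_1 y + v$, $v \sim N(0, 1 - \lambda_1^2)$, deleting where $r > 0$:
$\lambda_0$ is the standard-normal quantile of the target proportion
(30% by default) and $\lambda_1 \in \{0, .35, .70\}$ spans MCAR to strong
MAR. $y$ is always complete.

Two calibration conflicts in the quadratic design were resolved as package
design choices:

* **Residual split of x.** Taking $R^2_{xz}$ literally as a fraction of the
  level-2 variance would give $\mathrm{Cor}(x, z) = \sqrt{\rho_{Ix}
  R^2_{xz}} \approx .32$ at $w = 0$, not the intended ceiling of about .7.
  The generator instead treats $R^2_{xz}$ as a fraction of the *total* unit
  variance of $x$ and shrinks the two residual components — the level-2
  disturbance $\rho_{Ix}(1 - R^2_{xz})$ and the level-1 part
  $(1 - \rho_{Ix})$ — proportionally so the total stays 1. The consequence
  is that the realized ICC of $x$ in this design exceeds the nominal
  $\rho_{Ix}$ (it is $R^2 + \mathrm{Var}(\epsilon) \approx .56$); the
  correlation range 0–.7 across $w$, which identifies the design, is exact.
* **ICC of y.** With those covariates the systematic between-cluster
  variance of $y$ is about .35 at the default coefficients, so an ICC of
  .20 cannot coexist with unit total variance.
  `calibrateOutcomeVariances()` keeps the ICC as the binding target: the
  total variance of $y$ scales up to $V_2/\rho_{Iy}$ with $\tau_0^2 = 0$.
  Because $y$ then has a nonzero mean (≈ .4, from the quadratic terms) and
  variance above 1, `effectiveLambda0()` rescales the propensity intercept
  so the marginal missing proportion still equals
  $\Phi(\lambda_0)$. The linear designs keep the literal quantile (their
  deviation is below one percentage point) and solve the
  ICC/unit-variance system in closed form from normal product moments; the
  quadratic design evaluates its variance decomposition by a fixed-seed
  Monte Carlo draw of $4 \times 10^5$ cluster-level components, which is
  deterministic and leaves the caller's RNG stream untouched.

The generators emulate the validated designs' correlation structure,
variance decomposition and missingness mechanism. They do not emulate
non-normal level-1 noise, unbalanced cluster sizes, categorical variables
or MNAR selection, so passing tests speak to the estimator's behaviour
under the stated normal-theory conditions, not to robustness beyond them.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `burnIn` | 2000 | iterations before the first save; adaptation window |
| `nBetween` | 100 | iterations between saved datasets |
| `m` | 10 | number of imputations |
| `adaptBand` | (0.3, 0.6) | target MH acceptance band during burn-in |
| `adaptEvery` | 50 | iterations per adaptation window |
| priors | see above | conjugate hyperparameters |

The burn-in and spacing defaults are deliberately generous for routine use;
the validated designs converge well within them. Harder posteriors — e.g.
strong MAR combined with quadratic terms, where the conditional density of
a missing cell can be bimodal — profit from longer burn-in, which is why
the test suite uses 1500 burn-in iterations for the quadratic design.

## Problem sizes used in the test suite

Full-scale Monte Carlo grids (1000 replications at up to $J = 1000$) are
not desk-scale; the suite exercises the same claims at sizes chosen to keep
a full run within minutes while leaving the Monte Carlo error quantifiable
(it is always reported alongside the estimate):

* coverage of the cross-level-interaction interval, MCAR, ICC .20:
  $J = 100$, $n = 10$, 200 replications, chains 500 + 10×25;
* bias bounds in the quadratic design under MAR ($\lambda_1 = .70$):
  $J = 120$, $n = 20$, 20 replications per nonlinear weight
  $w \in \{.25, .5, .75, 1\}$, chains 1500 + 10×25;
* generator moment checks at $10^5$–$10^6$ rows; the conjugate-posterior,
  stationary-distribution (grid-normalized Kolmogorov–Smirnov at a fixed
  kernel), pooling and recovery properties on small fixtures.

## Known limitations

* Conditional models are normal linear models; categorical/ordinal
  variables, heteroscedastic level-1 variances and non-normal residuals
  are not supported.
* Two levels only; no cross-classification; latent (rather than manifest)
  cluster means are not implemented.
* $\hat R$ from a single run uses split chains; fully independent
  replicate chains must be run explicitly and combined via `rhat()`.
* The missingness machinery targets explanatory variables; an incomplete
  outcome is handled by its own (final) model but has no dedicated
  machinery beyond that.
* MNAR selection or pattern-mixture extensions are out of scope.
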