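# smcmi — substantive-model-compatible multiple imputation for two-level data

Multilevel analyses routinely include *nonlinear* effects of explanatory
variables: random slopes, cross-level interactions, cluster-mean-centered
effects, quadratic terms. When such an explanatory variable has missing
values, conventional multilevel imputation (joint multivariate-normal models,
or "reversed" fully conditional specification) imputes under a model that
contradicts the analysis model, and the resulting estimates — especially
interaction coefficients and slope variances — can be badly biased even
under MAR.

`smcmi` implements a **sequential modeling** approach to multilevel multiple
imputation. The joint distribution of outcome *y* and explanatory variables
*x*₁, …, *x*_P is factorized into a chain of conditional univariate models,

g(y, x; γ) = g_y(y | x; γ_y) · ∏ₚ g_{x_p}(x_p | x₁, …, x_{p−1}; γ_{x_p}),

with the substantive analysis model itself (or an extension of it) as
g_y. Imputations drawn from this factorization are *compatible* with the
intended analysis by construction. Each conditional model is a normal
multilevel model (level-1 variables; random effects carried by data
augmentation) or a normal regression at the cluster level (level-2
variables).

Parameters are updated by exact conjugate Gibbs steps. Replacements for the
missing cells of variable *q* in cluster *j* are drawn by a random-walk
Metropolis–Hastings step whose ratio

M_jq = L_q(z*_jq | z_j(−q), γ) / L_q(z_jq | z_j(−q), γ)

is evaluated **at the cluster level**, jointly accepting or rejecting the
proposals for all units of the cluster: since the analysis model may contain
manifest cluster means of *x*, imputing one unit's value moves the cluster
mean and changes the posterior of every other value in the cluster. All
derived terms (cluster means, deviations, interactions, powers) are
recomputed under the proposal before the ratio is evaluated. Proposal
scales adapt per (variable, cluster) toward a target acceptance band during
burn-in and are frozen afterwards, so the sampling phase is a fixed-kernel
chain.

The *m* completed datasets are analyzed by maximum likelihood (`lme4`) and
combined by Rubin's rules with Barnard–Rubin adjusted degrees of freedom. A
simulation harness implements three reference Monte Carlo designs (conflated random-coefficient model; cluster-mean-centered
model; quadratic model with a nonlinear covariate–covariate association)
together with the latent-propensity MAR mechanism, and reports relative
bias, RMSE and coverage with Monte Carlo errors.

## Worked example

Generate one dataset from the random-coefficients design (J = 60 clusters of
n = 10; unit-variance x, y; effects .40/.20/.20; slope variance .10), delete
30% of x through a propensity that increases with y (MAR), impute, and pool:

```r
library(smcmi)

d <- studyDesign(1, n = 10, J = 60)
set.seed(42)
dat <- genOutcome(d, genCovariates(d))
inc <- induceMissing(dat, "x", lambda0 = qnorm(0.30), lambda1 = 0.7)
inc
#> Two-level dataset: 600 rows, 60 clusters
#>   level pct.missing
#> x     1        31.3
#> z     2         0.0
#> y     1         0.0

seqn <- defaultSequence(inc, substantiveModel(d), list(x = covariateModel(d)))
imp  <- smcImpute(inc, seqn, burnIn = 1000, nBetween = 50, m = 10, seed = 7)
imp
#> Imputation set: 10 completed datasets
#> mean MH acceptance: x=0.47
#> max split-chain Rhat: 1.15

fits <- lapply(1:10, function(k)
  fitSubstantive(completedData(imp, k), substantiveModel(d)))
poolFits(fits)
#> Pooled estimates (m = 10 imputations)
#>             estimate     se      df ciLower ciUpper
#> (Intercept)  -0.0152 0.0482 41.7320 -0.1125  0.0820
#> x             0.3576 0.0661 42.0890  0.2243  0.4909
#> z             0.0762 0.0445 42.5364 -0.0135  0.1659
#> x:z           0.1511 0.0594 38.6336  0.0309  0.2714
#> variance components (averaged across imputations):
#>   sigma2 tau[1,1] tau[2,1] tau[2,2]
#>   0.5640   0.0495   0.0316   0.1419
```

The pooled coefficients sit near the generating values (.40 for x, .20 for
z and the cross-level interaction x:z; slope variance .10) up to the
sampling noise of a single J = 60 dataset. Listwise deletion on the same
data gives `x = 0.273`, `x:z = 0.125` and a badly shifted intercept
(−0.266) — the MAR selection on y attenuates every coefficient, which the
imputation repairs. `defaultSequence()` orders covariate models level-2
first, then by ascending missingness, and always places the substantive
model last; `imp$rhat` and `imp$acceptance` carry convergence diagnostics.

Model formulas use `cmean(x)` (manifest cluster mean), `wdev(x)`
(within-cluster deviation), `:` products, `x^k` powers and an lme4-style
random part, e.g.

```r
parseFormula("y ~ 1 + wdev(x) + cmean(x) + z + wdev(x):z + cmean(x):z + (1 + wdev(x) | g)")
```

A thin command-line wrapper over the same functions ships in
`inst/cli/smcmi.R` (`impute`, `pool`, `simulate`, `diagnose`, each driven by
a YAML config; see the vignette for the schema).

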