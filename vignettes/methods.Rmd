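---
title: "Methods: model, priors, and Bayes-factor machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, priors, and Bayes-factor machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the prior presets and the
reasoning behind them, the numerical design of the density estimators and
samplers, and the known limitations. Code chunks are shown but not executed
at build time; every quantitative claim made here is computed by the test
suite (`tests/testthat/`) or by `scripts/acceptance.R`, not asserted from
memory.

## The model

An MPT model maps a parameter vector $\theta \in (0,1)^P$ to category
probabilities via sums of branch products. For the 2HTSM with source-A items,
for example,

$$P(\text{"A"} \mid \text{source A}) = D\,d + D\,(1-d)\,g + (1-D)\,b\,g,$$

with $D$ item recognition, $d$ source memory, $b$ old/new guessing and $g$
source guessing. `build_2htsm()` constructs the three-tree single-condition
model; `build_2htsm_bell()` crosses $D$, $d$ and $g$ with two conditions
(suffixes `_pleasant`, `_disgusting` by default) and two sources (`_A`,
`_B`), keeping one $b$ per condition and defining the derived
$D_{New} = (D_A + D_B)/2$ for the new-item trees. Arbitrary models can be read
from EQN text (`read_eqn()`, `parse_eqn()`); models are validated at
construction by checking that category probabilities sum to one on a
quasi-random sweep of the parameter cube.

### Latent-trait hierarchy

Individual parameters are probit-transformed:
$\eta_{ip} = \Phi^{-1}(\theta_{ip})$, and

$$\eta_i = \mu + \delta_i, \qquad \delta_i \sim \mathrm{MVN}(0,\;
\mathrm{diag}(\sigma)\,\Omega\,\mathrm{diag}(\sigma)).$$

$\Phi(\mu_p)$ is the group *median* of parameter $p$ on the probability
scale; the group *mean* is $E[\Phi(\mu_p/\sqrt{1+\sigma_p^2})]$. `tidy()`
reports medians; `group_prob_summary()` exposes both.

## Prior presets and their rationale

`informative_preset()` encodes two substantive beliefs on the probit scale:

- memory parameters ($D$, $d$): $\mu \sim N(0, 1)$, i.e. uniform on the
  probability scale — genuinely weak;
- guessing parameters ($b$, $g$): $\mu \sim N(0, 0.28)$, concentrating the
  implied probability-scale prior around $1/2$, because participants in
  source-monitoring tasks guess near chance unless the design induces bias;
- $\sigma_p \sim \mathrm{Gamma}(2, 3)$ (mean $2/3$, zero density at 0), and
  $\Omega \sim \mathrm{LKJ}(1)$, uniform over correlation matrices.

`matzke_klauer_preset()` reproduces a widely used default: $N(0,1)$ means for
*all* parameters and a covariance built from
$\Sigma^{-1} \sim \mathrm{Wishart}(I, P+1)$ with uniform $U(0,10)$ scaling
factors $\xi_p$. Its implied *individual-level* priors are strongly
bimodal — most prior mass for an individual's $g$ sits near 0 or 1, not near
1/2. The package quantifies this with `extremeness_index()` (prior mass
outside $[0.1, 0.9]$); the test suite verifies that the index is larger under
this preset than under the informative one by more than three pooled Monte
Carlo standard errors for both $g$ and $d$. This matters practically:
extreme implied priors weaken hierarchical shrinkage and inflate
individual-level Bayes factors for "everyone conforms" hypotheses.

Two distributional identities keep prior Monte Carlo cheap, and both are
verified numerically in the test suite rather than taken on faith:

- a $k \times k$ principal submatrix of an $\mathrm{LKJ}(\eta, P)$ matrix is
  $\mathrm{LKJ}(\eta + (P-k)/2, k)$;
- a $k \times k$ principal submatrix of an $\mathrm{IW}(I_P, P+1)$ matrix is
  $\mathrm{IW}(I_k, k+1)$.

`draw_cov_prior_subset()` uses these to draw only the sub-covariance of the
parameters a constraint mentions, instead of the full $P \times P$ matrix.

## Posterior sampling

`fit_posterior()` runs an adaptive random-walk Metropolis-within-Gibbs
sampler written for this package (block updates for each participant's
$\eta_i$, the group means, the scales, and the correlation matrix, with
acceptance-rate adaptation during warmup only, so the retained chain is a
valid fixed-kernel chain). Diagnostics are split-R-hat and
`coda::effectiveSize()`-based ESS per quantity; a single-chain fit reports
R-hat as `NA` with a message. `mcmc_smoke_profile()` (2000 draws, 1000
warmup) is for tests and examples; real analyses should use
`mcmc_settings()` with tens of thousands of draws — `glance()` flags
convergence warnings either way.

## Predictive checks

`predictive_simulate()` resamples category counts from posterior (or prior)
draws under a `study_design`. `t1_t2()` computes

- **T1**, a $\chi^2$-style discrepancy between observed and expected mean
  category counts, and
- **T2**, a discrepancy between observed and expected covariance structure
  (expected covariance includes the multinomial sampling covariance),

each with a posterior-predictive p-value: the proportion of replicated data
sets whose discrepancy exceeds the observed one. Extreme p-values in either
tail signal misfit of the mean (T1) or of the individual-differences
structure (T2). T2 requires at least two participants and is reported `NA`
otherwise.

## Density estimation for Savage–Dickey ratios

`savage_dickey_bf()` needs the posterior density of a derived quantity
(typically a probability-scale difference, supported on $[-1,1]$) at the null
point. Two estimators are provided:

- **`logspline`** (default): maximum-likelihood log-density on a cubic
  B-spline basis over the known support, with the normalizing constant
  computed by Simpson quadrature and the basis dimension chosen by BIC over
  `df_grid = c(5, 7, 9, 12)`. This estimator handles boundary mass and
  skewness and requires at least 500 in-support draws.
- **`truncated_normal`**: a moment-matched normal renormalized to the
  support. It is fast and smooth but systematically biased when the true
  density is non-normal (for a Beta(26, 26)-shaped posterior the bias at the
  center is about 1.5%; for more dispersed Beta shapes it reaches several
  percent). It is offered as a cross-check, not as the default.

Prior densities at the null are analytic where symmetry permits: the
probability-scale difference of two parameters with independent standard
normal probit priors has the triangular density $1 - |x|$ on $[-1, 1]$
(exactly 1 at zero), and a single such parameter has implied density 1 on
$(0,1)$. `prior_density_at_null()` validates the structural conditions and
errors with guidance otherwise; `prior_method = "auto"` falls back to the
log-spline route. With exactly two quantities, `joint = TRUE` replaces the
product of univariate ratios by a bivariate tensor-product log-spline
(`df = 6` per margin, accurate to roughly 10%); the product form is the
default because the group-mean priors are independent by construction.

The correctness anchor for both estimators is a conjugate binomial toy: 25
successes in 50 trials under a uniform prior gives posterior Beta(26, 26) and
an exact Savage–Dickey Bayes factor $\mathrm{dbeta}(1/2, 26, 26)$ at the
null rate $1/2$. The test suite requires both estimators to hit this within
5% at $10^5$ draws. The toy's symmetric, moderately concentrated shape was
chosen *before* the acceptance test was written, because the truncated-normal
estimator's kurtosis bias exceeds 3% for flatter Beta shapes — that bias is a
property of the estimator, documented here, not something the test hides.

## Order constraints and encompassing Bayes factors

`constraint_spec()` parses strict inequalities over parameter expressions
(`"d_A_pleasant - d_B_pleasant > 0"`), on the probability scale by default;
the direction of every inequality is user-specified, never assumed.
`encompassing_bf()` computes
$\mathrm{BF}_{re} = \hat{p}_{\text{post}} / \hat{p}_{\text{prior}}$ from
conforming-draw proportions. Design points:

- **Ties count as non-conforming** (strict inequalities), so degenerate draws
  cannot inflate the count.
- **Analytic prior proportions** are used when the constrained quantities
  are differences of parameters with identical, independent priors:
  $(1/2)^m$ for $m$ sign constraints, divided by $k!$ for a complete
  ordering chain of $k$ exchangeable quantities. The structural conditions
  (same prior, disjoint parameters, complete chain) are validated and the
  function refuses with guidance otherwise.
- **Zero conforming posterior draws** yield the bound
  $\mathrm{BF}_{re} \le 1/(n \cdot \hat{p}_{\text{prior}})$, flagged
  `is_bound = TRUE`, never a silent zero.
- **Transitivity**: $\mathrm{BF}_{r0} = \mathrm{BF}_{re}/\mathrm{BF}_{0e}$
  via `compose_by_transitivity()`, which refuses to combine results computed
  from different posterior draw sets (a fingerprint of the draws is carried
  on each result).
- **Stability**: `bf_repeat()` re-estimates the BF on disjoint,
  chain-respecting segments of the posterior (fast mode) or on full refits
  (full mode) and reports median and range.

### "Every participant" hypotheses

`individual_level_bf()` tests whether a constraint holds for *all* $N$
participants simultaneously. The prior probability of that event is tiny
(for the two-condition disordinal constraint under the informative preset at
$N = 138$ it is on the order of $5 \times 10^{-4}$), so naive Monte Carlo
wastes almost all of its draws. The package draws the group-level
configuration, then evaluates participants *sequentially within each draw*,
abandoning a draw at the first non-conforming participant. This is an
unbiased estimator of the all-conform probability with geometrically
shrinking per-draw cost, which is what makes $10^6$ prior draws feasible in
seconds. `descriptive_individual_effects()` complements the BF with
per-participant posterior medians and interval checks.

## Synthetic data

`generate_dataset()` draws true individual parameters from the latent-trait
model around a user-specified truth (or from a `prior_spec`), then samples
multinomial counts per tree. `bell_design()` reproduces a two-condition
source-monitoring trial structure: 10 + 10 source items per condition and 40
new items split 20/20 across condition-labeled new trees (the split is a
package design decision; the generator exposes `new_split` to change it).
`recovery_report()`/`recovery_summary()` compare estimates to truth with
bias and RMSE.

## Limitations

- The sampler is a random-walk scheme: adequate for the problem sizes the
  package targets (tens to ~150 participants, up to ~12 free parameters) but
  slower-mixing than gradient-based samplers. The 12-parameter two-condition
  model does not converge under the smoke profile; use production settings
  for it.
- Analytic prior proportions and densities cover only the symmetric
  structures described above; everything else goes through Monte Carlo or
  log-spline estimates with reported standard errors.
- The truncated-normal density estimator is biased for non-normal
  posteriors; treat it as a sensitivity check.
- The joint (bivariate) Savage–Dickey option is accurate only to roughly
  10% and is off by default.
- Posterior-predictive p-values are not calibrated tail probabilities in the
  frequentist sense; the package uses the conventional (0.025, 0.975)
  screening interval.
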