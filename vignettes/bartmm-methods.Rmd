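---
title: "Semiparametric regression with trees and multilevel structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiparametric regression with trees and multilevel structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bartmm)
```

## The model

`bartmm` fits the semiparametric multilevel regression

$$
Y_i \mid \beta, \lambda, T, M
  = x_i^\beta \beta + f(x_i, z_i; T, M) + w_i \lambda + \epsilon_i,
\qquad
\lambda \sim N(0, \Sigma_\lambda),
\qquad
\epsilon_i \sim N(0, \sigma^2),
$$

the stan4bart model class: a parametric linear term $x^\beta\beta$, a
sum-of-trees ensemble $f(x, z; T, M) = \sum_{j=1}^m g(x, z; T_j, M_j)$
(BART: each $T_j$ is a binary tree of axis-aligned splits, each $M_j$ its
leaf constants), and multilevel group effects $w\lambda$ — varying
intercepts and/or varying slopes for one or more grouping factors, with
$\Sigma_\lambda$ block-diagonal over factors. A covariate may appear in both
the parametric and the tree component; their sum remains identified even
when the components individually are not, and the over-parameterization acts
as parameter expansion for the Gibbs sampler.

The global intercept is eliminated: a continuous response is rescaled
affinely onto $[-0.5, 0.5]$, the ensemble prior is centered at zero, and the
parametric columns are mean-centered, so the response centering absorbs the
intercept. Binary outcomes use the probit latent-variable construction: a
latent $Y^\ast \sim N(\text{fit}, 1)$ truncated to agree with the observed
class, with $\sigma \equiv 1$.

### Priors

* Trees: a node at depth $d$ splits with probability
  $\alpha (1 + d)^{-\beta_d}$, defaults $\alpha = 0.95$, $\beta_d = 2$, with
  the split variable and cutpoint uniform over the available grid. Leaf
  values are $N(0, \sigma_\mu^2)$ with
  $\sigma_\mu = 0.5 / (k \sqrt m)$, $k = 2$, so $\pm k$ prior standard
  deviations of the ensemble sum span the rescaled response range. The
  residual variance (standalone-ensemble mode only) has a scaled-inverse-
  $\chi^2(\nu, \lambda_{cal})$ prior with $\nu = 3$ and $\lambda_{cal}$
  solving $\Pr(\sigma < \hat\sigma) = 0.9$ at an initial residual-sd
  estimate. $m = 200$ trees by default; the replicated studies in this
  package use $m = 50$, which the BART literature reports as typically
  sufficient. These are the canonical constants of the BART literature; the
  model class fixes the prior's *roles* but not its constants.
* Parametric block: $\beta_j \sim N(0, (2.5\, \mathrm{sd}(y) /
  \mathrm{sd}(x_j))^2)$ (weakly informative, autoscaled), $\sigma$ and the
  group standard deviations Exponential with rate $1/\mathrm{sd}(y)$ on the
  model scale, and each correlation matrix LKJ with shape 1 (uniform over
  valid correlation matrices; shapes above 1 concentrate on the identity).
  $\Sigma_\lambda$ is handled through the $\Sigma = DCD$ decomposition:
  $D$ diagonal standard deviations, $C$ a correlation matrix kept as its
  Cholesky factor, parameterized by tanh-transformed canonical partial
  correlations on the unconstrained scale. Group effects are non-centered
  ($\lambda_g = D L \eta_g$, $\eta_g \sim N(0, I)$), which the sampler needs
  when groups carry little data; the posterior is unchanged.

## The sampler

The two blocks alternate in a Gibbs cycle. Each iteration:

1. (probit only) redraw the latent response given the full current fit;
2. collect the current tree predictions and hand them to the parametric
   block as a fixed offset; draw $(\beta, \lambda, \sigma, \Sigma_\lambda)$
   jointly with one no-U-turn (NUTS) Hamiltonian transition over the
   unconstrained parameterization;
3. hand $\sigma$ and the parametric fit $x^\beta\beta + w\lambda$ back to
   the ensemble as its offset and fixed variance; run one Bayesian
   backfitting sweep — each tree is updated by a Metropolis–Hastings
   proposal (GROW 0.25 / PRUNE 0.25 / CHANGE 0.50, no SWAP) against the
   partial residuals of the other trees, using the integrated leaf
   likelihood, then its leaf values are redrawn from their conjugate normal
   posteriors.

Proposals that would create an empty leaf are rejected outright, which keeps
the integrated likelihood well defined; ties route left ($x \le c$ goes to
the left child), fixed for reproducibility. The NUTS transition uses a
diagonal Euclidean metric, multinomial sampling along the doubling
trajectory weighted by the energy error, a divergence threshold of 1000
nats, and max tree depth 10. Warm-up adapts the stepsize by dual averaging
(target acceptance 0.8, $\gamma = 0.05$, $t_0 = 10$, $\kappa = 0.75$) and
the metric from expanding windows of draws, in the standard three-phase
schedule scaled to the warm-up length.

Chains start from trees sampled from the regularization prior, with offset
and residual sd taken from a cheap maximum-likelihood-style fit: ordinary
(ridge-fallback) least squares on the combined covariates plus one-way
moment-of-variance (ANOVA) estimates of the group intercept variances and
shrunken group means. Eight chains is the default; each chain derives its
seed reproducibly from the master seed and the same seed yields bit-identical
fits.

Two degenerate limits hold exactly in the code paths, not approximately:
with `m = 0` the cycle is the pure multilevel sampler, and with no
parametric or group terms it is standalone BART with $\sigma$ drawn by a
one-dimensional parametric block.

### Numerical choices

* Cutpoint grids: at most 100 per column, at uniform quantiles of the
  distinct values, strictly inside the observed range (exact midpoints when
  few distinct values; 0.5 for binary indicators). Constant columns are
  never split.
* Trees are kept in a canonical preorder layout before every update, so the
  persistent compiled representation used inside chains and the
  value-semantics representation used by the exported single-sweep
  operations consume the random-number stream identically and produce
  bit-identical chains.
* The one-way moment estimator uses the unbalanced-design correction
  $\tilde n = (n - \sum_g n_g^2 / n)/(G - 1)$ and truncates negative
  variance estimates at zero; singular least-squares designs fall back to a
  ridge-regularized solve.
* Effective sample size uses $S / (1 + 2\sum_t \hat\rho_t)$ with the Geyer
  initial-monotone-pair truncation, pooled over split chains; first-order
  antithetic chains legitimately give ESS above $S$ and the estimate is not
  clamped. Split-$\hat R$ is reported alongside.

## The causal layer

With a binary treatment, the model is fit to the observed data and
counterfactual predictions are drawn for a test table whose treatment column
is flipped ($z \mapsto 1 - z$). Per draw, the expected-outcome matrices
recombine as $\mu_1 = z\mu_{obs} + (1 - z)\mu_{cf}$ and
$\mu_0 = (1 - z)\mu_{obs} + z\mu_{cf}$; their difference gives iCATE draws,
and averages over unit subsets give CATE (all units), SATT (treated),
GSATE/GSATT (per group, with groups lacking treated units reported as
absent, never imputed). Posterior-predictive effects fix the observed arm at
the observed outcome and draw the counterfactual arm from the predictive
distribution, giving SATE-style sample effects. Intervals default to the
$\pm 1.96\,\mathrm{sd}$ form over the estimand draws, with percentile
intervals alongside.

Propensity scores for the pure-BART comparators come from a probit ensemble
of the treatment on the covariates with `k_shrink = 4` — twice the
regression default, i.e. leaf values shrunk twice as hard — which keeps
estimated scores strictly inside (0, 1) and guards against overfitting the
assignment mechanism. The hyperparameter is exposed; conservative shrinkage
is our resolution of the ambiguous guidance in the literature about how
strongly propensity ensembles should be regularized.

## The synthetic benchmark generator

`simulate_dataset()` emulates the structure of the IHDP-based semi-synthetic
benchmark without any real data: 6 continuous covariates from a correlated
Gaussian copula (pairwise correlations drawn once per dataset, uniform on
$(-0.5, 0.5)$, projected to the nearest valid correlation matrix), 9 binary
covariates by thresholding latent normals at prevalences in (0.1, 0.9), and
2 unordered categoricals (4 and 8 levels) from Dirichlet-weighted
multinomials. Treatment is randomized at $P(z = 1) = 1/3$ and then made
observational by deleting treated units whose first binary covariate (the
"nonwhite mother" analogue of the original study) equals 1 — confounding
every covariate correlated with it through the copula while keeping common
support where treated units remain.

Three response surfaces: A is linear with $h_1 = h_0$ (a constant effect
enters through the group step); B keeps $h_0$ linear and sets
$h_1 = \exp((X + 0.5)\beta_B)$, recentered to $h_0$'s mean; C adds squared
and interaction terms whose curvature differs between arms, with at least
one pure quadratic and one cross term guaranteed nonzero. Coefficients are
drawn once per dataset from sparse discrete sets in the style of the
original benchmark — surface A from $\{0,1,2,3,4\}$ with weights
$(.5,.2,.15,.1,.05)$, surface B from $\{0,.1,.2,.3,.4\}$, surface C
nonlinear terms from $\{0,.5,1\}$ over a random fifth of the eligible
terms — and recorded with the dataset.

Group structure: 8 or 26 levels (site-indicator and mother's-age analogues)
with Dirichlet-multinomial sizes; varying intercepts
$\lambda^{int}_g \sim N(0, \sigma_{int})$ with
$\sigma_{int}^2 = \frac{ICC}{1 - ICC}\sigma_0^2$, defining the intraclass
correlation on the control-outcome scale (one convention had to be fixed).
Under the intercepts-and-slopes structure the treated arm additionally gets
$\lambda^{slo}_g \sim N(0, \sigma_{int})$. In both structures a constant
$\tau$ is calibrated so the realized SATT equals
`effect_size` $\times\ \mathrm{sd}(Y)$, using the analytic decomposition
$\mathrm{sd}(Y)^2 = \mathrm{var}(h_0) + \sigma_{int}^2 + \sigma_0^2$
evaluated on the sample's own $h_0$ (equivalent in expectation to
calibrating against a large auxiliary draw, and far cheaper at study scale).
The published description ties the effect-size knob to the spread of the
effect term under varying slopes, which cannot pin down a zero-mean target;
the additive-constant convention keeps the knob meaningful in both
structures and makes the stored true SATT exact by construction. Error sds
$\sigma_0 = \sigma_1 = 1$ (nothing suggests they differ). Defaults follow
the benchmark grid: $n = 985$, effect sizes $\{0, .2, .5, .8\}$, ICC
$\{.2, .333, .5\}$.

What the generator does *not* emulate: the real covariate joint
distribution (only its type census and a generic correlation structure),
group-level treatment assignment, or common-support violations. Passing
tests on these data therefore demonstrate correctness of the machinery and
calibration under the model's assumptions, not performance on any real
study population.

## The evaluation harness

`run_study()` crosses simulation configurations with comparator methods on
identical per-replication datasets under a deterministic seed schedule.
Comparators: pooled and fixed-effect linear regressions (plus a
treatment-by-group interacted variant), Bayesian varying-intercept/slope
linear models run through this package's own sampler with the ensemble
disabled, pure-BART variants (grouping omitted, one-hot fixed effects, or
varying intercepts) each with the propensity score appended, and the
coupled semiparametric model with `(1 | g)` or `(1 + z | g)`. The published
comparator list distinguishes a "LinearX v.i.s." from "Linear v.i.s." while
describing them identically; here `linearx_vis` adds parametric
treatment-by-covariate interactions (our reading of the "X") on top of the
varying intercepts and slopes. Bayesian causal forests are out of scope (no
public multilevel reference implementation exists to mirror).

Metrics: SATT/GSATT RMSE and mean 95%-interval length, standardized by each
replication's outcome sd; coverage against the nominal 95% level; and PEHE,
$\sqrt{\frac1n \sum_i (\hat\tau_i - \tau_i)^2}$, for unit-level effects.
Frequentist linear baselines report normal-theory intervals; Bayesian
methods report their posterior intervals; methods without an interval for
an estimand report it as absent, and coverage is then absent rather than
zero.

## Study scale and validation design

The validation suite favors many small, sharply targeted checks over few
large ones. Exact oracles: full enumeration of the single-tree posterior on
a ten-point fixture (total variation against the sampler's long-run
topology frequencies), closed-form and numeric-integration checks of every
conjugate update, finite-difference checks of the posterior gradient, and
detailed-balance identities for the tree proposals. Distributional oracles:
known-moment Gaussian targets for NUTS, simulation-based calibration of the
parametric block (rank uniformity of prior draws within their posteriors),
and a Geweke joint-distribution comparison for the full coupled sampler —
the marginal-conditional simulator draws from the prior, the
successive-conditional simulator alternates data and parameter updates, and
moments of both must agree. The Geweke and calibration chains draw a fresh
stepsize per transition from a modest range around the adapted value: a
valid kernel mixture that keeps a single fixed stepsize from trapping the
chain in one scale regime of the heavy-tailed prior, which would otherwise
dominate the comparison with finite-sample mixing error.

The replicated studies run at a deliberately reduced scale chosen once:
$n = 500$ units, 50 replications, 1–2 chains of 150–300 retained draws,
$m = 50$ trees. These sizes give the calibration and ordering checks enough
resolution (binomial coverage bands of roughly $\pm 0.06$ at 50
replications) while keeping the full suite runnable on a laptop in minutes.

## Known limitations

* One grouping factor per `(... | g)` term, no nested/interacted factor
  syntax sugar, no missing-data handling, no survey weights, at most two
  treatment arms.
* The tree component has no heteroskedastic extension and no sparse
  variable-selection prior; counts, survival times, and multivariate
  outcomes are out of scope.
* The NUTS metric is diagonal; strongly correlated parametric posteriors
  mix more slowly than a dense-metric sampler would.
* Interval coverage claims inherit the usual caveat of the benchmark
  design: they are verified under the generator's assumptions (ignorability
  and overlap hold by construction), not against violations of them.
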