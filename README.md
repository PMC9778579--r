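# bartmm

Semiparametric Bayesian regression that combines a BART tree ensemble with
a parametric linear term and multilevel (varying-intercept / varying-slope)
group effects, with a causal-inference layer for heterogeneous treatment
effects in grouped observational data.

## Who this is for

Applied statisticians and epidemiologists analyzing observational studies
where units are nested in groups — patients in hospitals, students in
schools, families in study sites — and where the outcome's dependence on
covariates is too irregular for a linear model, but the grouped error
structure is too important to ignore. Machine-learning response-surface
methods usually assume i.i.d. errors; multilevel models usually assume
linearity. This package fits both at once.

## The model

$$
Y_i = x_i^\beta \beta + f(x_i, z_i; T, M) + w_i \lambda + \epsilon_i,
\qquad \lambda \sim N(0, \Sigma_\lambda), \quad \epsilon_i \sim N(0, \sigma^2)
$$

where $f$ is a sum of $m$ regression trees under the BART regularization
prior, $x^\beta\beta$ is an ordinary linear term, and $w\lambda$ carries
group-level intercepts and slopes with covariance $\Sigma_\lambda = DCD$
(exponential priors on the standard deviations in $D$, an LKJ prior on the
correlation matrix $C$). Inference is a Gibbs sampler that alternates one
no-U-turn Hamiltonian draw of the parametric block with one Bayesian
backfitting sweep over the trees, each conditioned on the other as a fixed
offset — the stan4bart sampling scheme. Binary outcomes use the probit
latent-variable trick with $\sigma \equiv 1$.

For causal questions, the model is fit to the observed data together with a
counterfactual copy of it in which the treatment indicator is flipped;
posterior draws of each unit's two expected potential outcomes then yield
iCATE, CATE, SATE, SATT and per-group GSATE/GSATT posteriors.

## Worked example

Simulate a confounded multilevel observational study (an IHDP-style
benchmark: 17 covariates, 8 sites, treated fraction one third before a
nonrandom deletion), fit the model, and estimate the sample average
treatment effect on the treated:

```r
library(bartmm)

cfg <- sim_config(n = 500, surface = "C", grouping = "g8",
                  structure = "vi", effect_size = 0.5, icc = 0.2, seed = 1)
sim <- simulate_dataset(cfg)
d <- sim$data

fit <- bartmm("y ~ bart(. - g) + (1 | g)",
              train = d,
              test = make_counterfactual(d, "z"),
              treatment = "z",
              chains = 4, warmup = 500, draws = 500, m = 100, seed = 2)
print(fit)
#> bartmm fit: y ~ bart(. - g) + (1 | g)
#>   n = 500, trees = 100, chains = 4, draws = 500 (+500 warmup)
#>   divergences: 9 5 5 5
#>   residual sd: mean 1.091 (95% interval 0.9877-1.217)

satt(fit)
#> estimate 1.799  [1.483, 2.114]  (sd 0.1608, 122 units, 2000 draws)
sim$truth$satt
#> [1] 2.092529
```

The fitted residual sd brackets the generator's $\sigma_0 = 1$, and the
SATT interval covers the recorded ground truth (2.09) — this is a hard
dataset (a curvature-heavy response surface at $n = 500$), and the point
estimate's mild attenuation toward zero is visible. Group-level effects and
unit-level effects come from the same fit:

```r
gsatt(fit, d$g)$grp3      # treated-unit average effect within site 3
#> estimate 1.874  [1.495, 2.253]  (sd 0.1933, 11 units, 2000 draws)
head(round(rowMeans(icate_draws(fit)), 3))  # per-unit effect estimates
#> [1] 1.782 1.236 1.794 1.718 2.317 2.553
```

The model-specification language accepts plain parametric terms, `a:b`
interactions, a `bart(...)` set (with `.`, `+`, `-`), and `lme4`-style
`(1 + z | g)` multilevel terms. `run_study()` replicates datasets across
surface/grouping/effect-size/ICC configurations and compares the coupled
model with linear and pure-BART baselines on standardized RMSE, interval
length, coverage, and PEHE; see the methods vignette
(`vignettes/bartmm-methods.Rmd`) for the full account of priors, sampler
internals, the generator's design, and validation methodology.

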