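small_fit <- function(d, test = NULL, ...) {
  bartmm("y ~ z + bart(. - g) + (1 | g)", d, test = test, treatment = "z",
         chains = 2L, warmup = 60L, draws = 40L, m = 10L, seed = 42, ...)
}

test_that("same seed and inputs give a bit-identical fit", {
  d <- toy_table(60, seed = 30)
  test <- make_counterfactual(d, "z")
  f1 <- small_fit(d, test)
  f2 <- small_fit(d, test)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$seeds, f2$seeds)
  f3 <- bartmm("y ~ z + bart(. - g) + (1 | g)", d, test = test,
               treatment = "z", chains = 2L, warmup = 60L, draws = 40L,
               m = 10L, seed = 43)
  expect_false(identical(f1$draws$sigma, f3$draws$sigma))
})

test_that("eight chains is the default and chains are stored side by side", {
  expect_equal(formals(bartmm)$chains, 8L)
  d <- toy_table(50, seed = 31)
  f <- small_fit(d)
  expect_equal(ncol(f$draws$f_train), 2L * 40L)
  expect_length(f$draws$sigma, 80L)
  # pooled summaries are invariant to chain order (exchangeability)
  s <- f$draws$sigma
  perm <- c(41:80, 1:40)
  expect_equal(mean(s), mean(s[perm]))
  expect_equal(quantile(s, c(0.1, 0.9)), quantile(s[perm], c(0.1, 0.9)))
})

test_that("stored expected values decompose into their components", {
  d <- toy_table(60, seed = 32)
  test <- make_counterfactual(d, "z")
  f <- small_fit(d, test)
  ev <- extract(f, "train", "ev")
  bartpart <- extract(f, "train", "bart")
  parpart <- extract(f, "train", "param")
  # components are reported on the spread scale; the ev adds the center once
  center <- f$design$scale$center
  expect_equal(ev, bartpart + parpart + center, tolerance = 1e-10)
  # parametric component reproduces X beta + W lambda draw by draw
  des <- f$design
  S <- ncol(f$draws$par_train)
  g <- des$W$g
  for (s in c(1L, S %/% 2L, S)) {
    lam <- matrix(f$draws$lambda$g[, s], g$L, g$K)
    par_s <- as.vector(des$X_beta %*% f$draws$beta[, s]) +
      rowSums(g$U * lam[g$index, , drop = FALSE])
    expect_equal(f$draws$par_train[, s], par_s, tolerance = 1e-10)
  }
})

test_that("extraction rescales to the outcome scale and validates input", {
  d <- toy_table(60, seed = 33)
  test <- make_counterfactual(d, "z")
  f <- small_fit(d, test)
  ev <- extract(f, "train", "ev")
  expect_equal(dim(ev), c(60L, 80L))
  # fitted values live on the outcome scale
  expect_lt(abs(mean(ev) - mean(d$y)), 2 * sd(d$y))
  expect_error(extract(f, "train", "ppd"), "test sample")
  f0 <- small_fit(d)
  expect_error(extract(f0, "test", "ev"), "without a test table")
  # ppd draws are ev plus mean-zero noise
  ppd <- extract(f, "test", "ppd")
  evt <- extract(f, "test", "ev")
  expect_equal(mean(ppd - evt), 0,
               tolerance = 4 * sd(ppd - evt) / sqrt(length(ppd)))
})

test_that("binary outcomes run the probit path with sigma fixed at 1", {
  d <- toy_table(80, seed = 34)
  d$y <- rbinom(80, 1, pnorm(0.8 * d$x1))
  test <- make_counterfactual(d, "z")
  f <- bartmm("y ~ z + bart(. - g) + (1 | g)", d, test = test,
              treatment = "z", chains = 1L, warmup = 50L, draws = 30L,
              m = 10L, seed = 1)
  expect_true(all(f$draws$sigma == 1))
  ppd <- extract(f, "test", "ppd")
  expect_true(all(ppd %in% c(0, 1)))
})

test_that("with the ensemble disabled the fit is the multilevel sampler", {
  d <- toy_table(60, seed = 35)
  f <- bartmm("y ~ z + bart(. - g) + (1 | g)", d, treatment = "z",
              chains = 1L, warmup = 50L, draws = 30L, m = 0L, seed = 7)
  # manual pure-parametric chain replicating the run loop on the same design
  spec <- parse_formula("y ~ z + bart(. - g) + (1 | g)", treatment = "z")
  des <- build_design(spec, d)
  set.seed(7)
  chain_seed <- sample.int(.Machine$integer.max, 1L)
  ml <- ml_init(des)
  set.seed(chain_seed)
  model <- build_param_model(des, offset = numeric(60), priors = list())
  theta <- bartmm:::.init_theta(model, ml)
  model$set_offset(numeric(60))
  param <- list(theta = theta, state = bartmm:::.param_state(model, theta))
  eps0 <- bartmm:::.init_stepsize(model$lp_grad, theta, rep(1, model$dim))
  ad <- bartmm:::.adapter_new(model$dim, 50L, 0.8, eps0)
  for (t in 1:50) {
    dp <- draw_param_block(model, param$theta, ad$eps, ad$inv_metric, 10L)
    param <- list(theta = dp$theta, state = dp$state)
    bartmm:::.adapter_update(ad, param$theta, dp$accept_stat, dp$divergent)
  }
  sig <- numeric(30)
  for (t in 1:30) {
    dp <- draw_param_block(model, param$theta, ad$eps, ad$inv_metric, 10L)
    param <- list(theta = dp$theta, state = dp$state)
    sig[t] <- dp$state$sigma
  }
  expect_identical(f$draws$sigma, sig)
  expect_true(all(f$draws$f_train == 0))
})

test_that("with no parametric terms the fit is standalone BART plus a
           sigma-only sampler", {
  d <- toy_table(60, seed = 36)
  f <- bartmm("y ~ bart(. - g)", d, chains = 1L, warmup = 40L, draws = 25L,
              m = 8L, seed = 9)
  # the parametric block holds only sigma: no beta, no group effects
  expect_null(f$draws$beta)
  expect_null(f$draws$lambda)
  expect_true(all(f$draws$par_train == 0))
  # manual mirror: prior trees + sigma-only NUTS + backfitting
  spec <- parse_formula("y ~ bart(. - g)")
  des <- build_design(spec, d)
  set.seed(9)
  chain_seed <- sample.int(.Machine$integer.max, 1L)
  ml <- ml_init(des)
  hyper <- calibrate_hyperparams(des$y, m = 8L, sigma_hat = max(ml$sigma, 1e-3))
  set.seed(chain_seed)
  model <- build_param_model(des, offset = numeric(60), priors = list())
  ens <- ensemble_init(des$X_bart, des$cutpoints, hyper,
                       sigma = max(ml$sigma, 1e-3), persistent = TRUE)
  theta <- bartmm:::.init_theta(model, ml)
  model$set_offset(ens$total_fit)
  param <- list(theta = theta, state = bartmm:::.param_state(model, theta))
  eps0 <- bartmm:::.init_stepsize(model$lp_grad, theta, rep(1, model$dim))
  ad <- bartmm:::.adapter_new(model$dim, 40L, 0.8, eps0)
  run1 <- function() {
    gs <- gibbs_step(ens, param, model, des, ad$eps, ad$inv_metric, 10L)
    ens <<- gs$ensemble; param <<- gs$param
    gs
  }
  for (t in 1:40) {
    gs <- run1()
    bartmm:::.adapter_update(ad, param$theta, gs$accept_stat, gs$divergent)
  }
  fmat <- matrix(0, 60, 25)
  for (t in 1:25) { run1(); fmat[, t] <- ens$total_fit }
  expect_equal(f$draws$f_train, fmat, tolerance = 1e-12)
})

test_that("effective sample size follows the doubled-sum estimator", {
  set.seed(37)
  # near-iid draws: ESS close to S
  x <- rnorm(4000)
  e <- effective_sample_size(x)
  expect_gt(e$ess, 3000)
  expect_lt(abs(e$rhat - 1), 0.02)
  # AR(1) with phi = 0.5: ESS/S -> (1 - phi)/(1 + phi) = 1/3
  phi <- 0.5
  ar <- as.vector(arima.sim(list(ar = phi), 20000))
  ear <- effective_sample_size(ar)
  expect_equal(ear$ess / 20000, 1 / 3, tolerance = 0.15)
  # antithetic chains: ESS above S, reported unclamped
  z <- rnorm(10001)
  anti <- z[-1] - 0.9 * z[-10001]
  eanti <- effective_sample_size(anti)
  expect_gt(eanti$ess, 10000)
  # constant chains are flagged, and short chains rejected
  expect_true(is.na(effective_sample_size(rep(1, 100))$ess))
  expect_error(effective_sample_size(rnorm(5)), "at least 10")
  # multi-chain disagreement inflates split-R-hat
  m2 <- cbind(rnorm(500), rnorm(500) + 3)
  expect_gt(effective_sample_size(m2)$rhat, 1.5)
})

test_that("divergence and acceptance diagnostics are recorded per chain", {
  d <- toy_table(50, seed = 38)
  f <- small_fit(d)
  expect_length(f$diagnostics$divergences, 2L)
  expect_true(all(f$diagnostics$accept_mean > 0.3))
  expect_true(all(f$diagnostics$stepsize > 0))
})
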