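test_that("covariance reassembles from sds and correlation Cholesky", {
  expect_equal(reconstruct_sigma_lambda(2, matrix(1)), matrix(4))
  expect_equal(reconstruct_sigma_lambda(c(1, 1), diag(2)), diag(2))
  # sds (1,2), correlation 0.5
  L <- t(chol(matrix(c(1, 0.5, 0.5, 1), 2)))
  expect_equal(reconstruct_sigma_lambda(c(1, 2), L),
               matrix(c(1, 1, 1, 4), 2), tolerance = 1e-12)
})

test_that("log-posterior gradient matches central finite differences", {
  d <- toy_table(50, seed = 8)
  spec <- parse_formula("y ~ z + x1 + bart(x1) + (1 + z | g)")
  des <- build_design(spec, d)
  m <- build_param_model(des, offset = rnorm(50, 0, 0.1))
  set.seed(9)
  for (rep in 1:20) {
    th <- rnorm(m$dim, 0, 0.5)
    g <- m$lp_grad(th)$grad
    fd <- vapply(seq_len(m$dim), function(i) {
      h <- 1e-6
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (m$lp_grad(tp)$lp - m$lp_grad(tm)$lp) / (2 * h)
    }, 0)
    expect_lt(max(abs(fd - g) / (abs(g) + 1e-4)), 1e-5)
  }
})

test_that("unconstrained <-> constrained transforms round-trip", {
  d <- toy_table(40, seed = 10)
  des <- build_design(parse_formula("y ~ z + bart(x1) + (1 + z | g)"), d)
  m <- build_param_model(des, offset = numeric(40))
  set.seed(11)
  th <- rnorm(m$dim, 0, 0.8)
  st <- m$unpack(th)
  th2 <- m$pack(st$beta, lapply(st$groups, function(g)
    list(eta = g$eta, log_sd = g$log_sd, z = g$z)), st$log_sigma)
  expect_equal(th2, th, tolerance = 1e-12)
  # the correlation Cholesky factor has unit-norm rows
  L <- st$groups[[1]]$Lc
  expect_equal(rowSums(L^2), rep(1, 2), tolerance = 1e-12)
  # reconstructed covariance is symmetric positive definite
  S <- reconstruct_sigma_lambda(st$groups[[1]]$sds, L)
  expect_equal(S, t(S))
  expect_true(all(eigen(S)$values > 0))
})

test_that("flat-prior no-group posterior mode is the least-squares solution", {
  set.seed(12)
  n <- 120
  X <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  beta_true <- c(1, -0.5, 0.2)
  y <- X %*% beta_true + rnorm(n, 0, 0.3)
  d <- data.frame(y = as.vector(y), x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  des <- build_design(parse_formula("y ~ x1 + x2 + x3 + bart(x1)"), d)
  m <- build_param_model(des, offset = numeric(n),
                         priors = list(beta_scale = 100))
  ls <- qr.coef(qr(des$X_beta), des$y)
  # optimize the log posterior over beta with sigma fixed near truth
  f <- function(b) -m$lp_grad(c(b, log(0.3 / diff(range(d$y)))))$lp
  opt <- optim(rep(0, 3), f, method = "BFGS")
  expect_equal(opt$par, unname(ls), tolerance = 1e-3)
})

test_that("perfect offset drives the residual sd posterior to zero", {
  set.seed(13)
  n <- 80
  d <- data.frame(y = rnorm(n), x1 = rnorm(n))
  des <- build_design(parse_formula("y ~ x1 + bart(x1)"), d)
  m <- build_param_model(des, offset = des$y) # offset = y exactly (beta = 0)
  # at beta = 0, larger sigma is strictly worse
  lp_at <- function(ls) m$lp_grad(c(0, ls))$lp
  expect_gt(lp_at(log(0.001)), lp_at(log(0.1)))
  expect_gt(lp_at(log(0.001)), lp_at(log(1)))
})

test_that("one NUTS transition: known 1-d Gaussian target recovered", {
  set.seed(14)
  lp <- function(q) list(lp = -q^2 / 2, grad = -q)
  q <- 0
  draws <- numeric(1e4)
  for (i in seq_len(1e4)) {
    q <- nuts_transition(lp, q, stepsize = 0.8)$position
    draws[i] <- q
  }
  ess <- effective_sample_size(draws)$ess
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(ess))
  expect_equal(var(draws), 1, tolerance = 0.1)
})

test_that("leapfrog energy error scales as stepsize squared", {
  set.seed(15)
  # integrate a standard Gaussian Hamiltonian to fixed time T; the energy
  # error of the trajectory endpoint scales as eps^2
  energy_err <- function(eps, T = 1) {
    q <- 1.3; p <- 0.7
    H0 <- (q^2 + p^2) / 2
    for (s in seq_len(round(T / eps))) {
      p <- p - eps / 2 * q
      q <- q + eps * p
      p <- p - eps / 2 * q
    }
    abs((q^2 + p^2) / 2 - H0)
  }
  e1 <- energy_err(0.2)
  e2 <- energy_err(0.1)
  expect_equal(e1 / e2, 4, tolerance = 0.35)
  # and through the sampler: halving the stepsize shrinks the mean energy
  # error roughly fourfold on a quadratic target
  lp <- function(q) list(lp = -sum(q^2) / 2, grad = -q)
  err_at <- function(eps) {
    set.seed(16)
    a <- replicate(200, nuts_transition(lp, rnorm(4), eps)$accept_stat)
    mean(-log(pmin(a, 1 - 1e-12)))
  }
  r <- err_at(0.5) / err_at(0.25)
  expect_gt(r, 2.2)
  expect_lt(r, 7)
})

test_that("zero-stepsize limit keeps the position still", {
  lp <- function(q) list(lp = -sum(q^2) / 2, grad = -q)
  set.seed(17)
  tr <- nuts_transition(lp, c(1, 2), stepsize = 1e-10)
  expect_equal(tr$position, c(1, 2), tolerance = 1e-6)
})

test_that("warm-up adaptation finds the scale structure of the target", {
  set.seed(18)
  # N(0, diag(1, 100)): adapted metric ratio within a factor 3 of 100
  P <- c(1, 1 / 100)
  lp <- function(q) list(lp = -sum(P * q^2) / 2, grad = -P * q)
  ad <- warmup_adapt(lp, c(0, 0), iters = 400, target_accept = 0.8)
  ratio <- ad$inv_metric[2] / ad$inv_metric[1]
  expect_gt(ratio, 100 / 3)
  expect_lt(ratio, 300)
  # realized acceptance near the target after warm-up
  acc <- mean(tail(ad$accept_stats, 100))
  expect_gt(acc, 0.6)
  expect_lt(acc, 0.95)
})

test_that("joint parametric draws match the conjugate posterior", {
  set.seed(19)
  n <- 100
  X <- cbind(rnorm(n), rnorm(n))
  beta_true <- c(0.8, -0.4)
  sigma <- 0.5
  y <- as.vector(X %*% beta_true) + rnorm(n, 0, sigma)
  d <- data.frame(y = y, x1 = X[, 1], x2 = X[, 2])
  des <- build_design(parse_formula("y ~ x1 + x2 + bart(x1)"), d)
  prior_sd <- 10 # effectively flat on the model scale
  m <- build_param_model(des, offset = numeric(n),
                         priors = list(beta_scale = prior_sd))
  ad <- warmup_adapt(m, rep(0, m$dim), iters = 300)
  th <- ad$state
  S <- 4000
  bdraws <- matrix(0, S, 2)
  for (i in seq_len(S)) {
    dp <- draw_param_block(m, th, ad$stepsize, ad$inv_metric)
    th <- dp$theta
    bdraws[i, ] <- dp$state$beta
  }
  # conditional on sigma the posterior is Gaussian; compare against the
  # ridge-form posterior mean using the average drawn sigma
  sig_hat <- sd(des$y - des$X_beta %*% colMeans(bdraws))
  V <- solve(crossprod(des$X_beta) / sig_hat^2 + diag(1 / prior_sd^2, 2))
  b_post <- V %*% crossprod(des$X_beta, des$y) / sig_hat^2
  for (j in 1:2) {
    ess <- effective_sample_size(bdraws[, j])$ess
    expect_lt(abs(mean(bdraws[, j]) - b_post[j]),
              4 * sd(bdraws[, j]) / sqrt(ess) + 0.02 * abs(b_post[j]))
  }
  # reproducibility of a single draw
  set.seed(77)
  d1 <- draw_param_block(m, th, ad$stepsize, ad$inv_metric)
  set.seed(77)
  d2 <- draw_param_block(m, th, ad$stepsize, ad$inv_metric)
  expect_identical(d1$theta, d2$theta)
})

test_that("varying-intercept scale is recovered from simulated data", {
  dg <- vi_data(n = 400, G = 20, sd_g = 0.7, sigma = 1, seed = 20)
  des <- build_design(parse_formula("y ~ x + bart(x) + (1 | g)"), dg$d)
  m <- build_param_model(des, offset = numeric(400))
  set.seed(21)
  ad <- warmup_adapt(m, rep(0.1, m$dim), iters = 300)
  th <- ad$state
  S <- 1200
  sds <- numeric(S)
  for (i in seq_len(S)) {
    dp <- draw_param_block(m, th, ad$stepsize, ad$inv_metric)
    th <- dp$theta
    sds[i] <- dp$state$groups[[1]]$sds
  }
  scale_y <- diff(range(dg$d$y))
  sd_draws <- sds * scale_y
  expect_lt(abs(mean(sd_draws) - dg$sd_g), 3 * sd(sd_draws) + 0.1)
})

test_that("stronger LKJ shapes concentrate correlations at identity", {
  # prior draws of the correlation via the model's own transform
  set.seed(22)
  mean_abs_corr <- function(shape) {
    # CPC prior for K = 2: x = tanh(z) with density prop to (1-x^2)^shape
    # on the unconstrained scale; sample by grid inversion
    z <- seq(-6, 6, length.out = 4001)
    w <- exp(shape * log(1 - tanh(z)^2))
    x <- tanh(sample(z, 4000, TRUE, prob = w / sum(w)))
    mean(abs(x))
  }
  m1 <- mean_abs_corr(1)
  m4 <- mean_abs_corr(4)
  expect_lt(m4, m1)
  # shape 1 corresponds to a uniform correlation: E|rho| = 0.5
  expect_equal(m1, 0.5, tolerance = 0.05)
})

test_that("ML-style initialization matches its oracles", {
  # balanced one-way layout: moment estimator equals the ANOVA identity
  set.seed(23)
  G <- 8; npg <- 25
  g <- rep(seq_len(G), each = npg)
  lam <- rnorm(G, 0, 1.2)
  y <- lam[g] + rnorm(G * npg, 0, 0.8)
  d <- data.frame(y = y, g = factor(g), x = rnorm(G * npg, 0, 1e-8))
  des <- build_design(parse_formula("y ~ bart(x) + (1 | g)"), d)
  ml <- ml_init(des)
  res <- des$y - ml$fitted
  means <- tapply(res, g, mean)
  msb <- npg * sum((means - mean(res))^2) / (G - 1)
  msw <- sum((res - means[g])^2) / (G * npg - G)
  expect_equal(ml$sd_lambda$g[1]^2, max(0, (msb - msw) / npg),
               tolerance = 1e-6)
  # noiseless pure-linear data: offset reproduces the signal, sigma ~ 0
  d2 <- data.frame(y = 1 + 2 * rnorm(50), x = 0)
  d2$x <- (d2$y - 1) / 2
  des2 <- build_design(parse_formula("y ~ x + bart(x)"), d2)
  ml2 <- ml_init(des2)
  expect_lte(ml2$sigma, 1e-6)
  # no grouping reduces to ordinary least squares
  d3 <- toy_table(60)
  des3 <- build_design(parse_formula("y ~ z + x1 + bart(x1)"), d3)
  ml3 <- ml_init(des3)
  ols <- lm(des3$y ~ des3$X_beta)
  expect_equal(ml3$beta, unname(coef(ols)[-1]), tolerance = 1e-8)
})

test_that("single-level grouping factors are rejected", {
  d <- toy_table(30)
  d$g <- factor("a")
  des <- suppressWarnings(
    build_design(parse_formula("y ~ bart(x1) + (1 | g)"), d))
  expect_error(build_param_model(des, numeric(30)), "single level")
})
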