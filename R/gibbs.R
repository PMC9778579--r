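# The coupled sampler: alternate one joint no-U-turn draw of the parametric
# block (conditioned on the tree predictions as an offset) with one Bayesian
# backfitting sweep over the trees (conditioned on the parametric fit as an
# offset and on the freshly drawn residual sd). Binary outcomes insert a
# truncated-normal latent update at the top of each cycle.

#' One cycle of the coupled Gibbs sampler
#'
#' (1) collect the current ensemble predictions as the parametric model's
#' offset; (2) draw the parametric block jointly by NUTS; (3) pass sigma and
#' the parametric fit to the ensemble as its offset; (4) run one backfitting
#' sweep with fixed variance. Probit mode first redraws the latent response
#' given the full current fit.
#'
#' @param ensemble a `bartmm_ensemble` (may have zero trees).
#' @param param list with `theta` (unconstrained) and `state`.
#' @param model a `bartmm_param_model` bound to the same design.
#' @param design the `bartmm_design`.
#' @param stepsize,inv_metric,max_depth NUTS settings.
#' @param y_latent current latent response for probit mode (NULL otherwise).
#' @return list with updated `ensemble`, `param`, `y_latent`, and transition
#'   diagnostics.
#' @export
gibbs_step <- function(ensemble, param, model, design, stepsize,
                       inv_metric = NULL, max_depth = 10L, y_latent = NULL) {
  probit <- design$outcome_kind == "binary"
  if (probit) {
    mean_full <- ensemble$total_fit +
      (if (!is.null(param$state)) param$state$fit_param else 0)
    y_latent <- probit_latent_update(design$y, mean_full)
    model$set_y(y_latent)
  }
  model$set_offset(ensemble$total_fit)
  diag_ <- list(accept_stat = NA_real_, divergent = FALSE)
  if (model$dim > 0L) {
    dp <- draw_param_block(model, param$theta, stepsize, inv_metric, max_depth)
    param <- list(theta = dp$theta, state = dp$state)
    diag_ <- list(accept_stat = dp$accept_stat, divergent = dp$divergent)
  }
  sigma <- if (probit) 1 else param$state$sigma
  ensemble$sigma <- sigma
  y_work <- (if (probit) y_latent else design$y) -
    (if (!is.null(param$state)) param$state$fit_param else 0)
  if (ensemble$hyper$m > 0L) ensemble <- backfit_sweep(ensemble, y_work)
  list(ensemble = ensemble, param = param, y_latent = y_latent,
       accept_stat = diag_$accept_stat, divergent = diag_$divergent)
}

# initial unconstrained position from the ML-style fit, with a small jitter
.init_theta <- function(model, ml, jitter_sd = 0.02) {
  groups <- model$groups
  gs <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    sdl <- pmax(ml$sd_lambda[[g$factor]], 1e-2)
    lam <- ml$lambda[[g$factor]]
    eta <- sweep(lam, 2L, sdl, "/") # L = I at initialization
    gs[[i]] <- list(eta = eta, log_sd = log(sdl),
                    z = numeric((g$K * (g$K - 1L)) %/% 2L))
  }
  beta <- if (model$p > 0L) ml$beta else numeric(0)
  theta <- model$pack(beta, gs,
                      if (is.null(model$sigma_fixed))
                        log(max(ml$sigma, 1e-3)) else NULL)
  theta + rnorm(length(theta)) * jitter_sd
}

.null_param_state <- function(n) {
  list(beta = numeric(0), groups = list(), sigma = 1, theta = numeric(0),
       fit_param = numeric(n))
}

#' Fit the semiparametric multilevel model
#'
#' Runs the coupled BART + parametric Gibbs sampler: per chain, trees are
#' initialized from the regularization prior with offset and variance taken
#' from a maximum-likelihood-style multilevel fit, warm-up cycles adapt the
#' NUTS stepsize and diagonal metric, and the retained cycles store draws of
#' every component together with expected-value draws for the training table
#' and an optional test table (typically the flipped-treatment counterfactual
#' from [make_counterfactual()]).
#'
#' @param formula a specification string or `bartmm_spec`; see
#'   [parse_formula()].
#' @param train training data frame.
#' @param test optional data frame with the same columns (counterfactual
#'   predictions are drawn for it).
#' @param treatment optional treatment column name (recorded for the causal
#'   layer).
#' @param chains number of MCMC chains (default 8).
#' @param warmup,draws warm-up and retained cycles per chain.
#' @param m number of trees (0 disables the ensemble even if the formula has
#'   a bart() term).
#' @param seed master seed; chain seeds are derived from it reproducibly.
#' @param k_shrink,nu,q ensemble hyperparameters, see
#'   [calibrate_hyperparams()].
#' @param max_cuts cutpoints per tree predictor.
#' @param priors parametric-block prior settings, see [build_param_model()].
#' @param target_accept,max_depth_nuts NUTS adaptation settings.
#' @param verbose print per-chain progress lines.
#' @return an object of class `bartmm_fit`.
#' @export
bartmm <- function(formula, train, test = NULL, treatment = NULL,
                   chains = 8L, warmup = 1000L, draws = 1000L, m = 200L,
                   seed = NULL, k_shrink = 2, nu = 3, q = 0.9,
                   max_cuts = 100L, priors = list(), target_accept = 0.8,
                   max_depth_nuts = 10L, verbose = FALSE) {
  spec <- if (inherits(formula, "bartmm_spec")) formula
          else parse_formula(formula, treatment = treatment)
  if (!is.null(treatment)) spec$treatment <- treatment
  design <- build_design(spec, train, max_cuts = max_cuts)
  test_des <- if (!is.null(test)) {
    if (!setequal(names(test), names(train)) || nrow(test) == 0L)
      stop("test table must have the training columns", call. = FALSE)
    .design_newdata(design, test)
  }
  if (!spec$has_bart) m <- 0L
  probit <- design$outcome_kind == "binary"
  n <- design$n

  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, chains)

  ml <- ml_init(design)
  hyper <- calibrate_hyperparams(design$y, m = max(m, 1L),
                                 k_shrink = k_shrink, nu = nu, q = q,
                                 sigma_hat = max(ml$sigma, 1e-3))
  hyper$m <- as.integer(m)

  chain_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    chain_out[[ch]] <- .run_chain(design, test_des, ml, hyper, warmup, draws,
                                  priors, probit, target_accept,
                                  max_depth_nuts, verbose, ch)
  }

  combine <- function(name) {
    parts <- lapply(chain_out, `[[`, name)
    if (is.null(parts[[1]])) return(NULL)
    if (is.matrix(parts[[1]])) do.call(cbind, parts) else do.call(c, parts)
  }
  groups_meta <- lapply(design$W, function(g)
    list(factor = g$factor, levels = g$levels, K = g$K, L = g$L))

  structure(list(
    spec = spec, design = design, test_design = test_des,
    draws = list(
      f_train = combine("f_train"), par_train = combine("par_train"),
      f_test = combine("f_test"), par_test = combine("par_test"),
      ppd_test = combine("ppd_test"),
      sigma = combine("sigma"), beta = combine("beta"),
      lambda = if (length(design$W) > 0L)
        stats::setNames(lapply(names(design$W), function(nm)
          do.call(cbind, lapply(chain_out, function(co) co$lambda[[nm]]))),
          names(design$W))
      else NULL,
      sds = if (length(design$W) > 0L)
        stats::setNames(lapply(names(design$W), function(nm)
          do.call(cbind, lapply(chain_out, function(co) co$sds[[nm]]))),
          names(design$W))
      else NULL
    ),
    groups_meta = groups_meta,
    settings = list(chains = chains, warmup = warmup, draws = draws, m = m,
                    k_shrink = k_shrink, nu = nu, q = q,
                    target_accept = target_accept,
                    max_depth_nuts = max_depth_nuts, seed = seed),
    seeds = chain_seeds,
    diagnostics = list(
      divergences = vapply(chain_out, `[[`, 0L, "divergences"),
      accept_mean = vapply(chain_out, `[[`, 0, "accept_mean"),
      stepsize = vapply(chain_out, `[[`, 0, "stepsize")),
    hyper = hyper
  ), class = "bartmm_fit")
}

.run_chain <- function(design, test_des, ml, hyper, warmup, draws, priors,
                       probit, target_accept, max_depth_nuts, verbose, ch) {
  n <- design$n
  m <- hyper$m
  has_param <- ncol(design$X_beta) > 0L || length(design$W) > 0L || !probit
  model <- build_param_model(design, offset = numeric(n), priors = priors,
                             sigma_fixed = if (probit) 1 else NULL)

  ens <- ensemble_init(design$X_bart, design$cutpoints, hyper,
                       sigma = if (probit) 1 else max(ml$sigma, 1e-3),
                       persistent = TRUE)
  if (m > 0L) {
    # center the ensemble start around the ML offset via the working response
    ens$sigma <- if (probit) 1 else max(ml$sigma, 1e-3)
  }
  param <- if (model$dim > 0L) {
    theta0 <- .init_theta(model, ml)
    model$set_offset(ens$total_fit)
    list(theta = theta0, state = .param_state(model, theta0))
  } else list(theta = numeric(0), state = .null_param_state(n))

  y_latent <- NULL
  ad <- NULL
  if (model$dim > 0L) {
    model$set_offset(ens$total_fit)
    if (probit) model$set_y(probit_latent_update(design$y,
                                                 ens$total_fit +
                                                   param$state$fit_param))
    eps0 <- .init_stepsize(model$lp_grad, param$theta, rep(1, model$dim))
    ad <- .adapter_new(model$dim, warmup, target_accept, eps0)
  }

  for (t in seq_len(warmup)) {
    gs <- gibbs_step(ens, param, model, design,
                     stepsize = if (is.null(ad)) 0.1 else ad$eps,
                     inv_metric = if (is.null(ad)) NULL else ad$inv_metric,
                     max_depth = max_depth_nuts, y_latent = y_latent)
    ens <- gs$ensemble; param <- gs$param; y_latent <- gs$y_latent
    if (!is.null(ad))
      .adapter_update(ad, param$theta, gs$accept_stat, gs$divergent)
  }
  eps <- if (is.null(ad)) 0.1 else ad$eps
  invm <- if (is.null(ad)) NULL else ad$inv_metric

  p <- ncol(design$X_beta)
  out <- list(
    f_train = matrix(0, n, draws), par_train = matrix(0, n, draws),
    sigma = numeric(draws),
    beta = if (p > 0L) matrix(0, p, draws,
                              dimnames = list(colnames(design$X_beta), NULL)),
    lambda = lapply(design$W, function(g) matrix(0, g$L * g$K, draws)),
    sds = lapply(design$W, function(g) matrix(0, g$K, draws))
  )
  if (!is.null(test_des)) {
    out$f_test <- matrix(0, test_des$n, draws)
    out$par_test <- matrix(0, test_des$n, draws)
    out$ppd_test <- matrix(0, test_des$n, draws)
  }
  accepts <- numeric(draws); divs <- 0L

  for (t in seq_len(draws)) {
    gs <- gibbs_step(ens, param, model, design, eps, invm,
                     max_depth = max_depth_nuts, y_latent = y_latent)
    ens <- gs$ensemble; param <- gs$param; y_latent <- gs$y_latent
    accepts[t] <- gs$accept_stat
    divs <- divs + as.integer(isTRUE(gs$divergent))
    st <- param$state
    out$f_train[, t] <- ens$total_fit
    out$par_train[, t] <- st$fit_param
    out$sigma[t] <- if (probit) 1 else st$sigma
    if (p > 0L) out$beta[, t] <- st$beta
    for (i in seq_along(design$W)) {
      out$lambda[[i]][, t] <- as.vector(st$groups[[i]]$Lambda)
      out$sds[[i]][, t] <- st$groups[[i]]$sds
    }
    if (!is.null(test_des)) {
      f_t <- if (m > 0L) predict_ensemble(ens, test_des$X_bart)
             else numeric(test_des$n)
      par_t <- numeric(test_des$n)
      if (p > 0L) par_t <- par_t + as.vector(test_des$X_beta %*% st$beta)
      for (i in seq_along(test_des$W)) {
        g <- test_des$W[[i]]
        par_t <- par_t +
          rowSums(g$U * st$groups[[i]]$Lambda[g$index, , drop = FALSE])
      }
      out$f_test[, t] <- f_t
      out$par_test[, t] <- par_t
      ev_t <- f_t + par_t
      out$ppd_test[, t] <- if (probit) rbinom(test_des$n, 1L, pnorm(ev_t))
                           else ev_t + rnorm(test_des$n) * st$sigma
    }
    if (verbose && t %% max(1L, draws %/% 5L) == 0L)
      message(sprintf("chain %d iter %d/%d sigma=%.4f accept=%.2f div=%d",
                      ch, t, draws, out$sigma[t], accepts[t], divs))
  }
  names(out$lambda) <- names(design$W)
  names(out$sds) <- names(design$W)
  out$divergences <- divs + (if (is.null(ad)) 0L else ad$divergences)
  out$accept_mean <- mean(accepts, na.rm = TRUE)
  out$stepsize <- eps
  out
}

#' Extract posterior draw matrices from a fit
#'
#' Returns an observations-by-samples matrix on the original outcome scale.
#' `value = "ev"` gives the expected value (parametric fit + ensemble fit),
#' `"ppd"` the posterior predictive draws (test sample only; expected value
#' plus residual noise, or Bernoulli draws for binary outcomes), `"bart"` the
#' ensemble component alone (scale only, not recentered), and `"param"` the
#' parametric component alone.
#'
#' @param fit a `bartmm_fit`.
#' @param sample `"train"` or `"test"`.
#' @param value `"ev"`, `"ppd"`, `"bart"`, or `"param"`.
#' @param ... unused.
#' @return a numeric matrix (observations x samples).
#' @export
extract <- function(fit, ...) UseMethod("extract")

#' @rdname extract
#' @export
extract.bartmm_fit <- function(fit, sample = c("train", "test"),
                               value = c("ev", "ppd", "bart", "param"), ...) {
  sample <- match.arg(sample)
  value <- match.arg(value)
  d <- fit$draws
  if (sample == "test" && is.null(d$f_test))
    stop("no test draws stored: fit was run without a test table",
         call. = FALSE)
  pick <- function(f, par) switch(value,
    ev = f + par,
    ppd = stop("internal"), bart = f, param = par)
  if (value == "ppd") {
    if (sample != "test")
      stop("posterior predictive draws are stored for the test sample",
           call. = FALSE)
    out <- d$ppd_test
    return(if (fit$design$outcome_kind == "binary") out
           else .unscale(fit$design, out, "value"))
  }
  out <- if (sample == "train") pick(d$f_train, d$par_train)
         else pick(d$f_test, d$par_test)
  if (value == "ev") .unscale(fit$design, out, "value")
  else .unscale(fit$design, out, "spread")
}

#' @export
print.bartmm_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf("bartmm fit: %s\n", format(x$spec)))
  cat(sprintf("  n = %d, trees = %d, chains = %d, draws = %d (+%d warmup)\n",
              x$design$n, s$m, s$chains, s$draws, s$warmup))
  cat(sprintf("  divergences: %s\n",
              paste(x$diagnostics$divergences, collapse = " ")))
  if (x$design$outcome_kind == "continuous") {
    sig <- .unscale(x$design, x$draws$sigma, "spread")
    cat(sprintf("  residual sd: mean %.4g (95%% interval %.4g-%.4g)\n",
                mean(sig), quantile(sig, 0.025), quantile(sig, 0.975)))
  }
  invisible(x)
}

#' Effective sample size and split-R-hat
#'
#' ESS is `S / (1 + 2 sum_t rho_t)` with the autocorrelation sum truncated at
#' the first non-positive Geyer pair, pooled over (split) chains. Values
#' above S (antithetic chains) are reported as-is, not clamped.
#'
#' @param x a vector (single chain) or an iterations-by-chains matrix.
#' @return list with `ess` and `rhat`.
#' @export
effective_sample_size <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  niter <- nrow(x)
  if (niter < 10L) stop("need at least 10 draws", call. = FALSE)
  if (all(apply(x, 2L, function(v) var(v) == 0)))
    return(list(ess = NA_real_, rhat = NA_real_, constant = TRUE))
  # split each chain in half
  h <- niter %/% 2L
  xs <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(h), j], x[h + seq_len(h), j])))
  M <- ncol(xs); N <- nrow(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2L, var)
  W <- mean(vars)
  B <- N * var(means)
  var_plus <- (N - 1) / N * W + B / N
  rhat <- sqrt(var_plus / W)
  # chain-averaged autocorrelations, combined multi-chain estimator
  lagmax <- N - 2L
  rho_chain <- vapply(seq_len(M), function(j) {
    a <- acf(xs[, j], lag.max = lagmax, plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a * vars[j]
  }, numeric(lagmax + 1L))
  rho <- 1 - (W - rowMeans(rho_chain)) / var_plus # lags 0..lagmax
  # Geyer: sum successive pairs (rho_2t, rho_2t+1); stop at the first
  # negative pair, enforcing monotone non-increase via a running minimum
  npair <- (length(rho)) %/% 2L
  tau <- 0
  run_min <- Inf
  for (k in seq_len(npair)) {
    p <- rho[2 * k - 1L] + rho[2 * k] # pair (rho_{2k-2}, rho_{2k-1})
    if (k > 1L && p < 0) break
    run_min <- min(run_min, p)
    tau <- tau + run_min
  }
  tau <- max(-1 + 2 * tau, 1e-8) # = 1 + 2 sum_{t>=1} rho_t when rho_0 = 1
  list(ess = (M * N) / tau, rhat = rhat)
}
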