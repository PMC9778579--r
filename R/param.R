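# The parametric multilevel block: Gaussian likelihood with a fixed
# nonparametric offset, normal coefficient priors, exponential scale priors,
# and an LKJ prior on each grouping factor's correlation matrix. Group
# effects are non-centered: lambda_g = D L eta_g with eta_g ~ N(0, I), where
# D is the diagonal of standard deviations and L the Cholesky factor of the
# correlation matrix. All sampling happens on an unconstrained vector; scales
# are log-transformed and the correlation Cholesky factor is parameterized
# through tanh-transformed canonical partial correlations.

#' Reassemble a group-effect covariance matrix from its decomposition
#'
#' Computes `D (L L') D` where `D = diag(sds)` and `L` is the Cholesky factor
#' of the correlation matrix.
#'
#' @param sds vector of standard deviations.
#' @param corr_chol lower-triangular Cholesky factor of the correlation
#'   matrix (unit-norm rows).
#' @return the symmetric positive-definite covariance matrix.
#' @export
reconstruct_sigma_lambda <- function(sds, corr_chol) {
  corr_chol <- as.matrix(corr_chol)
  stopifnot(length(sds) == nrow(corr_chol))
  D <- diag(sds, nrow = length(sds))
  D %*% (corr_chol %*% t(corr_chol)) %*% D
}

# Build L (K x K) from tanh-transformed canonical partial correlations x
# (row-wise, length K(K-1)/2), plus the per-entry partial derivatives needed
# for the gradient.
.chol_from_cpc <- function(x, K) {
  L <- diag(1, K)
  idx <- 0L
  xm <- matrix(0, K, K)
  for (k in seq_len(K)[-1]) {
    run <- 1
    for (j in seq_len(k - 1L)) {
      idx <- idx + 1L
      xm[k, j] <- x[idx]
      L[k, j] <- x[idx] * run
      run <- run * sqrt(1 - x[idx]^2)
    }
    L[k, k] <- run
  }
  list(L = L, xm = xm)
}

# gradient of a scalar function wrt the CPC vector x, given dF/dL (lower
# triangle including diagonal). Row k of L is
#   L[k,j] = x_j * prod_{j'<j} c_j',   L[k,k] = prod_{j'<k} c_j'
# with c = sqrt(1 - x^2), so dL[k,j]/dx_i is prod_{j'<i} c_j' when i == j and
# -L[k,j] x_i / (1 - x_i^2) when i < j (zero otherwise).
.chol_cpc_grad <- function(G_L, xm, K) {
  gx <- numeric(K * (K - 1L) / 2L)
  idx <- 0L
  for (k in seq_len(K)[-1]) {
    xs <- xm[k, seq_len(k - 1L)]
    cs <- sqrt(1 - xs^2)
    Lrow <- numeric(k)
    run <- 1
    for (j in seq_len(k - 1L)) { Lrow[j] <- xs[j] * run; run <- run * cs[j] }
    Lrow[k] <- run
    for (i in seq_len(k - 1L)) {
      idx <- idx + 1L
      g <- G_L[k, i] * (if (i > 1L) prod(cs[seq_len(i - 1L)]) else 1)
      for (j in seq(i + 1L, k))
        g <- g - G_L[k, j] * Lrow[j] * xs[i] / (1 - xs[i]^2)
      gx[idx] <- g
    }
  }
  gx
}

#' Build the parametric-block posterior with gradient
#'
#' Constructs the joint log posterior of the multilevel linear component
#' conditioned on a fixed offset (the current tree-ensemble predictions):
#' `y ~ N(X_beta beta + offset + W lambda, sigma^2 I)`, with per-coefficient
#' normal priors on beta (autoscaled), exponential priors on sigma and the
#' group standard deviations, an LKJ prior on each correlation matrix, and a
#' non-centered parameterization for the group effects. In probit mode `y` is
#' the current latent response and sigma is fixed at 1.
#'
#' @param design a `bartmm_design`.
#' @param offset fixed offset vector of length n.
#' @param priors list with `beta_scale` (scalar multiplier or per-column
#'   vector), `sigma_rate`, `sd_rate`, `lkj_shape`; missing entries are
#'   autoscaled from the model-scale response.
#' @param sigma_fixed fix sigma at this value (e.g. 1 for probit) instead of
#'   sampling it.
#' @return an environment of class `bartmm_param_model` with `lp_grad(theta)`,
#'   `dim`, `pack`/`unpack`, and mutable `set_offset(offset)` /
#'   `set_y(y)` bindings.
#' @export
build_param_model <- function(design, offset = NULL, priors = list(),
                              sigma_fixed = NULL) {
  X <- design$X_beta
  p <- ncol(X)
  groups <- design$W
  for (g in groups) if (g$L < 2L)
    stop("grouping factor '", g$factor,
         "' has a single level: variance unidentifiable", call. = FALSE)
  n <- design$n
  y <- design$y
  if (is.null(offset)) offset <- numeric(n)
  stopifnot(length(offset) == n)

  sdy <- max(sd(y), 1e-3)
  beta_scale <- priors$beta_scale
  if (is.null(beta_scale)) {
    sdx <- apply(X, 2L, sd)
    sdx[sdx == 0] <- 1
    beta_scale <- 2.5 * sdy / sdx
  } else if (length(beta_scale) == 1L) beta_scale <- rep(beta_scale, p)
  sigma_rate <- if (is.null(priors$sigma_rate)) 1 / sdy else priors$sigma_rate
  sd_rate <- if (is.null(priors$sd_rate)) 1 / sdy else priors$sd_rate
  lkj_shape <- if (is.null(priors$lkj_shape)) 1 else priors$lkj_shape

  # parameter layout
  Ks <- vapply(groups, `[[`, 1L, "K")
  Ls <- vapply(groups, `[[`, 1L, "L")
  nz <- (Ks * (Ks - 1L)) %/% 2L
  free_sigma <- is.null(sigma_fixed)
  dim_total <- p + sum(Ls * Ks) + sum(Ks) + sum(nz) + as.integer(free_sigma)

  env <- new.env(parent = emptyenv())
  env$dim <- dim_total
  env$p <- p
  env$groups <- groups
  # per-factor aggregation plans: sorted order + run boundaries, so per-level
  # sums are two O(n) passes instead of a generic rowsum() per gradient call
  env$agg <- lapply(groups, function(g) {
    ord <- order(g$index)
    idx_s <- g$index[ord]
    ends <- which(c(idx_s[-1] != idx_s[-length(idx_s)], TRUE))
    list(ord = ord, ends = ends, lev = idx_s[ends])
  })
  env$offset <- offset
  env$y <- y
  env$priors <- list(beta_scale = beta_scale, sigma_rate = sigma_rate,
                     sd_rate = sd_rate, lkj_shape = lkj_shape)
  env$sigma_fixed <- sigma_fixed
  env$set_offset <- function(o) env$offset <- o
  env$set_y <- function(yy) env$y <- yy

  env$unpack <- function(theta) {
    pos <- 0L
    beta <- theta[seq_len(p)]; pos <- p
    gs <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      K <- Ks[i]; L <- Ls[i]
      eta <- matrix(theta[pos + seq_len(L * K)], L, K); pos <- pos + L * K
      log_sd <- theta[pos + seq_len(K)]; pos <- pos + K
      zc <- if (nz[i] > 0L) theta[pos + seq_len(nz[i])] else numeric(0)
      pos <- pos + nz[i]
      x <- tanh(zc)
      ch <- .chol_from_cpc(x, K)
      d <- exp(log_sd)
      dLc <- d * ch$L # rows of L scaled by the sds
      Lambda <- if (K == 1L) eta * d else eta %*% t(dLc)
      gs[[i]] <- list(eta = eta, log_sd = log_sd, sds = d, z = zc, x = x,
                      Lc = ch$L, dLc = dLc, xm = ch$xm, Lambda = Lambda)
    }
    sigma <- if (free_sigma) exp(theta[pos + 1L]) else sigma_fixed
    list(beta = beta, groups = gs, sigma = sigma,
         log_sigma = if (free_sigma) theta[pos + 1L] else NULL)
  }

  env$pack <- function(beta, group_states, log_sigma = NULL) {
    theta <- beta
    for (i in seq_along(groups))
      theta <- c(theta, as.vector(group_states[[i]]$eta),
                 group_states[[i]]$log_sd, group_states[[i]]$z)
    if (free_sigma) theta <- c(theta, log_sigma)
    theta
  }

  env$fitted <- function(st) {
    fit <- env$offset
    if (p > 0L) fit <- fit + as.vector(X %*% st$beta)
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      Lam <- st$groups[[i]]$Lambda
      fit <- fit + if (g$K == 1L && g$intercept) Lam[g$index]
        else rowSums(g$U * Lam[g$index, , drop = FALSE])
    }
    fit
  }

  # per-level sums of each column of M (n x K) using the aggregation plan
  agg_sum <- function(i, M, L, K) {
    pl <- env$agg[[i]]
    out <- matrix(0, L, K)
    for (k in seq_len(K)) {
      cs <- cumsum(M[pl$ord, k])[pl$ends]
      out[pl$lev, k] <- diff(c(0, cs))
    }
    out
  }

  env$lp_grad <- function(theta) {
    st <- env$unpack(theta)
    sigma <- st$sigma
    sig2 <- sigma^2
    fit <- env$fitted(st)
    r <- env$y - fit
    lp <- -n * log(sigma) - sum(r^2) / (2 * sig2)
    e <- r / sig2
    grad <- numeric(env$dim)
    pos <- 0L
    if (p > 0L) {
      lp <- lp - sum((st$beta / beta_scale)^2) / 2
      grad[seq_len(p)] <- as.vector(crossprod(X, e)) - st$beta / beta_scale^2
    }
    pos <- p
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      gs <- st$groups[[i]]
      K <- Ks[i]; L <- Ls[i]
      # per-level aggregated likelihood gradient wrt Lambda
      A_full <- agg_sum(i, if (K == 1L && g$intercept) matrix(e, ncol = 1L)
                        else g$U * e, L, K)
      # eta
      grad_eta <- A_full %*% gs$dLc - gs$eta
      lp <- lp - sum(gs$eta^2) / 2
      grad[pos + seq_len(L * K)] <- as.vector(grad_eta); pos <- pos + L * K
      # log sds: likelihood + exponential prior + log jacobian
      M <- gs$eta %*% t(gs$Lc)
      grad_d <- colSums(A_full * M)
      lp <- lp + sum(log(sd_rate) - sd_rate * gs$sds + gs$log_sd)
      grad[pos + seq_len(K)] <- grad_d * gs$sds - sd_rate * gs$sds + 1
      pos <- pos + K
      # correlation CPCs
      if (nz[i] > 0L) {
        G_L <- diag(gs$sds, K) %*% (t(A_full) %*% gs$eta) # dlp/dL
        gx_lik <- .chol_cpc_grad(G_L, gs$xm, K)
        # LKJ-Cholesky density + transform jacobian, expressed in the CPCs
        xs <- gs$xm
        gx_prior <- numeric(nz[i])
        idx <- 0L
        for (k in seq_len(K)[-1]) {
          coefk <- K - k + 2 * lkj_shape - 2
          for (j in seq_len(k - 1L)) {
            idx <- idx + 1L
            xx <- xs[k, j]
            lp <- lp + 0.5 * coefk * log(1 - xx^2) +
              0.5 * (k - 1L - j) * log(1 - xx^2) + log(1 - xx^2)
            gx_prior[idx] <- (-xx / (1 - xx^2)) *
              (coefk + (k - 1L - j) + 2)
          }
        }
        dx_dz <- 1 - gs$x^2
        grad[pos + seq_len(nz[i])] <- (gx_lik + gx_prior) * dx_dz
        pos <- pos + nz[i]
      }
    }
    if (free_sigma) {
      # dlp/dlog sigma: likelihood + exponential prior + jacobian
      dls <- -n + sum(r^2) / sig2
      lp <- lp + log(sigma_rate) - sigma_rate * sigma + st$log_sigma
      grad[pos + 1L] <- dls - sigma_rate * sigma + 1
    }
    list(lp = lp, grad = grad)
  }

  class(env) <- "bartmm_param_model"
  env
}

# constrained-scale state extracted from an unconstrained draw
.param_state <- function(model, theta) {
  st <- model$unpack(theta)
  groups <- lapply(seq_along(st$groups), function(i) {
    gs <- st$groups[[i]]
    list(Lambda = gs$Lambda, sds = gs$sds, corr_chol = gs$Lc,
         Sigma = reconstruct_sigma_lambda(gs$sds, gs$Lc))
  })
  names(groups) <- names(model$groups)
  # parametric fit excluding the offset
  fit <- model$fitted(st) - model$offset
  list(beta = st$beta, groups = groups, sigma = st$sigma, theta = theta,
       fit_param = fit)
}

#' Maximum-likelihood-style initialization
#'
#' A cheap approximate fit: ordinary (ridge-fallback) least squares on the
#' combined parametric and tree covariates, followed by one-way
#' moment-of-variance (ANOVA) estimates of the group intercept variances and
#' shrunken group means. Supplies the initial offset for the tree ensemble
#' and the starting parametric state. Binary outcomes use an iteratively
#' reweighted probit fit.
#'
#' @param design a `bartmm_design`.
#' @return list with `offset` (parametric-component fit), `sigma`, `beta`,
#'   `sd_lambda` (per factor), `lambda` (per factor shrunken effects), and
#'   `fitted` (full-design fitted values).
#' @export
ml_init <- function(design) {
  n <- design$n
  Xall <- cbind(`(Intercept)` = 1, design$X_beta, design$X_bart)
  Xall <- Xall[, !duplicated(colnames(Xall)), drop = FALSE]
  y <- design$y
  if (design$outcome_kind == "binary") {
    fit0 <- tryCatch(
      suppressWarnings(stats::glm.fit(Xall, y,
                                      family = stats::binomial("probit"))),
      error = function(e) NULL)
    if (is.null(fit0)) {
      cf <- .ridge_solve(Xall, qnorm(pmin(pmax(y, 0.05), 0.95)))
    } else cf <- coef(fit0)
    cf[!is.finite(cf)] <- 0
    linpred <- as.vector(Xall %*% cf)
    res <- qnorm(pmin(pmax(y, 0.02), 0.98)) - linpred # crude working resid
    sigma_hat <- 1
  } else {
    cf <- .ridge_solve(Xall, y)
    linpred <- as.vector(Xall %*% cf)
    res <- y - linpred
    sigma_hat <- sqrt(max(sum(res^2) / max(n - ncol(Xall), 1L), 1e-12))
  }

  sd_lambda <- list(); lambda <- list()
  for (g in design$W) {
    idx <- g$index
    ng <- tabulate(idx, g$L)
    keep <- ng > 0L
    rbar <- rowsum(res, idx, reorder = FALSE)
    means <- numeric(g$L)
    means[as.integer(rownames(rbar))] <- rbar / pmax(ng[as.integer(rownames(rbar))], 1L)
    gm <- mean(res)
    G_eff <- sum(keep)
    if (G_eff >= 2L) {
      msb <- sum(ng[keep] * (means[keep] - gm)^2) / (G_eff - 1L)
      msw <- sum((res - means[idx])^2) / max(n - G_eff, 1L)
      n_tilde <- (n - sum(ng^2) / n) / (G_eff - 1L)
      s2 <- max(0, (msb - msw) / n_tilde)
    } else { msw <- var(res); s2 <- 0 }
    shrink <- if (s2 > 0) s2 / (s2 + msw / pmax(ng, 1L)) else rep(0, g$L)
    lam <- matrix(0, g$L, g$K)
    if (g$intercept) lam[, 1] <- shrink * means
    sd_lambda[[g$factor]] <- rep(max(sqrt(s2), 0.05 * max(sd(y), 1e-3)), g$K)
    lambda[[g$factor]] <- lam
    res <- res - rowSums(g$U * lam[idx, , drop = FALSE])
  }
  if (length(design$W) > 0L && design$outcome_kind != "binary")
    sigma_hat <- sqrt(max(mean(res^2), 1e-12))

  beta <- if (ncol(design$X_beta) > 0L)
    cf[colnames(design$X_beta)] else numeric(0)
  beta[is.na(beta)] <- 0
  param_fit <- numeric(n)
  if (length(beta) > 0L)
    param_fit <- param_fit + as.vector(design$X_beta %*% beta)
  for (g in design$W)
    param_fit <- param_fit +
      rowSums(g$U * lambda[[g$factor]][g$index, , drop = FALSE])

  list(offset = param_fit, sigma = sigma_hat, beta = unname(beta),
       sd_lambda = sd_lambda, lambda = lambda, fitted = linpred)
}

.ridge_solve <- function(X, y) {
  fit <- tryCatch({
    qr_ <- qr(X)
    if (qr_$rank < ncol(X)) stop("singular")
    qr.coef(qr_, y)
  }, error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) {
    XtX <- crossprod(X)
    lam <- 1e-6 * mean(diag(XtX))
    fit <- solve(XtX + diag(lam + 1e-12, ncol(X)), crossprod(X, y))[, 1]
  }
  stats::setNames(as.vector(fit), colnames(X))
}
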