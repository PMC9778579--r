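# Sum-of-trees model with the standard regularization prior. Trees are flat
# matrices with columns (var, split, value, left, right); var == 0 marks a
# leaf, links are 1-based row indices, and observations with x <= split route
# left. All tree computation happens on the rescaled [-0.5, 0.5] outcome.

.new_leaf_tree <- function(value = 0) {
  matrix(c(0, 0, value, 0, 0), 1, 5,
         dimnames = list(NULL, c("var", "split", "value", "left", "right")))
}

.tree_depths <- function(tree) {
  k <- nrow(tree)
  depth <- integer(k)
  if (k == 1L) return(depth)
  parent <- integer(k)
  for (i in seq_len(k)) if (tree[i, "var"] != 0) {
    parent[tree[i, "left"]] <- i
    parent[tree[i, "right"]] <- i
  }
  for (i in seq_len(k)[-1]) {
    p <- parent[i]; d <- 0L
    while (p != 0L) { d <- d + 1L; p <- parent[p] }
    depth[i] <- d
  }
  depth
}

#' Calibrate the ensemble hyperparameters
#'
#' Sets the leaf-value prior scale so that `k_shrink` prior standard
#' deviations of the ensemble sum span half the rescaled response range
#' (`sigma_mu = 0.5 / (k_shrink * sqrt(m))`), and solves the residual-variance
#' prior scale so that `Pr(sigma < sigma_hat) = q` under a scaled-inverse-
#' chi-squared(nu, lambda_cal) prior, with `sigma_hat` an initial residual-sd
#' estimate.
#'
#' @param y rescaled outcome (used for the default `sigma_hat`).
#' @param m number of trees.
#' @param k_shrink leaf shrinkage factor (default 2).
#' @param nu,q residual-variance prior degrees of freedom and quantile.
#' @param alpha_split,beta_split depth-prior parameters.
#' @param sigma_hat optional residual-sd estimate; defaults to `sd(y)`.
#' @return a list of hyperparameter settings.
#' @export
calibrate_hyperparams <- function(y, m = 200L, k_shrink = 2, nu = 3, q = 0.9,
                                  alpha_split = 0.95, beta_split = 2,
                                  sigma_hat = NULL) {
  stopifnot(m >= 1L, q > 0, q < 1, nu > 0, k_shrink > 0)
  if (is.null(sigma_hat)) sigma_hat <- sd(y)
  if (!is.finite(sigma_hat) || sigma_hat <= 0)
    stop("calibration error: non-finite residual sd estimate", call. = FALSE)
  list(
    m = as.integer(m), k_shrink = k_shrink, nu = nu, q = q,
    alpha_split = alpha_split, beta_split = beta_split,
    sigma_mu = 0.5 / (k_shrink * sqrt(m)),
    lambda_cal = sigma_hat^2 * qchisq(1 - q, nu) / nu
  )
}

#' Log prior probability of a tree topology
#'
#' A node at depth `d` splits with probability
#' `alpha_split * (1 + d)^(-beta_split)`. When cutpoint grids are supplied,
#' the uniform split-variable/cutpoint choice terms are included as well.
#'
#' @param tree a tree matrix.
#' @param alpha_split,beta_split depth-prior parameters.
#' @param cutpoints optional list of per-column cutpoint grids.
#' @return the log prior (a real number).
#' @export
tree_log_prior <- function(tree, alpha_split = 0.95, beta_split = 2,
                           cutpoints = NULL) {
  stopifnot(alpha_split > 0, alpha_split < 1, beta_split >= 0)
  depth <- .tree_depths(tree)
  psplit <- alpha_split * (1 + depth)^(-beta_split)
  internal <- tree[, "var"] != 0
  lp <- sum(log(psplit[internal])) + sum(log(1 - psplit[!internal]))
  if (!is.null(cutpoints)) {
    V <- sum(vapply(cutpoints, length, 1L) > 0L)
    for (i in which(internal))
      lp <- lp - log(V) - log(length(cutpoints[[tree[i, "var"]]]))
  }
  lp
}

#' Integrated (marginal) log-likelihood of one leaf
#'
#' Computes `log integral prod_i N(r_i | mu, sigma^2) N(mu | 0, sigma_mu^2)
#' dmu` in closed form. An empty residual set returns 0 (the log of an empty
#' product); proposal mechanisms must nonetheless treat empty leaves as
#' invalid.
#'
#' @param residuals residual vector assigned to the leaf.
#' @param sigma residual standard deviation.
#' @param sigma_mu leaf-value prior standard deviation.
#' @return the marginal log-likelihood.
#' @export
node_marginal_loglik <- function(residuals, sigma, sigma_mu) {
  stopifnot(sigma > 0, sigma_mu > 0)
  n <- length(residuals)
  if (n == 0L) return(0)
  s <- sum(residuals)
  sig2 <- sigma^2; smu2 <- sigma_mu^2
  -n / 2 * log(2 * pi * sig2) - sum(residuals^2) / (2 * sig2) +
    0.5 * log(sig2 / (sig2 + n * smu2)) +
    smu2 * s^2 / (2 * sig2 * (sig2 + n * smu2))
}

.default_moves <- c(grow = 0.25, prune = 0.25, change = 0.50)

#' One Metropolis-Hastings update of a single tree
#'
#' Proposes one GROW, PRUNE, or CHANGE move evaluated through the integrated
#' leaf likelihood, the depth prior, and the proposal ratio; proposals that
#' create an empty leaf are rejected outright. Leaf values are then redrawn
#' from their conjugate normal posteriors regardless of acceptance.
#'
#' @param tree a tree matrix.
#' @param X tree design matrix (training rows).
#' @param cutpoints per-column cutpoint grids.
#' @param resid partial residuals: working response minus the fit of all
#'   other trees.
#' @param sigma,sigma_mu current residual sd and leaf prior sd.
#' @param alpha_split,beta_split depth-prior parameters.
#' @param moves move mixture `c(grow, prune, change)`.
#' @param max_depth optional hard depth cap (0 = none), used by validation
#'   oracles.
#' @param prior_only if TRUE the likelihood is switched off and the sampler
#'   targets the tree prior.
#' @return list with elements `tree`, `fit` (per-row contribution), and
#'   `accepted`.
#' @export
update_tree <- function(tree, X, cutpoints, resid, sigma, sigma_mu,
                        alpha_split = 0.95, beta_split = 2,
                        moves = .default_moves, max_depth = 0L,
                        prior_only = FALSE) {
  if (any(!is.finite(resid))) stop("non-finite residuals", call. = FALSE)
  out <- .bart_sweep_cpp(list(tree), matrix(0, nrow(X), 1), X, cutpoints,
                         resid, sigma, sigma_mu, alpha_split, beta_split,
                         moves[[1]], moves[[2]], as.integer(max_depth),
                         prior_only, 1L)
  list(tree = out$trees[[1]], fit = out$total_fit,
       accepted = out$accepts > 0L)
}

#' One Bayesian-backfitting sweep over all trees
#'
#' Applies [update_tree()] to trees `j = 1..m` in order against the partial
#' residuals of the remaining trees, maintaining the total fit incrementally.
#'
#' @param state an ensemble state from [ensemble_init()].
#' @param y_working the outcome minus any external offset, on model scale.
#' @param prior_only see [update_tree()].
#' @return the updated ensemble state.
#' @export
backfit_sweep <- function(state, y_working, prior_only = FALSE) {
  if (any(!is.finite(y_working)))
    stop("non-finite working response", call. = FALSE)
  h <- state$hyper
  if (!is.null(state$ptr)) { # persistent ensemble: in-place, same RNG order
    state$accepts <- .bart_state_sweep(state$ptr, y_working, state$sigma,
                                       h$sigma_mu, h$alpha_split,
                                       h$beta_split, state$moves[[1]],
                                       state$moves[[2]],
                                       as.integer(state$max_depth),
                                       prior_only)
    state$total_fit <- .bart_state_total(state$ptr)
    return(state)
  }
  out <- .bart_sweep_cpp(state$trees, state$tree_fits, state$X,
                         state$cutpoints, y_working, state$sigma, h$sigma_mu,
                         h$alpha_split, h$beta_split,
                         state$moves[[1]], state$moves[[2]],
                         as.integer(state$max_depth), prior_only, 0L)
  state$trees <- out$trees
  state$tree_fits <- out$tree_fits
  state$total_fit <- out$total_fit
  state$accepts <- out$accepts
  state
}

#' Draw the residual standard deviation (standalone mode)
#'
#' Draws sigma^2 from its conjugate scaled-inverse-chi-squared full
#' conditional. Inside the coupled sampler sigma is drawn by the parametric
#' block instead and the ensemble runs with fixed variance.
#'
#' @param residuals current residuals (outcome minus total fit).
#' @param nu,lambda_cal prior degrees of freedom and scale.
#' @return a positive draw of sigma.
#' @export
draw_sigma <- function(residuals, nu, lambda_cal) {
  n <- length(residuals)
  sqrt((nu * lambda_cal + sum(residuals^2)) / rchisq(1L, nu + n))
}

#' Truncated-normal latent update for binary outcomes
#'
#' Draws the latent continuous response underlying a probit model: from
#' `N(mean_i, 1)` truncated to `(0, Inf)` when `y_i = 1` and to `(-Inf, 0]`
#' when `y_i = 0`.
#'
#' @param y_binary 0/1 outcome vector.
#' @param mean current total fit (all model components).
#' @return latent continuous vector with signs consistent with `y_binary`.
#' @export
probit_latent_update <- function(y_binary, mean) {
  n <- length(y_binary)
  p0 <- pnorm(-mean) # mass below 0
  u <- runif(n)
  pu <- ifelse(y_binary == 1, p0 + u * (1 - p0), u * p0)
  pu <- pmin(pmax(pu, 1e-12), 1 - 1e-12)
  mean + qnorm(pu)
}

#' Predict from a tree ensemble
#'
#' Sums each tree's leaf value along the routing path for every row of
#' `X_new`, on model scale. Points beyond the training range follow the same
#' step function as the nearest training extreme.
#'
#' @param state an ensemble state (or a bare list of tree matrices).
#' @param X_new matrix with the training columns.
#' @return fitted vector.
#' @export
predict_ensemble <- function(state, X_new) {
  p_train <- if (is.list(state) && !is.null(state$X)) ncol(state$X) else NULL
  if (!is.null(p_train) && ncol(X_new) != p_train)
    stop("column mismatch: expected ", p_train, " columns", call. = FALSE)
  if (is.list(state) && !is.null(state$ptr))
    return(.bart_state_predict(state$ptr, X_new))
  trees <- if (is.list(state) && !is.null(state$trees)) state$trees else state
  .bart_predict_cpp(trees, X_new)
}

# draw one tree from the regularization prior (used for chain initialization)
.prior_tree_draw <- function(X, cutpoints, alpha_split, beta_split, sigma_mu,
                             max_depth = 0L) {
  splittable <- which(vapply(cutpoints, length, 1L) > 0L)
  rows <- list() # grown as list of c(var, split, value, left, right)
  grow_node <- function(obs, depth) {
    id <- length(rows) + 1L
    rows[[id]] <<- c(0, 0, rnorm(1L, 0, sigma_mu), 0, 0)
    can_split <- length(splittable) > 0L && length(obs) >= 2L &&
      (max_depth <= 0L || depth < max_depth)
    if (can_split && runif(1L) < alpha_split * (1 + depth)^(-beta_split)) {
      v <- splittable[sample.int(length(splittable), 1L)]
      cuts <- cutpoints[[v]]
      cc <- cuts[sample.int(length(cuts), 1L)]
      left_obs <- obs[X[obs, v] <= cc]
      right_obs <- obs[X[obs, v] > cc]
      if (length(left_obs) > 0L && length(right_obs) > 0L) {
        lid <- grow_node(left_obs, depth + 1L)
        rid <- grow_node(right_obs, depth + 1L)
        rows[[id]] <<- c(v, cc, 0, lid, rid)
      }
    }
    id
  }
  grow_node(seq_len(nrow(X)), 0L)
  m <- do.call(rbind, rows)
  colnames(m) <- c("var", "split", "value", "left", "right")
  m
}

#' Initialize an ensemble state
#'
#' Trees are drawn from the regularization prior (leaf values from
#' `N(0, sigma_mu^2)`).
#'
#' @param X tree design matrix.
#' @param cutpoints per-column cutpoint grids.
#' @param hyper hyperparameters from [calibrate_hyperparams()].
#' @param sigma initial residual sd (model scale).
#' @param from_prior draw initial topologies from the prior (default) or
#'   start at single leaves.
#' @param max_depth optional hard depth cap for validation runs.
#' @param moves move mixture.
#' @param persistent keep the ensemble in compiled storage (reference
#'   semantics, no per-sweep conversion); used by the chain runner. The
#'   `trees`/`tree_fits` fields then go stale after sweeps -- use
#'   [ensemble_trees()] to read them back.
#' @return an ensemble state list.
#' @export
ensemble_init <- function(X, cutpoints, hyper, sigma,
                          from_prior = TRUE, max_depth = 0L,
                          moves = .default_moves, persistent = FALSE) {
  m <- hyper$m
  trees <- vector("list", m)
  for (j in seq_len(m))
    trees[[j]] <- if (from_prior)
      .prior_tree_draw(X, cutpoints, hyper$alpha_split, hyper$beta_split,
                       hyper$sigma_mu, max_depth)
    else .new_leaf_tree()
  tree_fits <- vapply(trees, function(t) .bart_predict_cpp(list(t), X),
                      numeric(nrow(X)))
  tree_fits <- matrix(tree_fits, nrow(X), m)
  st <- structure(list(trees = trees, tree_fits = tree_fits,
                       total_fit = rowSums(tree_fits),
                       sigma = sigma, hyper = hyper, X = X,
                       cutpoints = cutpoints,
                       max_depth = as.integer(max_depth), moves = moves,
                       ptr = NULL),
                  class = "bartmm_ensemble")
  if (persistent && m > 0L)
    st$ptr <- .bart_state_new(trees, X, cutpoints)
  st
}

#' Current tree matrices of an ensemble state
#' @param state an ensemble state.
#' @return list of tree matrices.
#' @export
ensemble_trees <- function(state) {
  if (!is.null(state$ptr)) .bart_state_trees(state$ptr) else state$trees
}

#' Serialize an ensemble to a JSON tree dump
#' @param state an ensemble state.
#' @return a JSON string with topology, split rules, and leaf values.
#' @export
ensemble_to_json <- function(state) {
  jsonlite::toJSON(lapply(ensemble_trees(state), function(t)
    as.data.frame(t)), dataframe = "columns", digits = NA)
}

# Log acceptance ratios of the tree moves, mirrored in R for detailed-balance
# diagnostics (the sampler itself runs in compiled code). `move` is "grow"
# with (leaf, var, cut) or "prune" with (node).
.tree_move_logratio <- function(tree, X, cutpoints, resid, sigma, sigma_mu,
                                alpha_split, beta_split, moves, move,
                                leaf = NULL, var = NULL, cut = NULL,
                                node = NULL, max_depth = 0L) {
  depth <- .tree_depths(tree)
  leaves <- which(tree[, "var"] == 0)
  growable <- leaves[max_depth <= 0L | depth[leaves] < max_depth]
  is_nog <- function(t, i) t[i, "var"] != 0 &&
    t[t[i, "left"], "var"] == 0 && t[t[i, "right"], "var"] == 0
  nogs <- Filter(function(i) is_nog(tree, i), which(tree[, "var"] != 0))
  route_all <- function(t) {
    vapply(seq_len(nrow(X)), function(i) {
      nd <- 1L
      while (t[nd, "var"] != 0)
        nd <- as.integer(if (X[i, t[nd, "var"]] <= t[nd, "split"])
          t[nd, "left"] else t[nd, "right"])
      nd
    }, 1L)
  }
  mll <- function(idx) node_marginal_loglik(resid[idx], sigma, sigma_mu)
  lf_of <- route_all(tree)
  if (move == "grow") {
    obs <- which(lf_of == leaf)
    goleft <- X[obs, var] <= cut
    if (!any(goleft) || all(goleft)) return(-Inf)
    d <- depth[leaf]
    psd <- alpha_split * (1 + d)^(-beta_split)
    psd1 <- alpha_split * (2 + d)^(-beta_split)
    loglik <- mll(obs[goleft]) + mll(obs[!goleft]) - mll(obs)
    logprior <- log(psd) + 2 * log(1 - psd1) - log(1 - psd)
    parent <- 0L
    for (i in which(tree[, "var"] != 0))
      if (tree[i, "left"] == leaf || tree[i, "right"] == leaf) parent <- i
    nog_after <- length(nogs) + 1L -
      (parent != 0L && is_nog(tree, parent))
    loglik + logprior + log(moves[["prune"]]) - log(nog_after) -
      log(moves[["grow"]]) + log(length(growable))
  } else {
    l <- tree[node, "left"]; r <- tree[node, "right"]
    d <- depth[node]
    psd <- alpha_split * (1 + d)^(-beta_split)
    psd1 <- alpha_split * (2 + d)^(-beta_split)
    obs_l <- which(lf_of == l); obs_r <- which(lf_of == r)
    loglik <- mll(c(obs_l, obs_r)) - mll(obs_l) - mll(obs_r)
    logprior <- -(log(psd) + 2 * log(1 - psd1) - log(1 - psd))
    G_after <- length(growable) + 1L -
      2L * (max_depth <= 0L || d + 1L < max_depth)
    loglik + logprior + log(moves[["grow"]]) - log(G_after) -
      log(moves[["prune"]]) + log(length(nogs))
  }
}
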