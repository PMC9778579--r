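# No-U-turn Hamiltonian sampler over a differentiable log posterior, with a
# diagonal Euclidean metric. The trajectory doubles forward/backward in time
# until the endpoints start moving toward each other; the next state is
# chosen by multinomial sampling over the visited states weighted by
# exp(-energy error). Stepsize is tuned by dual averaging during warm-up and
# the metric from windowed draws, following the standard three-phase scheme.

.DIVERGENCE_NATS <- 1000

#' One no-U-turn transition
#'
#' @param lp_grad function of the position vector returning
#'   `list(lp =, grad =)`.
#' @param position current unconstrained position.
#' @param stepsize leapfrog stepsize (> 0).
#' @param inv_metric diagonal of the inverse metric (posterior-variance
#'   estimates); momentum is drawn from `N(0, inv_metric^-1)`.
#' @param max_depth maximum number of trajectory doublings (default 10).
#' @return list with `position`, `lp`, `accept_stat` (mean Metropolis-like
#'   acceptance over the trajectory), `divergent`, `depth`, `n_leapfrog`.
#' @export
nuts_transition <- function(lp_grad, position, stepsize, inv_metric = NULL,
                            max_depth = 10L) {
  stopifnot(stepsize > 0)
  d <- length(position)
  if (is.null(inv_metric)) inv_metric <- rep(1, d)
  stopifnot(all(inv_metric > 0))

  cur <- lp_grad(position)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at current position")
  p0 <- rnorm(d) / sqrt(inv_metric)
  H0 <- -cur$lp + sum(p0^2 * inv_metric) / 2

  leapfrog <- function(q, p, grad, eps) {
    p1 <- p + eps / 2 * grad
    q1 <- q + eps * (inv_metric * p1)
    g1 <- lp_grad(q1)
    if (!all(is.finite(g1$grad)) || !is.finite(g1$lp))
      return(list(q = q1, p = p1, lp = -Inf, grad = rep(0, d), bad = TRUE))
    p2 <- p1 + eps / 2 * g1$grad
    list(q = q1, p = p2, lp = g1$lp, grad = g1$grad, bad = FALSE)
  }

  n_leapfrog <- 0L
  sum_accept <- 0
  n_accept <- 0L

  # subtree built recursively; returns endpoints, a multinomial sample, the
  # log weight (logsumexp of -energy errors), and validity flags
  build <- function(q, p, grad, lp, dir, depth) {
    if (depth == 0L) {
      st <- leapfrog(q, p, grad, dir * stepsize)
      n_leapfrog <<- n_leapfrog + 1L
      H <- if (st$bad) Inf else -st$lp + sum(st$p^2 * inv_metric) / 2
      err <- H - H0
      divergent <- !is.finite(err) || err > .DIVERGENCE_NATS
      sum_accept <<- sum_accept + min(1, exp(min(0, -err)))
      n_accept <<- n_accept + 1L
      list(q_minus = st$q, p_minus = st$p, grad_minus = st$grad,
           lp_minus = st$lp,
           q_plus = st$q, p_plus = st$p, grad_plus = st$grad,
           lp_plus = st$lp,
           q_sample = st$q, lp_sample = st$lp,
           log_w = if (divergent) -Inf else -err,
           divergent = divergent, turning = FALSE)
    } else {
      t1 <- build(q, p, grad, lp, dir, depth - 1L)
      if (t1$divergent || t1$turning) return(t1)
      if (dir > 0) {
        t2 <- build(t1$q_plus, t1$p_plus, t1$grad_plus, t1$lp_plus, dir,
                    depth - 1L)
        out <- list(q_minus = t1$q_minus, p_minus = t1$p_minus,
                    grad_minus = t1$grad_minus, lp_minus = t1$lp_minus,
                    q_plus = t2$q_plus, p_plus = t2$p_plus,
                    grad_plus = t2$grad_plus, lp_plus = t2$lp_plus)
      } else {
        t2 <- build(t1$q_minus, t1$p_minus, t1$grad_minus, t1$lp_minus, dir,
                    depth - 1L)
        out <- list(q_minus = t2$q_minus, p_minus = t2$p_minus,
                    grad_minus = t2$grad_minus, lp_minus = t2$lp_minus,
                    q_plus = t1$q_plus, p_plus = t1$p_plus,
                    grad_plus = t1$grad_plus, lp_plus = t1$lp_plus)
      }
      out$divergent <- t2$divergent
      lw <- .logsumexp(t1$log_w, t2$log_w)
      pick2 <- is.finite(t2$log_w) &&
        log(runif(1L)) < t2$log_w - lw
      out$q_sample <- if (pick2) t2$q_sample else t1$q_sample
      out$lp_sample <- if (pick2) t2$lp_sample else t1$lp_sample
      out$log_w <- lw
      dq <- out$q_plus - out$q_minus
      out$turning <- t2$turning ||
        sum(dq * (inv_metric * out$p_minus)) < 0 ||
        sum(dq * (inv_metric * out$p_plus)) < 0
      out
    }
  }

  traj <- list(q_minus = position, p_minus = p0, grad_minus = cur$grad,
               lp_minus = cur$lp,
               q_plus = position, p_plus = p0, grad_plus = cur$grad,
               lp_plus = cur$lp,
               q_sample = position, lp_sample = cur$lp, log_w = 0,
               divergent = FALSE, turning = FALSE)
  depth <- 0L
  divergent <- FALSE
  while (depth < max_depth) {
    dir <- if (runif(1L) < 0.5) -1 else 1
    sub <- if (dir > 0)
      build(traj$q_plus, traj$p_plus, traj$grad_plus, traj$lp_plus, dir, depth)
    else
      build(traj$q_minus, traj$p_minus, traj$grad_minus, traj$lp_minus, dir,
            depth)
    if (sub$divergent) { divergent <- TRUE; break }
    if (!sub$turning) {
      # biased progressive sampling toward the new subtree
      if (is.finite(sub$log_w) &&
          log(runif(1L)) < sub$log_w - traj$log_w) {
        traj$q_sample <- sub$q_sample
        traj$lp_sample <- sub$lp_sample
      }
    }
    if (dir > 0) {
      traj$q_plus <- sub$q_plus; traj$p_plus <- sub$p_plus
      traj$grad_plus <- sub$grad_plus; traj$lp_plus <- sub$lp_plus
    } else {
      traj$q_minus <- sub$q_minus; traj$p_minus <- sub$p_minus
      traj$grad_minus <- sub$grad_minus; traj$lp_minus <- sub$lp_minus
    }
    traj$log_w <- .logsumexp(traj$log_w, sub$log_w)
    dq <- traj$q_plus - traj$q_minus
    turning <- sub$turning ||
      sum(dq * (inv_metric * traj$p_minus)) < 0 ||
      sum(dq * (inv_metric * traj$p_plus)) < 0
    depth <- depth + 1L
    if (turning) break
  }

  list(position = traj$q_sample, lp = traj$lp_sample,
       accept_stat = if (n_accept > 0L) sum_accept / n_accept else 0,
       divergent = divergent, depth = depth, n_leapfrog = n_leapfrog)
}

.logsumexp <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(-Inf)
  m + log(exp(a - m) + exp(b - m))
}

# reasonable initial stepsize: double/halve until the one-step acceptance
# crosses 0.5 (standard heuristic)
.init_stepsize <- function(lp_grad, position, inv_metric) {
  d <- length(position)
  eps <- 0.1
  cur <- lp_grad(position)
  p0 <- rnorm(d) / sqrt(inv_metric)
  H0 <- -cur$lp + sum(p0^2 * inv_metric) / 2
  one <- function(eps) {
    p1 <- p0 + eps / 2 * cur$grad
    q1 <- position + eps * (inv_metric * p1)
    g1 <- lp_grad(q1)
    if (!is.finite(g1$lp) || !all(is.finite(g1$grad))) return(-Inf)
    p2 <- p1 + eps / 2 * g1$grad
    -( -g1$lp + sum(p2^2 * inv_metric) / 2 - H0)
  }
  a <- one(eps)
  dir <- if (is.finite(a) && a > log(0.5)) 1 else -1
  for (i in 1:30) {
    eps2 <- eps * 2^dir
    a2 <- one(eps2)
    if (dir > 0 && !(is.finite(a2) && a2 > log(0.5))) break
    if (dir < 0 && (is.finite(a2) && a2 > log(0.5))) { eps <- eps2; break }
    eps <- eps2
  }
  eps
}

# --- warm-up adaptation ------------------------------------------------------

# mutable adapter: dual-averaging stepsize + windowed diagonal metric
.adapter_new <- function(dim, iters, target_accept = 0.8, eps0 = 0.1,
                         gamma = 0.05, t0 = 10, kappa = 0.75) {
  ad <- new.env(parent = emptyenv())
  ad$dim <- dim
  ad$target <- target_accept
  ad$eps <- eps0
  ad$mu <- log(10 * eps0)
  ad$log_eps_bar <- log(eps0)
  ad$H_bar <- 0
  ad$count <- 0L
  ad$gamma <- gamma; ad$t0 <- t0; ad$kappa <- kappa
  ad$inv_metric <- rep(1, dim)
  ad$iters <- iters
  # three-phase windows: fast start, expanding slow windows, fast end
  init_buf <- max(10L, round(0.15 * iters))
  term_buf <- max(10L, round(0.10 * iters))
  slow <- iters - init_buf - term_buf
  ends <- integer(0)
  if (slow > 20L) {
    w <- max(15L, round(slow / 7))
    pos <- init_buf
    while (pos + w < init_buf + slow) {
      pos <- pos + w
      ends <- c(ends, pos)
      w <- 2L * w
    }
    ends <- c(ends[ends < init_buf + slow], init_buf + slow)
    ends <- unique(ends)
  } else if (slow > 0L) ends <- init_buf + slow
  ad$window_ends <- ends
  ad$init_buf <- init_buf
  ad$win_sum <- rep(0, dim); ad$win_sumsq <- rep(0, dim); ad$win_n <- 0L
  ad$divergences <- 0L
  ad$recent_div <- 0L
  ad$since_reset <- 0L
  ad
}

.adapter_update <- function(ad, theta, accept_stat, divergent = FALSE) {
  ad$count <- ad$count + 1L
  t <- ad$count
  if (divergent) { ad$divergences <- ad$divergences + 1L
                   ad$recent_div <- ad$recent_div + 1L }
  ad$since_reset <- ad$since_reset + 1L
  # dual averaging
  eta <- 1 / (t + ad$t0)
  ad$H_bar <- (1 - eta) * ad$H_bar + eta * (ad$target - accept_stat)
  log_eps <- ad$mu - sqrt(t) / ad$gamma * ad$H_bar
  w <- t^(-ad$kappa)
  ad$log_eps_bar <- w * log_eps + (1 - w) * ad$log_eps_bar
  ad$eps <- exp(log_eps)
  # metric accumulation inside slow windows
  in_slow <- length(ad$window_ends) > 0L &&
    t > ad$init_buf && t <= max(ad$window_ends)
  if (in_slow) {
    ad$win_sum <- ad$win_sum + theta
    ad$win_sumsq <- ad$win_sumsq + theta^2
    ad$win_n <- ad$win_n + 1L
  }
  if (t %in% ad$window_ends && ad$win_n >= 10L) {
    nn <- ad$win_n
    v <- (ad$win_sumsq - ad$win_sum^2 / nn) / (nn - 1)
    ad$inv_metric <- (nn / (nn + 5)) * pmax(v, 1e-10) +
      (5 / (nn + 5)) * 1e-3
    ad$win_sum <- rep(0, ad$dim); ad$win_sumsq <- rep(0, ad$dim)
    ad$win_n <- 0L
    # restart dual averaging around the current stepsize
    ad$mu <- log(10 * ad$eps)
    ad$H_bar <- 0
    if (ad$since_reset > 0L && ad$recent_div > 0.5 * ad$since_reset) {
      warning("persistent divergences during warm-up; shrinking stepsize")
      ad$eps <- ad$eps / 2
    }
    ad$recent_div <- 0L
    ad$since_reset <- 0L
  }
  if (t == ad$iters) ad$eps <- exp(ad$log_eps_bar)
  invisible(ad)
}

#' Warm-up adaptation on a fixed target
#'
#' Runs `iters` no-U-turn transitions with dual-averaging stepsize adaptation
#' toward `target_accept` and windowed diagonal-metric estimation, returning
#' the adapted settings and the final state.
#'
#' @param lp_grad log-posterior-with-gradient function (or a
#'   `bartmm_param_model`).
#' @param init initial position.
#' @param iters number of warm-up iterations (>= 20).
#' @param target_accept target acceptance statistic (default 0.8).
#' @param max_depth trajectory doubling cap.
#' @return list with `stepsize`, `inv_metric`, `state`, `accept_stats`,
#'   `divergences`.
#' @export
warmup_adapt <- function(lp_grad, init, iters, target_accept = 0.8,
                         max_depth = 10L) {
  stopifnot(iters >= 20L)
  if (inherits(lp_grad, "bartmm_param_model")) {
    model <- lp_grad
    lp_grad <- model$lp_grad
  }
  eps0 <- .init_stepsize(lp_grad, init, rep(1, length(init)))
  ad <- .adapter_new(length(init), iters, target_accept, eps0)
  theta <- init
  accepts <- numeric(iters)
  for (t in seq_len(iters)) {
    tr <- nuts_transition(lp_grad, theta, ad$eps, ad$inv_metric, max_depth)
    theta <- tr$position
    accepts[t] <- tr$accept_stat
    .adapter_update(ad, theta, tr$accept_stat, tr$divergent)
  }
  list(stepsize = ad$eps, inv_metric = ad$inv_metric, state = theta,
       accept_stats = accepts, divergences = ad$divergences)
}

#' One joint draw of the parametric block
#'
#' A single no-U-turn transition over all parametric unknowns (coefficients,
#' group effects, scales, correlations, residual sd), returning the
#' constrained-scale state.
#'
#' @param model a `bartmm_param_model` (bound to the current offset).
#' @param theta current unconstrained position.
#' @param stepsize,inv_metric adapted sampler settings.
#' @param max_depth trajectory doubling cap.
#' @return list with the constrained `state` (beta, group effects, sigma,
#'   sds, correlation Cholesky factors, parametric fit), the new `theta`,
#'   and transition diagnostics.
#' @export
draw_param_block <- function(model, theta, stepsize, inv_metric = NULL,
                             max_depth = 10L) {
  tr <- nuts_transition(model$lp_grad, theta, stepsize, inv_metric, max_depth)
  st <- .param_state(model, tr$position)
  list(state = st, theta = tr$position, accept_stat = tr$accept_stat,
       divergent = tr$divergent, lp = tr$lp)
}
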