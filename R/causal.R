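# Causal estimands from a fit on observed data plus a flipped-treatment test
# table. Posterior draws of each unit's expected outcome under treatment and
# control are recombined from the observed-arm and counterfactual-arm draws:
# mu1 = z * mu_obs + (1 - z) * mu_cf and mu0 = (1 - z) * mu_obs + z * mu_cf.

#' Posterior draws of individual conditional average treatment effects
#'
#' Requires a fit whose test table was the flipped-treatment copy of the
#' training table. Returns per-unit, per-draw `mu1 - mu0` on the original
#' outcome scale; the recombined `mu1`/`mu0` matrices are attached as
#' attributes.
#'
#' @param fit a `bartmm_fit` with test draws.
#' @param z observed 0/1 treatment vector (defaults to the design's).
#' @return an n-by-samples matrix of iCATE draws.
#' @export
icate_draws <- function(fit, z = NULL) {
  if (is.null(z)) z <- fit$design$z
  if (is.null(z)) stop("no treatment vector available", call. = FALSE)
  mu_obs <- extract(fit, sample = "train", value = "ev")
  mu_cf <- extract(fit, sample = "test", value = "ev")
  mu1 <- z * mu_obs + (1 - z) * mu_cf
  mu0 <- (1 - z) * mu_obs + z * mu_cf
  out <- mu1 - mu0
  attr(out, "mu1") <- mu1
  attr(out, "mu0") <- mu0
  out
}

#' Average a draw matrix of unit-level effects over a subset
#'
#' Per-draw means over the subset give the estimand's posterior draws; the
#' point estimate is their mean and the default interval is
#' `point +/- 1.96 * sd(draws)` (a percentile interval is also returned).
#' With the all-units mask this yields the CATE; with the treated mask a
#' SATT-style conditional effect; with group masks the GSATE/GSATT.
#'
#' @param draws n-by-samples matrix of unit-level effect draws.
#' @param subset logical or integer unit mask (default: all units).
#' @param level interval level (default 0.95 with the 1.96 normal constant).
#' @return an object of class `bartmm_estimand` with `point`, `interval`,
#'   `percentile`, `draws`, `n_units`.
#' @export
average_effect <- function(draws, subset = NULL, level = 0.95) {
  if (is.null(subset)) subset <- seq_len(nrow(draws))
  if (is.logical(subset)) subset <- which(subset)
  if (length(subset) == 0L)
    stop("empty estimand subset (e.g. a group with no treated units)",
         call. = FALSE)
  ed <- colMeans(draws[subset, , drop = FALSE])
  point <- mean(ed)
  sdd <- sd(ed)
  zq <- if (identical(level, 0.95)) 1.96 else qnorm(1 - (1 - level) / 2)
  a <- (1 - level) / 2
  structure(list(
    point = point,
    interval = c(lb = point - zq * sdd, ub = point + zq * sdd),
    percentile = unname(quantile(ed, c(a, 1 - a))),
    sd = sdd, draws = ed, n_units = length(subset)
  ), class = "bartmm_estimand")
}

#' @export
print.bartmm_estimand <- function(x, ...) {
  cat(sprintf("estimate %.4g  [%.4g, %.4g]  (sd %.4g, %d units, %d draws)\n",
              x$point, x$interval[1], x$interval[2], x$sd, x$n_units,
              length(x$draws)))
  invisible(x)
}

#' Sample average treatment effect on the treated and friends
#'
#' Convenience wrappers over [icate_draws()] + [average_effect()].
#'
#' @param fit a `bartmm_fit` with test draws.
#' @param z treatment vector (defaults to the design's).
#' @param groups factor/vector of group labels for the group-level versions.
#' @return `satt`/`cate`: a `bartmm_estimand`; `gsatt`/`gsate`: a named list
#'   with one entry per group (`NULL` where a group has no treated units).
#' @export
satt <- function(fit, z = NULL) {
  if (is.null(z)) z <- fit$design$z
  average_effect(icate_draws(fit, z), subset = z == 1)
}

#' @rdname satt
#' @export
cate <- function(fit, z = NULL) average_effect(icate_draws(fit, z))

#' @rdname satt
#' @export
gsatt <- function(fit, groups, z = NULL) {
  if (is.null(z)) z <- fit$design$z
  dr <- icate_draws(fit, z)
  lv <- unique(as.character(groups))
  out <- stats::setNames(vector("list", length(lv)), lv)
  for (g in lv) {
    sub <- which(groups == g & z == 1)
    out[[g]] <- if (length(sub) > 0L) average_effect(dr, sub) else NULL
  }
  out
}

#' @rdname satt
#' @export
gsate <- function(fit, groups, z = NULL) {
  dr <- icate_draws(fit, z)
  lv <- unique(as.character(groups))
  stats::setNames(lapply(lv, function(g)
    average_effect(dr, which(groups == g))), lv)
}

#' Sample-level effects from the posterior predictive distribution
#'
#' Per-draw individual effects `y1 - y0` where the observed arm is fixed at
#' the observed outcome and the counterfactual arm comes from the posterior
#' predictive draws; averaging over all units gives the SATE, over the
#' treated the sample ATT.
#'
#' @param fit a `bartmm_fit` with test ppd draws.
#' @param y observed outcomes (original scale; defaults to the design's).
#' @param z treatment vector.
#' @param subset unit mask as in [average_effect()].
#' @return a `bartmm_estimand`.
#' @export
sample_effect_ppd <- function(fit, y = NULL, z = NULL, subset = NULL) {
  if (is.null(y)) y <- fit$design$y_raw
  if (is.null(z)) z <- fit$design$z
  y_cf <- extract(fit, sample = "test", value = "ppd")
  y1 <- z * y + (1 - z) * y_cf
  y0 <- (1 - z) * y + z * y_cf
  average_effect(y1 - y0, subset = subset)
}

#' Propensity scores from a conservative probit ensemble
#'
#' Fits treatment on covariates with a probit tree ensemble using heavier
#' leaf-value shrinkage than the regression default (larger `k_shrink`, i.e.
#' a tighter end-node prior), which keeps the scores away from 0 and 1 and
#' guards against overfitting the assignment mechanism. Returns the
#' posterior mean of `Phi(f)` per unit.
#'
#' @param table data frame of covariates plus the treatment column (the
#'   outcome must not be among the covariates).
#' @param treatment name of the 0/1 treatment column.
#' @param covariates optional character vector (default: all other columns).
#' @param k_shrink leaf shrinkage multiplier (default 4; the regression
#'   default is 2 -- larger means stronger shrinkage).
#' @param m,chains,warmup,draws sampler scale (deliberately small defaults).
#' @param seed optional seed.
#' @return numeric vector of scores strictly inside (0, 1).
#' @export
fit_propensity <- function(table, treatment, covariates = NULL,
                           k_shrink = 4, m = 50L, chains = 2L,
                           warmup = 150L, draws = 150L, seed = NULL) {
  zv <- table[[treatment]]
  if (!all(zv %in% c(0, 1)) || length(unique(zv)) < 2L)
    stop("treatment must be binary and non-degenerate", call. = FALSE)
  if (is.null(covariates)) covariates <- setdiff(names(table), treatment)
  dat <- table[, c(treatment, covariates), drop = FALSE]
  f <- sprintf("%s ~ bart(%s)", treatment,
               paste(covariates, collapse = " + "))
  fit <- bartmm(f, dat, chains = chains, warmup = warmup, draws = draws,
                m = m, k_shrink = k_shrink, seed = seed)
  ev <- extract(fit, "train", "ev") # probit-scale latent mean draws
  rowMeans(pnorm(ev))
}
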