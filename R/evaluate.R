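# Comparator methods and the replicated-study harness: linear baselines
# (pooled, fixed-effect, interacted, and Bayesian varying-intercept/slope
# variants), pure-BART baselines with the grouping omitted / as fixed
# effects / as varying intercepts (each with an appended propensity score),
# and the coupled semiparametric model itself. Metrics follow the standard
# benchmark conventions: RMSE and interval length standardized by the
# outcome sd, 95% coverage, and PEHE for unit-level effects.

.study_methods <- c("linear_full_pool", "linear_fe", "linearx_fe",
                    "linear_vi", "linear_vis", "linearx_vis",
                    "bart_vanilla", "bart_fe", "bart_vi",
                    "stan4bart_vi", "stan4bart_vis")

#' Precision in estimating heterogeneous effects
#'
#' Root-mean-squared error of unit-level effect estimates:
#' `sqrt(mean((icate_hat - icate_true)^2))`.
#'
#' @param icate_hat,icate_true equal-length numeric vectors.
#' @return a nonnegative real.
#' @export
pehe <- function(icate_hat, icate_true) {
  if (length(icate_hat) != length(icate_true))
    stop("length mismatch", call. = FALSE)
  sqrt(mean((icate_hat - icate_true)^2))
}

# covariate columns of a simulated dataset (everything except g, z, y)
.sim_covariates <- function(data) setdiff(names(data), c("g", "z", "y"))

.lm_satt_rows <- function(est, se, groups, z, level_z = 1.96) {
  list(point = est, lb = est - level_z * se, ub = est + level_z * se)
}

#' Fit one comparator method to a simulated dataset
#'
#' Linear methods use least squares (`fe` adds group dummies, `linearx_fe`
#' adds treatment-by-group interactions); `*_vi`/`*_vis` are Bayesian
#' multilevel linear fits run through the same sampler with the ensemble
#' disabled; `bart_*` run the ensemble with the grouping omitted, one-hot
#' encoded, or as varying intercepts, with an estimated propensity score
#' appended as a covariate; `stan4bart_*` are the coupled semiparametric
#' variants with varying intercepts (`"y ~ bart(. - g) + (1 | g)"`) or
#' intercepts and slopes (`"y ~ bart(. - g) + (1 + z | g)"`).
#'
#' @param method one of `r paste0('"', .study_methods, '"', collapse = ", ")`.
#' @param sim a `bartmm_sim` (or a compatible list with `data`).
#' @param settings list: `chains`, `warmup`, `draws`, `m`, `seed` for the
#'   Bayesian methods.
#' @return a `bartmm_method_result`: `satt` (point/lb/ub), `gsatt`
#'   (data frame per group), `icate` (point estimates per unit), `method`.
#' @export
fit_baseline <- function(method, sim,
                         settings = list(chains = 2L, warmup = 300L,
                                         draws = 300L, m = 50L, seed = 1L)) {
  method <- match.arg(method, .study_methods)
  data <- sim$data
  n <- nrow(data)
  covs <- .sim_covariates(data)
  z <- data$z
  g <- data$g
  glev <- levels(g)
  s <- function(nm, def) if (is.null(settings[[nm]])) def else settings[[nm]]

  enc <- .build_X_bart(data, covs)$X # numeric encoding incl. one-hot
  # drop constant columns to keep lm() full rank
  enc <- enc[, apply(enc, 2L, function(v) var(v) > 0), drop = FALSE]

  result <- function(satt_pt, satt_lb, satt_ub, gsatt_df, icate_pt) {
    structure(list(method = method,
                   satt = list(point = satt_pt, lb = satt_lb, ub = satt_ub),
                   gsatt = gsatt_df, icate = icate_pt),
              class = "bartmm_method_result")
  }
  gsatt_frame <- function(pt, lb, ub) {
    data.frame(group = glev, point = pt, lb = lb, ub = ub,
               n_treated = as.vector(table(g[z == 1])[glev]))
  }

  if (method %in% c("linear_full_pool", "linear_fe")) {
    df <- data.frame(y = data$y, z = z, enc, check.names = TRUE)
    form <- if (method == "linear_fe") {
      df$g <- g
      y ~ . # includes g as dummies
    } else y ~ .
    f <- lm(form, data = df)
    est <- coef(f)[["z"]]; se <- sqrt(vcov(f)["z", "z"])
    gs <- gsatt_frame(rep(est, length(glev)), rep(est - 1.96 * se, length(glev)),
                      rep(est + 1.96 * se, length(glev)))
    gs[is.na(gs$n_treated), "n_treated"] <- 0L
    return(result(est, est - 1.96 * se, est + 1.96 * se, gs, rep(est, n)))
  }

  if (method == "linearx_fe") {
    df <- data.frame(y = data$y, z = z, g = g, enc, check.names = TRUE)
    f <- lm(y ~ z * g + ., data = df[, c("y", "z", "g", colnames(enc))])
    cf <- coef(f); V <- vcov(f)
    cf[is.na(cf)] <- 0
    # per-group effect = beta_z + beta_{z:g_k}
    eff <- vapply(glev, function(gg) {
      nm <- paste0("z:g", gg)
      cf[["z"]] + if (nm %in% names(cf)) cf[[nm]] else 0
    }, 0)
    sev <- vapply(glev, function(gg) {
      nm <- paste0("z:g", gg)
      if (nm %in% rownames(V))
        sqrt(V["z", "z"] + V[nm, nm] + 2 * V["z", nm])
      else sqrt(V["z", "z"])
    }, 0)
    icate_pt <- eff[as.character(g)]
    ng1 <- as.vector(table(factor(g[z == 1], levels = glev)))
    wt <- ng1 / sum(ng1)
    satt_pt <- sum(wt * eff)
    # delta-method variance of the weighted combination
    names_all <- c("z", paste0("z:g", glev))
    a <- stats::setNames(numeric(length(names_all)), names_all)
    a[["z"]] <- 1
    for (i in seq_along(glev)) {
      nm <- paste0("z:g", glev[i])
      if (nm %in% rownames(V)) a[[nm]] <- wt[i]
    }
    a <- a[names(a) %in% rownames(V)]
    satt_se <- sqrt(as.numeric(t(a) %*% V[names(a), names(a)] %*% a))
    gs <- gsatt_frame(eff, eff - 1.96 * sev, eff + 1.96 * sev)
    return(result(satt_pt, satt_pt - 1.96 * satt_se, satt_pt + 1.96 * satt_se,
                  gs, unname(icate_pt)))
  }

  # Bayesian methods share the counterfactual-prediction pipeline
  test <- make_counterfactual(data, "z")
  prop <- NULL
  if (method %in% c("bart_vanilla", "bart_fe", "bart_vi")) {
    prop <- fit_propensity(data[, c(covs, "z")], "z",
                           m = min(s("m", 50L), 50L), chains = 1L,
                           warmup = 100L, draws = 100L)
    data$ps <- prop
    test$ps <- prop
  }
  form <- switch(method,
    linear_vi = sprintf("y ~ z + %s + (1 | g)", paste(covs, collapse = " + ")),
    linear_vis = sprintf("y ~ z + %s + (1 + z | g)",
                         paste(covs, collapse = " + ")),
    linearx_vis = sprintf("y ~ z + %s + %s + (1 + z | g)",
                          paste(covs, collapse = " + "),
                          paste(paste0("z:", setdiff(covs, "z")),
                                collapse = " + ")),
    bart_vanilla = "y ~ bart(. - g)",
    bart_fe = "y ~ bart(.)",
    bart_vi = "y ~ bart(. - g) + (1 | g)",
    stan4bart_vi = "y ~ bart(. - g) + (1 | g)",
    stan4bart_vis = "y ~ bart(. - g) + (1 + z | g)")
  linear_method <- method %in% c("linear_vi", "linear_vis", "linearx_vis")
  # linearx_vis interactions only make sense for numeric covariates
  if (method == "linearx_vis") {
    numcovs <- covs[vapply(data[covs], is.numeric, TRUE)]
    form <- sprintf("y ~ z + %s + %s + (1 + z | g)",
                    paste(covs, collapse = " + "),
                    paste(paste0("z:", numcovs), collapse = " + "))
  }
  if (linear_method) {
    # categoricals enter the parametric design through dummy coding
    fit <- bartmm(form, data, test = test, treatment = "z",
                  chains = s("chains", 2L), warmup = s("warmup", 300L),
                  draws = s("draws", 300L), m = 0L, seed = s("seed", 1L))
  } else {
    fit <- bartmm(form, data, test = test, treatment = "z",
                  chains = s("chains", 2L), warmup = s("warmup", 300L),
                  draws = s("draws", 300L), m = s("m", 50L),
                  seed = s("seed", 1L))
  }
  dr <- icate_draws(fit, z)
  sa <- average_effect(dr, z == 1)
  gsl <- lapply(glev, function(gg) {
    sel <- which(g == gg & z == 1)
    if (length(sel) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    e <- average_effect(dr, sel)
    c(e$point, e$interval)
  })
  gsm <- do.call(rbind, gsl)
  gs <- gsatt_frame(gsm[, 1], gsm[, 2], gsm[, 3])
  result(sa$point, sa$interval[["lb"]], sa$interval[["ub"]], gs,
         rowMeans(dr))
}

#' Standardized SATT metrics over a study table
#'
#' Per (config, method): RMSE of the estimates against truth and average
#' interval length, both divided by the per-replication outcome sd, plus the
#' fraction of replications whose 95% interval covers the truth.
#'
#' @param study a study table from [run_study()].
#' @param estimand which estimand rows to summarize (default `"satt"`).
#' @return a data frame of summary rows.
#' @export
satt_metrics <- function(study, estimand = "satt") {
  rows <- study[study$estimand == estimand, , drop = FALSE]
  if (nrow(rows) == 0L) return(data.frame())
  key <- interaction(rows$config, rows$method, drop = TRUE)
  out <- lapply(split(rows, key), function(d) {
    has_int <- all(is.finite(d$lb) & is.finite(d$ub))
    data.frame(
      config = d$config[1], method = d$method[1], reps = nrow(d),
      rmse_std = sqrt(mean(((d$estimate - d$truth) / d$sd_y)^2)),
      len_std = if (has_int) mean((d$ub - d$lb) / d$sd_y) else NA_real_,
      coverage = if (has_int)
        mean(d$truth >= d$lb & d$truth <= d$ub) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run a replicated simulation study
#'
#' For every configuration and replication, one dataset is generated from a
#' deterministic per-cell seed and every method is fit to that identical
#' dataset; per-method SATT, per-group GSATT, and PEHE rows are appended to
#' a tidy study table. Per-cell failures are recorded, not fatal.
#'
#' @param grid list of `bartmm_simconfig` objects (their `seed` fields are
#'   overwritten by the schedule).
#' @param methods character vector of method ids, see [fit_baseline()].
#' @param reps replications per configuration.
#' @param seed master seed for the schedule.
#' @param settings sampler settings forwarded to [fit_baseline()].
#' @return a data frame (the study table) with columns config, rep, method,
#'   estimand, estimate, lb, ub, truth, sd_y.
#' @export
run_study <- function(grid, methods, reps = 50L, seed = 1L,
                      settings = list(chains = 2L, warmup = 300L,
                                      draws = 300L, m = 50L)) {
  if (inherits(grid, "bartmm_simconfig")) grid <- list(grid)
  set.seed(seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max %/% 2L,
                                  length(grid) * reps),
                       length(grid), reps)
  rows <- list()
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    cfg_id <- sprintf("%s_%s_%s_e%g_i%g", cfg$surface, cfg$grouping,
                      cfg$structure, cfg$effect_size, cfg$icc)
    for (r in seq_len(reps)) {
      cfg$seed <- cell_seeds[ci, r]
      sim <- simulate_dataset(cfg)
      for (mth in methods) {
        st <- settings
        st$seed <- cell_seeds[ci, r] + 1L
        res <- tryCatch(fit_baseline(mth, sim, st), error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            config = cfg_id, rep = r, method = mth, estimand = "error",
            estimate = NA_real_, lb = NA_real_, ub = NA_real_,
            truth = NA_real_, sd_y = sim$truth$sd_y,
            note = conditionMessage(res))
          next
        }
        new <- list(data.frame(
          config = cfg_id, rep = r, method = mth, estimand = "satt",
          estimate = res$satt$point, lb = res$satt$lb, ub = res$satt$ub,
          truth = sim$truth$satt, sd_y = sim$truth$sd_y, note = ""))
        gdf <- res$gsatt
        keep <- !is.na(gdf$point) & !is.na(sim$truth$gsatt[seq_len(nrow(gdf))])
        if (any(keep))
          new[[2]] <- data.frame(
            config = cfg_id, rep = r, method = mth,
            estimand = paste0("gsatt:", gdf$group[keep]),
            estimate = gdf$point[keep], lb = gdf$lb[keep], ub = gdf$ub[keep],
            truth = sim$truth$gsatt[seq_len(nrow(gdf))][keep],
            sd_y = sim$truth$sd_y, note = "")
        new[[length(new) + 1L]] <- data.frame(
          config = cfg_id, rep = r, method = mth, estimand = "pehe",
          estimate = pehe(res$icate, sim$truth$icate),
          lb = NA_real_, ub = NA_real_, truth = 0,
          sd_y = sim$truth$sd_y, note = "")
        rows <- c(rows, new)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
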