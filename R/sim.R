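# Fully synthetic multilevel observational-study generator patterned on the
# Infant Health and Development Program benchmark: 6 continuous, 9 binary,
# and 2 unordered categorical covariates; a randomized treatment (1/3
# treated) made observational by deleting the treated units of a nonrandom
# subgroup flagged by one binary covariate; linear (A), exponential (B), and
# quadratic/interaction (C) response surfaces; and group structure with 8 or
# 26 levels entering as varying intercepts (vi) or intercepts plus slopes
# (vis). Ground truth (potential-outcome means, iCATEs, group effects,
# SATT/GSATT) is recorded alongside the data.

#' Simulation configuration
#'
#' @param n target number of units after the deletion step (default 985).
#' @param surface response surface: `"A"` (linear, constant effect), `"B"`
#'   (exponential treated surface), `"C"` (squares and interactions).
#' @param grouping `"g8"`, `"g26"`, or an integer number of levels.
#' @param structure `"vi"` (varying intercepts) or `"vis"` (varying
#'   intercepts and slopes).
#' @param effect_size treatment effect in sd-of-outcome units; the grid
#'   {0, 0.2, 0.5, 0.8} reproduces the study design but any value works.
#' @param icc intraclass correlation on the control-outcome scale; the grid
#'   {0.2, 0.333, 0.5} reproduces the study design.
#' @param sigma0,sigma1 error sds of the two potential outcomes.
#' @param seed integer seed.
#' @return a `bartmm_simconfig` list.
#' @export
sim_config <- function(n = 985L, surface = c("A", "B", "C"),
                       grouping = "g8", structure = c("vi", "vis"),
                       effect_size = 0.5, icc = 0.2,
                       sigma0 = 1, sigma1 = 1, seed = 1L) {
  surface <- match.arg(surface)
  structure_ <- match.arg(structure)
  n_groups <- if (is.numeric(grouping)) as.integer(grouping)
              else switch(grouping, g8 = 8L, g26 = 26L,
                          stop("grouping must be 'g8', 'g26', or an integer"))
  if (!(icc > 0 && icc < 1)) stop("icc must lie in (0, 1)", call. = FALSE)
  structure(list(n = as.integer(n), surface = surface, n_groups = n_groups,
                 grouping = if (is.numeric(grouping))
                   paste0("g", n_groups) else grouping,
                 structure = structure_, effect_size = effect_size,
                 icc = icc, sigma0 = sigma0, sigma1 = sigma1,
                 seed = as.integer(seed)),
            class = "bartmm_simconfig")
}

# nearest correlation matrix by eigenvalue clipping
.fix_corr <- function(R, floor_ = 1e-3) {
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, floor_)
  R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(R2)))
  D %*% R2 %*% D
}

#' Draw an IHDP-like covariate table
#'
#' Six continuous variables from a correlated Gaussian copula (pairwise
#' correlations drawn once, uniformly on (-0.5, 0.5), then projected to the
#' nearest valid correlation matrix), nine binary variables by thresholding
#' latent normals at prevalences drawn from (0.1, 0.9), and two unordered
#' categoricals (4 and 8 levels) from Dirichlet-weighted multinomials. The
#' first binary column `b1` doubles as the deletion indicator analogue used
#' by [assign_treatment()].
#'
#' @param n number of rows (>= 50).
#' @return a data frame with columns x1..x6, b1..b9, c1, c2; the drawn
#'   copula parameters are attached as the `"gen"` attribute.
#' @export
make_covariates <- function(n) {
  stopifnot(n >= 50L)
  d <- 15L # 6 continuous + 9 binary latents
  R <- diag(1, d)
  off <- runif(d * (d - 1L) / 2L, -0.5, 0.5)
  R[upper.tri(R)] <- off
  R <- R + t(R) - diag(diag(R))
  R <- .fix_corr(R)
  Lr <- t(chol(R))
  Zl <- matrix(rnorm(n * d), d, n)
  lat <- t(Lr %*% Zl)
  prev <- runif(9L, 0.1, 0.9)
  out <- as.data.frame(lat[, 1:6])
  names(out) <- paste0("x", 1:6)
  for (j in 1:9)
    out[[paste0("b", j)]] <- as.numeric(lat[, 6L + j] < qnorm(prev[j]))
  p1 <- rgamma(4L, 1); p1 <- p1 / sum(p1)
  p2 <- rgamma(8L, 1); p2 <- p2 / sum(p2)
  out$c1 <- factor(letters[sample.int(4L, n, replace = TRUE, prob = p1)],
                   levels = letters[1:4])
  out$c2 <- factor(LETTERS[sample.int(8L, n, replace = TRUE, prob = p2)],
                   levels = LETTERS[1:8])
  attr(out, "gen") <- list(R = R, prev = prev, p1 = p1, p2 = p2)
  out
}

#' Randomize then confound the treatment
#'
#' Treatment is randomized with probability 1/3; treated units whose
#' deletion indicator equals 1 are then removed, which correlates treatment
#' with every covariate linked to the indicator through the copula while
#' keeping common support for the remaining treated units.
#'
#' @param covariates a table from [make_covariates()].
#' @param indicator name of the 0/1 deletion-indicator column.
#' @param p_treat randomization probability (default 1/3).
#' @return list with `z` (for all rows) and `keep` (logical mask).
#' @export
assign_treatment <- function(covariates, indicator = "b1", p_treat = 1 / 3) {
  ind <- covariates[[indicator]]
  if (is.null(ind)) stop("deletion indicator column missing", call. = FALSE)
  n <- nrow(covariates)
  z <- rbinom(n, 1L, p_treat)
  keep <- !(z == 1L & ind == 1)
  if (sum(z[keep]) < 10L)
    stop("fewer than 10 treated units remain after deletion; ",
         "increase n", call. = FALSE)
  list(z = z, keep = keep)
}

# numeric encoding used by the response surfaces (standardized continuous,
# raw binaries, one-hot categoricals)
.sim_encode <- function(covs) {
  Xc <- scale(as.matrix(covs[paste0("x", 1:6)]))
  Xb <- as.matrix(covs[paste0("b", 1:9)])
  X1 <- .onehot(covs$c1, levels(covs$c1), "c1")
  X2 <- .onehot(covs$c2, levels(covs$c2), "c2")
  cbind(Xc, Xb, X1, X2)
}

#' Potential-outcome mean surfaces
#'
#' Surface A is linear with `h1 = h0` (the treatment effect enters later
#' through the group-structure step). Surface B keeps `h0` linear but sets
#' `h1 = exp((X + 0.5) beta_B)`, recentered to match `h0`'s mean. Surface C
#' adds squared and interaction terms whose curvature differs between the
#' two arms. Coefficients are drawn once per dataset from sparse discrete
#' sets and returned in the coefficient record.
#'
#' @param surface `"A"`, `"B"`, or `"C"`.
#' @param covariates covariate table.
#' @return list with `h0`, `h1`, and the coefficient `record`.
#' @export
response_surface <- function(surface, covariates) {
  X <- .sim_encode(covariates)
  p <- ncol(X)
  record <- list(surface = surface)
  if (surface == "A") {
    beta <- sample(c(0, 1, 2, 3, 4), p, replace = TRUE,
                   prob = c(0.5, 0.2, 0.15, 0.1, 0.05))
    h0 <- as.vector(X %*% beta)
    h1 <- h0
    record$beta <- beta
  } else if (surface == "B") {
    beta <- sample(c(0, 0.1, 0.2, 0.3, 0.4), p, replace = TRUE,
                   prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
    h0 <- as.vector(X %*% beta)
    h1 <- exp(as.vector((X + 0.5) %*% beta))
    if (any(!is.finite(h1)))
      stop("non-finite exponential surface", call. = FALSE)
    h1 <- h1 - mean(h1) + mean(h0)
    record$beta <- beta
  } else {
    beta <- sample(c(0, 0.5, 1, 1.5, 2), p, replace = TRUE,
                   prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    # eligible nonlinear terms: squares of the continuous block, cross terms
    # among the first 15 (continuous + binary) columns
    sq_idx <- 1:6
    cross <- t(utils::combn(1:15, 2L))
    n_el <- length(sq_idx) + nrow(cross)
    pick <- sort(sample.int(n_el, max(2L, round(0.2 * n_el))))
    # guarantee at least one pure quadratic and one cross term
    if (!any(pick <= 6L)) pick <- c(sample(sq_idx, 1L), pick)
    if (!any(pick > 6L)) pick <- c(pick, 6L + sample.int(nrow(cross), 1L))
    pick <- sort(unique(pick))
    draw_gamma <- function() {
      g <- sample(c(0, 0.5, 1), length(pick), replace = TRUE,
                  prob = c(0.4, 0.3, 0.3))
      # keep the guarantee: force a nonzero square and cross coefficient
      sq <- which(pick <= 6L); cr <- which(pick > 6L)
      if (all(g[sq] == 0)) g[sample(sq, 1L)] <- 0.5
      if (all(g[cr] == 0)) g[sample(cr, 1L)] <- 0.5
      g
    }
    gamma0 <- draw_gamma(); gamma1 <- draw_gamma()
    Q <- vapply(pick, function(k) {
      if (k <= 6L) X[, k]^2 else X[, cross[k - 6L, 1L]] * X[, cross[k - 6L, 2L]]
    }, numeric(nrow(X)))
    h0 <- as.vector(X %*% beta) + as.vector(Q %*% gamma0)
    h1 <- as.vector(X %*% beta) + as.vector(Q %*% gamma1)
    record$beta <- beta
    record$terms <- pick
    record$cross_map <- cross
    record$gamma0 <- gamma0
    record$gamma1 <- gamma1
    record$has_square <- any(pick <= 6L & (gamma0 != 0 | gamma1 != 0))
    record$has_cross <- any(pick > 6L & (gamma0 != 0 | gamma1 != 0))
  }
  list(h0 = h0, h1 = h1, record = record)
}

#' Add multilevel structure and calibrate the effect size
#'
#' Group labels come from a Dirichlet-weighted multinomial (unequal sizes).
#' Varying intercepts are `N(0, sd_int)` with `sd_int^2 =
#' icc/(1-icc) * sigma0^2` so the intraclass correlation on the
#' control-outcome scale equals `icc`. Under `"vi"` the treated mean adds a
#' constant `tau`; under `"vis"` it adds `tau + lambda_slo[g]` with varying
#' slopes of the same scale as the intercepts. `tau` is calibrated so the
#' realized SATT equals `effect_size * sd_y`, where `sd_y^2 = var(h0) +
#' sd_int^2 + sigma0^2` is the analytic control-outcome variance.
#'
#' @param h0,h1 mean surfaces from [response_surface()].
#' @param z treatment vector (kept rows).
#' @param config a `bartmm_simconfig`.
#' @return list with group labels, effect components, potential-outcome
#'   means `mu0`/`mu1`, and the calibration record.
#' @export
add_group_structure <- function(h0, h1, z, config) {
  n <- length(h0)
  G <- config$n_groups
  pg <- rgamma(G, 5); pg <- pg / sum(pg)
  g <- sample.int(G, n, replace = TRUE, prob = pg)
  sd_int <- sqrt(config$icc / (1 - config$icc)) * config$sigma0
  lam_int <- rnorm(G, 0, sd_int)
  sd_y <- sqrt(var(h0) + sd_int^2 + config$sigma0^2)
  treated <- z == 1
  if (config$structure == "vi") {
    lam_slo <- rep(0, G)
  } else {
    lam_slo <- rnorm(G, 0, sd_int)
  }
  tau <- config$effect_size * sd_y -
    mean((h1 - h0 + lam_slo[g])[treated])
  mu0 <- h0 + lam_int[g]
  mu1 <- h1 + lam_int[g] + lam_slo[g] + tau
  list(g = g, lambda_int = lam_int, lambda_slo = lam_slo, tau = tau,
       sd_int = sd_int, sd_y = sd_y, mu0 = mu0, mu1 = mu1)
}

#' Generate one complete simulated dataset
#'
#' Composes covariate generation, treatment assignment with deletion, the
#' response surface, group structure, and the observed outcome
#' `y = (1-z) (mu0 + e0) + z (mu1 + e1)`.
#'
#' @param config a `bartmm_simconfig` (or arguments forwarded to
#'   [sim_config()]).
#' @return object of class `bartmm_sim`: `data` (covariates, `g`, `z`, `y`),
#'   `truth` (mu0, mu1, icate, satt, gsatt, group effects, sd_y, coefficient
#'   record), and the config.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "bartmm_simconfig")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  keep_rate <- 1 - 0.5 / 3 # worst-case guess; batch is padded anyway
  n_raw <- ceiling(config$n / keep_rate * 1.15) + 50L
  covs <- make_covariates(n_raw)
  tr <- assign_treatment(covs)
  keep_idx <- which(tr$keep)
  if (length(keep_idx) < config$n)
    stop("deletion removed too many rows; increase n", call. = FALSE)
  keep_idx <- keep_idx[seq_len(config$n)]
  covs_k <- covs[keep_idx, , drop = FALSE]
  rownames(covs_k) <- NULL
  z <- tr$z[keep_idx]
  surf <- response_surface(config$surface, covs_k)
  grp <- add_group_structure(surf$h0, surf$h1, z, config)
  e0 <- rnorm(config$n, 0, config$sigma0)
  e1 <- rnorm(config$n, 0, config$sigma1)
  y <- (1 - z) * (grp$mu0 + e0) + z * (grp$mu1 + e1)
  icate <- grp$mu1 - grp$mu0
  treated <- z == 1
  gsatt_true <- vapply(seq_len(config$n_groups), function(gg) {
    sel <- treated & grp$g == gg
    if (any(sel)) mean(icate[sel]) else NA_real_
  }, 0)
  dat <- covs_k
  dat$g <- factor(paste0("grp", grp$g),
                  levels = paste0("grp", seq_len(config$n_groups)))
  dat$z <- z
  dat$y <- y
  structure(list(
    data = dat,
    truth = list(mu0 = grp$mu0, mu1 = grp$mu1, icate = icate,
                 satt = mean(icate[treated]),
                 gsatt = gsatt_true,
                 lambda_int = grp$lambda_int, lambda_slo = grp$lambda_slo,
                 tau = grp$tau, sd_int = grp$sd_int, sd_y = sd(y),
                 sd_y_analytic = grp$sd_y,
                 record = surf$record),
    config = config
  ), class = "bartmm_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' `data.csv` plus `truth.json` (ground truth and the coefficient record).
#'
#' @param sim a `bartmm_sim`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$data, file.path(dir, "data.csv"), row.names = FALSE)
  tr <- sim$truth
  tr$record$cross_map <- NULL
  jsonlite::write_json(c(tr, list(config = unclass(sim$config))),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
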