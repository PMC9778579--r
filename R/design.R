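# Realized design structures: the tree-splittable matrix, the parametric
# matrix, and the sparse group design, plus the response rescaling that maps
# a continuous outcome onto [-0.5, 0.5].

#' Candidate split values for one predictor column
#'
#' At most `max_cuts` values are placed at uniform quantiles of the distinct
#' observed values, strictly inside the observed range. A two-valued column
#' gets its single midpoint (0.5 for a 0/1 indicator); a constant column gets
#' an empty set and is never split on. When the column has no more than
#' `max_cuts + 1` distinct values, the cutpoints are the exact midpoints of
#' consecutive distinct values, so every achievable partition is available.
#'
#' @param column numeric vector.
#' @param max_cuts maximum number of cutpoints (default 100).
#' @return sorted numeric vector of cutpoints (possibly empty).
#' @export
make_cutpoints <- function(column, max_cuts = 100L) {
  stopifnot(max_cuts >= 1L)
  u <- sort(unique(column[is.finite(column)]))
  if (length(u) < 2L) return(numeric(0))
  if (length(u) - 1L <= max_cuts) {
    cuts <- (u[-1] + u[-length(u)]) / 2
  } else {
    probs <- seq_len(max_cuts) / (max_cuts + 1)
    cuts <- unname(quantile(u, probs, type = 7))
    cuts <- sort(unique(cuts))
    cuts <- cuts[cuts > u[1] & cuts < u[length(u)]]
  }
  cuts
}

.onehot <- function(col, levels = NULL, name = "x") {
  if (is.null(levels)) {
    f <- if (is.factor(col)) col else factor(col, levels = unique(col))
    levels <- levels(f)
  } else {
    f <- factor(col, levels = levels)
  }
  m <- matrix(0, length(col), length(levels))
  m[cbind(seq_along(col), as.integer(f))] <- 1
  colnames(m) <- paste(name, levels, sep = ".")
  m
}

.encode_bart_column <- function(col, nm, levels = NULL) {
  if (is.numeric(col)) {
    m <- matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, nm))
    attr(m, "kind") <- "numeric"
    m
  } else if (is.logical(col)) {
    m <- matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, nm))
    attr(m, "kind") <- "numeric"
    m
  } else {
    m <- .onehot(col, levels = levels, name = nm)
    attr(m, "kind") <- "categorical"
    attr(m, "levels") <- if (is.null(levels))
      levels(if (is.factor(col)) col else factor(col, levels = unique(col)))
      else levels
    m
  }
}

.build_X_bart <- function(table, terms, enc = NULL) {
  pieces <- list()
  enc_out <- list()
  for (nm in terms) {
    lv <- if (!is.null(enc)) enc[[nm]]$levels else NULL
    m <- .encode_bart_column(table[[nm]], nm, levels = lv)
    enc_out[[nm]] <- list(kind = attr(m, "kind"), levels = attr(m, "levels"))
    pieces[[nm]] <- m
  }
  X <- if (length(pieces) > 0L) do.call(cbind, pieces) else
    matrix(0, nrow(table), 0)
  list(X = X, enc = enc_out)
}

.build_X_beta <- function(table, parametric, centers = NULL) {
  cols <- list()
  for (p in parametric) {
    if (length(p) == 1L) {
      col <- table[[p]]
      if (is.numeric(col) || is.logical(col)) {
        cols[[p]] <- as.numeric(col)
      } else {
        f <- if (is.factor(col)) col else factor(col, levels = unique(col))
        oh <- .onehot(f, levels = levels(f), name = p)
        for (j in seq_len(ncol(oh))[-1]) # drop first level (reference coding)
          cols[[colnames(oh)[j]]] <- oh[, j]
      }
    } else {
      a <- table[[p[1]]]; b <- table[[p[2]]]
      if (!is.numeric(a) || !is.numeric(b))
        stop("interaction terms require numeric columns: ",
             paste(p, collapse = ":"), call. = FALSE)
      cols[[paste(p, collapse = ":")]] <- a * b
    }
  }
  X <- if (length(cols) > 0L)
    do.call(cbind, cols) else matrix(0, nrow(table), 0)
  if (length(cols) > 0L) colnames(X) <- names(cols)
  if (is.null(centers)) centers <- colMeans(X)
  X <- sweep(X, 2L, centers, "-")
  list(X = X, centers = centers)
}

.build_W <- function(table, groups, level_sets = NULL) {
  out <- list()
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    col <- table[[g$factor]]
    lv <- if (!is.null(level_sets)) level_sets[[g$factor]] else
      unique(as.character(col))
    f <- factor(as.character(col), levels = lv)
    if (anyNA(f))
      stop("grouping factor '", g$factor, "' has levels unseen in training",
           call. = FALSE)
    if (length(lv) < 2L && is.null(level_sets))
      warning("grouping factor '", g$factor,
              "' has a single level; its variance is unidentified")
    U <- cbind(
      if (g$intercept) matrix(1, nrow(table), 1,
                              dimnames = list(NULL, "(Intercept)")),
      if (length(g$slopes) > 0L)
        do.call(cbind, stats::setNames(lapply(g$slopes, function(s) {
          v <- table[[s]]
          if (!is.numeric(v)) stop("group slope '", s, "' must be numeric")
          as.numeric(v)
        }), g$slopes))
    )
    out[[g$factor]] <- list(factor = g$factor, levels = lv,
                            index = as.integer(f), U = U,
                            K = ncol(U), L = length(lv),
                            intercept = g$intercept, slopes = g$slopes)
  }
  out
}

#' Bind a model specification to a data table
#'
#' Builds every design structure the samplers consume: the rescaled response
#' (continuous outcomes are mapped affinely onto \[-0.5, 0.5\]), the
#' one-hot-expanded tree matrix with per-column cutpoint grids, the centered
#' parametric matrix (no intercept column; the intercept is absorbed by the
#' response centering), and the per-factor group design.
#'
#' @param spec a `bartmm_spec` (resolved or not).
#' @param table a data frame with no missing values in referenced columns.
#' @param max_cuts cutpoints per column, see [make_cutpoints()].
#' @return an object of class `bartmm_design`.
#' @export
build_design <- function(spec, table, max_cuts = 100L) {
  spec <- resolve_spec(spec, names(table))
  used <- unique(c(spec$response, spec$treatment, unlist(spec$parametric),
                   spec$bart_terms,
                   unlist(lapply(spec$groups, function(g) c(g$factor, g$slopes)))))
  if (!all(complete.cases(table[, used, drop = FALSE])))
    stop("missing values in referenced columns", call. = FALSE)

  y_raw <- table[[spec$response]]
  outcome_kind <- spec$outcome_kind
  if (outcome_kind == "auto")
    outcome_kind <- if (all(y_raw %in% c(0, 1)) &&
                        length(unique(y_raw)) == 2L) "binary" else "continuous"
  if (outcome_kind == "continuous") {
    rng <- range(y_raw)
    if (diff(rng) == 0)
      stop("degenerate data: constant outcome", call. = FALSE)
    center <- mean(rng)
    half_range <- diff(rng) / 2
    y <- (y_raw - center) / (2 * half_range)
  } else {
    if (!all(y_raw %in% c(0, 1)))
      stop("binary outcome must be coded 0/1", call. = FALSE)
    center <- 0; half_range <- 0.5
    y <- as.numeric(y_raw)
  }

  z <- NULL
  if (!is.null(spec$treatment)) {
    z <- table[[spec$treatment]]
    if (!all(z %in% c(0, 1))) stop("treatment must be coded 0/1", call. = FALSE)
  }

  xb <- .build_X_bart(table, spec$bart_terms)
  cutpoints <- lapply(seq_len(ncol(xb$X)), function(j)
    make_cutpoints(xb$X[, j], max_cuts))
  names(cutpoints) <- colnames(xb$X)
  pb <- .build_X_beta(table, spec$parametric)
  W <- .build_W(table, spec$groups)

  structure(list(
    spec = spec, y = y, y_raw = y_raw, z = z,
    outcome_kind = outcome_kind,
    X_bart = xb$X, bart_enc = xb$enc, cutpoints = cutpoints,
    X_beta = pb$X, beta_centers = pb$centers,
    W = W, n = nrow(table),
    scale = list(center = center, half_range = half_range),
    max_cuts = max_cuts
  ), class = "bartmm_design")
}

# Apply a training design's encoders to new data (e.g. the counterfactual
# table); the response scaling, one-hot level sets, column centers and group
# level maps are all taken from the training design.
.design_newdata <- function(design, table) {
  spec <- design$spec
  xb <- .build_X_bart(table, spec$bart_terms, enc = design$bart_enc)
  pb <- .build_X_beta(table, spec$parametric, centers = design$beta_centers)
  level_sets <- lapply(design$W, `[[`, "levels")
  W <- .build_W(table, spec$groups, level_sets = level_sets)
  list(X_bart = xb$X, X_beta = pb$X, W = W, n = nrow(table))
}

# map model-scale values back to the outcome scale
.unscale <- function(design, v, what = c("value", "spread")) {
  what <- match.arg(what)
  if (design$outcome_kind == "binary") return(v)
  r <- 2 * design$scale$half_range
  if (what == "value") design$scale$center + r * v else r * v
}

#' Read a data table from CSV with an optional JSON schema sidecar
#'
#' The sidecar, when present, is a JSON object mapping column names to
#' `"categorical"`, `"numeric"` or `"binary"`, used to force typing (e.g. an
#' integer-coded site indicator that should be treated as unordered).
#'
#' @param path CSV file with a header row.
#' @param schema optional path to the JSON sidecar.
#' @return a data frame.
#' @export
read_design_csv <- function(path, schema = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    sch <- jsonlite::fromJSON(schema)
    for (nm in names(sch)) {
      if (!nm %in% names(d)) next
      if (sch[[nm]] == "categorical") d[[nm]] <- factor(d[[nm]])
      else d[[nm]] <- as.numeric(d[[nm]])
    }
  }
  d
}
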