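#' @useDynLib bartmm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile sd var rnorm runif rbinom rgamma rchisq qchisq
#'   pnorm qnorm acf lm coef vcov resid predict model.matrix rexp complete.cases
NULL

.name_rx <- "^[A-Za-z.][A-Za-z0-9._]*$"

.parse_error <- function(msg, piece = NULL, pos = NA) {
  loc <- if (!is.na(pos)) sprintf(" (at position %d)", pos) else ""
  stop(sprintf("model specification parse error%s: %s%s", loc, msg,
               if (!is.null(piece)) sprintf(" in '%s'", piece) else ""),
       call. = FALSE)
}

# split a string on a separator at parenthesis depth 0
.split_top <- function(s, sep = "+") {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  pieces <- character(0)
  starts <- integer(0)
  cur <- ""
  start <- 1L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) .parse_error("unbalanced ')'", pos = i)
    if (ch == sep && depth == 0L) {
      pieces <- c(pieces, cur)
      starts <- c(starts, start)
      cur <- ""
      start <- i + 1L
    } else cur <- paste0(cur, ch)
  }
  if (depth != 0L) .parse_error("unbalanced '('")
  pieces <- c(pieces, cur)
  starts <- c(starts, start)
  list(pieces = trimws(pieces), starts = starts)
}

.check_name <- function(nm, piece, pos) {
  if (!grepl(.name_rx, nm)) .parse_error(sprintf("unknown token '%s'", nm), piece, pos)
  nm
}

#' Parse a model-specification string
#'
#' The specification language augments the familiar `response ~ terms` syntax
#' with two constructs: `bart(expr)` marks variables eligible for regression
#' tree splits (where `expr` may use `.` for "all unclaimed columns", `+` to
#' add and `-` to remove names), and `(1 + slope | factor)` adds multilevel
#' varying intercepts/slopes for a grouping factor. Plain names and `a:b`
#' interactions form the parametric linear component; the global intercept is
#' always eliminated (the response is centered instead).
#'
#' @param spec_string a specification such as
#'   `"y ~ z + bart(. - g) + (1 + z | g)"`.
#' @param treatment optional name of the binary treatment column.
#' @param outcome_kind `"auto"`, `"continuous"` or `"binary"`. With `"auto"`
#'   the kind is resolved when the specification is bound to data.
#' @param columns optional character vector of available column names; when
#'   supplied, `.` inside `bart()` is expanded immediately.
#' @return an object of class `bartmm_spec`.
#' @export
parse_formula <- function(spec_string, treatment = NULL,
                          outcome_kind = c("auto", "continuous", "binary"),
                          columns = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  if (!is.character(spec_string) || length(spec_string) != 1L)
    .parse_error("specification must be a single string")
  tilde <- gregexpr("~", spec_string, fixed = TRUE)[[1]]
  if (length(tilde) != 1L || tilde[1] < 0)
    .parse_error("expected exactly one '~'")
  lhs <- trimws(substr(spec_string, 1L, tilde[1] - 1L))
  rhs <- substr(spec_string, tilde[1] + 1L, nchar(spec_string))
  .check_name(lhs, spec_string, 1L)

  sp <- .split_top(rhs, "+")
  parametric <- list()
  bart_plus <- character(0)
  bart_minus <- character(0)
  bart_dot <- FALSE
  n_bart <- 0L
  groups <- list()

  for (k in seq_along(sp$pieces)) {
    piece <- sp$pieces[k]
    pos <- sp$starts[k] + tilde[1]
    if (piece == "") .parse_error("empty term", rhs, pos)
    if (grepl("^bart\\(", piece)) {
      if (!grepl("\\)$", piece)) .parse_error("unterminated bart()", piece, pos)
      n_bart <- n_bart + 1L
      if (n_bart > 1L)
        stop("model specification error: duplicate bart() term", call. = FALSE)
      inner <- substr(piece, 6L, nchar(piece) - 1L)
      # tokens joined by + and -, with '-' flagging removals
      toks <- strsplit(gsub("\\s+", "", inner), "(?=[+-])", perl = TRUE)[[1]]
      sign <- 1L
      for (tk in toks) {
        if (tk == "") next
        if (tk == "+") { sign <- 1L; next }
        if (tk == "-") { sign <- -1L; next }
        if (startsWith(tk, "+")) { sign <- 1L; tk <- substring(tk, 2L) }
        if (startsWith(tk, "-")) { sign <- -1L; tk <- substring(tk, 2L) }
        if (tk == ".") {
          if (sign < 0) .parse_error("cannot remove '.'", piece, pos)
          bart_dot <- TRUE
        } else {
          .check_name(tk, piece, pos)
          if (sign > 0) bart_plus <- c(bart_plus, tk)
          else bart_minus <- c(bart_minus, tk)
        }
      }
    } else if (grepl("^\\(.*\\)$", piece)) {
      inner <- substr(piece, 2L, nchar(piece) - 1L)
      bar <- .split_top(inner, "|")
      if (length(bar$pieces) != 2L)
        .parse_error("group term must be '(terms | factor)'", piece, pos)
      fac <- bar$pieces[2]
      .check_name(fac, piece, pos)
      lterms <- .split_top(bar$pieces[1], "+")$pieces
      intercept <- TRUE
      slopes <- character(0)
      for (lt in lterms) {
        if (lt == "1") intercept <- TRUE
        else if (lt == "0" || lt == "-1") intercept <- FALSE
        else slopes <- c(slopes, .check_name(lt, piece, pos))
      }
      if (!intercept && length(slopes) == 0L)
        .parse_error("group term has neither intercept nor slopes", piece, pos)
      groups[[length(groups) + 1L]] <-
        list(factor = fac, intercept = intercept, slopes = slopes)
    } else if (grepl(":", piece, fixed = TRUE)) {
      parts <- trimws(strsplit(piece, ":", fixed = TRUE)[[1]])
      if (length(parts) != 2L) .parse_error("interactions must be 'a:b'", piece, pos)
      for (p in parts) .check_name(p, piece, pos)
      parametric[[length(parametric) + 1L]] <- parts
    } else if (piece == "1" || piece == "0" || piece == "-1") {
      # the global intercept is eliminated; tolerate and ignore an explicit 1
      next
    } else {
      .check_name(piece, piece, pos)
      parametric[[length(parametric) + 1L]] <- piece
    }
  }

  spec <- structure(list(
    response = lhs,
    treatment = treatment,
    parametric = parametric,
    bart_plus = unique(bart_plus),
    bart_minus = unique(bart_minus),
    bart_dot = bart_dot,
    has_bart = n_bart > 0L,
    bart_terms = if (bart_dot) NULL else unique(bart_plus),
    groups = groups,
    outcome_kind = outcome_kind
  ), class = "bartmm_spec")
  if (!is.null(columns)) spec <- resolve_spec(spec, columns)
  spec
}

#' Resolve a specification against a set of column names
#'
#' Expands `.` inside the `bart()` term: all columns that are not the
#' response, not claimed by a parametric term, not a grouping factor, and not
#' explicitly removed become tree-splittable. Columns may legitimately appear
#' in both the parametric and tree components.
#'
#' @param spec a `bartmm_spec`.
#' @param columns available column names.
#' @return the spec with `bart_terms` filled in and invariants checked.
#' @export
resolve_spec <- function(spec, columns) {
  stopifnot(inherits(spec, "bartmm_spec"))
  referenced <- c(spec$response, unlist(spec$parametric), spec$bart_plus,
                  spec$bart_minus, unlist(lapply(spec$groups, function(g)
                    c(g$factor, g$slopes))))
  missing <- setdiff(referenced, columns)
  if (length(missing) > 0L)
    stop("columns not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  gfac <- vapply(spec$groups, `[[`, "", "factor")
  if (spec$bart_dot) {
    claimed <- unique(c(spec$response, unlist(spec$parametric), gfac,
                        spec$bart_minus))
    spec$bart_terms <- unique(c(setdiff(columns, claimed), spec$bart_plus))
  } else {
    spec$bart_terms <- setdiff(unique(spec$bart_plus), spec$bart_minus)
  }
  bad <- intersect(gfac, c(spec$bart_terms, unlist(spec$parametric)))
  if (length(bad) > 0L)
    stop("grouping factor(s) may not appear as predictors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  spec
}

#' @export
format.bartmm_spec <- function(x, ...) {
  terms <- character(0)
  for (p in x$parametric)
    terms <- c(terms, paste(p, collapse = ":"))
  if (x$has_bart) {
    inner <- character(0)
    if (x$bart_dot) inner <- "."
    inner <- c(inner, setdiff(x$bart_plus, inner))
    b <- paste(inner, collapse = " + ")
    if (length(x$bart_minus) > 0L)
      b <- paste(b, paste("-", x$bart_minus, collapse = " "))
    terms <- c(terms, sprintf("bart(%s)", b))
  }
  for (g in x$groups) {
    l <- c(if (g$intercept) "1" else "0", g$slopes)
    terms <- c(terms, sprintf("(%s | %s)", paste(l, collapse = " + "), g$factor))
  }
  paste(x$response, "~", paste(terms, collapse = " + "))
}

#' @export
print.bartmm_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize a model specification to JSON
#' @param spec a `bartmm_spec`.
#' @return a JSON string.
#' @export
spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "bartmm_spec"))
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, null = "null")
}

#' Restore a model specification from JSON
#' @param json a string produced by [spec_to_json()].
#' @return a `bartmm_spec`.
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  x$parametric <- lapply(x$parametric, unlist)
  x$groups <- if (length(x$groups) == 0L) list() else
    lapply(seq_len(nrow(as.data.frame(x$groups))), function(i) {
      g <- x$groups[i, ]
      list(factor = g$factor, intercept = g$intercept,
           slopes = unlist(g$slopes))
    })
  if (is.null(x$treatment) || length(x$treatment) == 0L) x$treatment <- NULL
  if (is.null(x$bart_terms) || length(x$bart_terms) == 0L)
    x$bart_terms <- if (isTRUE(x$bart_dot)) NULL else character(0)
  structure(x[c("response", "treatment", "parametric", "bart_plus",
                "bart_minus", "bart_dot", "has_bart", "bart_terms", "groups",
                "outcome_kind")], class = "bartmm_spec")
}

#' Flip a binary treatment column
#'
#' Returns a copy of the table with the treatment recoded `1 - z`, leaving
#' everything else untouched; applying it twice recovers the original table.
#' This is the standard construction of the counterfactual test set for
#' causal prediction.
#'
#' @param table a data frame.
#' @param treatment name of a 0/1 column.
#' @return the table with treatment flipped.
#' @export
make_counterfactual <- function(table, treatment) {
  z <- table[[treatment]]
  if (is.null(z)) stop("treatment column '", treatment, "' not found")
  if (!all(z %in% c(0, 1))) stop("treatment must be coded 0/1")
  table[[treatment]] <- 1 - z
  table
}
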