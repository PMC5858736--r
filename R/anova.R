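# Multifactor fixed-effects ANOVA on the ordinal decision code.
#
# Terms are interactions over the lag-pair factor menu: F0..F5 (continuous
# scanpath FD), P0..P5 (3-level density group) and D1..D5 (categorical prior
# decisions). Each term gets a partial (drop-one, Type-II-style) F test:
# the model containing every requested term is compared against the model
# omitting that term. The response is the numeric ordinal decision code in a
# linear model; the source analysis states no link function, and partial
# tests keep composite overlapping terms order-independent.

parse_term <- function(term) {
  facs <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (any(duplicated(facs))) {
    stop_scanseq(sprintf("duplicate factor in term '%s'", term),
                 "scanseq_specification_error")
  }
  ok <- grepl("^[FPD][0-5]$", facs) & !(facs == "D0")
  if (!all(ok)) {
    stop_scanseq(sprintf("invalid factor symbol(s) in term '%s': %s", term,
                         paste(facs[!ok], collapse = ", ")),
                 "scanseq_specification_error")
  }
  facs
}

# columns (as a matrix) for one factor symbol, given the dataset
factor_columns <- function(dataset, sym) {
  v <- dataset[[sym]]
  kind <- substr(sym, 1, 1)
  if (kind == "F") {
    s <- stats::sd(v)
    z <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    m <- matrix(z, ncol = 1, dimnames = list(NULL, sym))
    return(m)
  }
  f <- droplevels(factor(v))
  levs <- levels(f)
  if (length(levs) < nlevels(factor(v, levels = levels(v)))) {
    warning(sprintf("factor %s: dropping unobserved level(s) %s", sym,
                    paste(setdiff(levels(v), levs), collapse = ", ")),
            call. = FALSE)
  }
  if (length(levs) < 2L) {
    return(matrix(numeric(nrow(dataset)), ncol = 0))
  }
  # treatment coding, reference = first level in canonical order
  m <- vapply(levs[-1L], function(L) as.numeric(f == L),
              numeric(length(f)))
  colnames(m) <- paste0(sym, ".", levs[-1L])
  m
}

#' Encode a design matrix for a set of ANOVA terms
#'
#' Continuous factors are standardized (mean 0, sd 1 within the dataset);
#' categorical factors are treatment-coded against their first observed
#' level; an interaction term's columns are all elementwise products of its
#' factors' columns.
#'
#' @param dataset A `lag_pair_dataset`.
#' @param terms Character vector of terms like `"F0"` or `"F0:P0:D1"`.
#' @return List with `X` (matrix, no intercept), `assign` (term index per
#'   column) and `terms`.
#' @export
encode_design <- function(dataset, terms) {
  lag <- attr(dataset, "lag") %||% 5L
  blocks <- vector("list", length(terms))
  for (ti in seq_along(terms)) {
    facs <- parse_term(terms[ti])
    depth <- max(as.integer(substr(facs, 2, 2)))
    if (depth > lag) {
      stop_scanseq(sprintf("term '%s' references lag %d but dataset depth is %d",
                           terms[ti], depth, lag),
                   "scanseq_specification_error")
    }
    miss <- setdiff(facs, names(dataset))
    if (length(miss)) {
      stop_scanseq(sprintf("term '%s': column(s) %s not in dataset",
                           terms[ti], paste(miss, collapse = ", ")),
                   "scanseq_specification_error")
    }
    cols <- lapply(facs, function(s) factor_columns(dataset, s))
    # product expansion across factors
    m <- cols[[1L]]
    if (length(cols) > 1L) {
      for (k in 2:length(cols)) {
        nxt <- cols[[k]]
        if (ncol(m) == 0L || ncol(nxt) == 0L) {
          m <- matrix(numeric(nrow(dataset)), ncol = 0)
          break
        }
        pieces <- lapply(seq_len(ncol(nxt)), function(j) {
          mm <- m * nxt[, j]
          colnames(mm) <- paste0(colnames(m), ":", colnames(nxt)[j])
          mm
        })
        m <- do.call(cbind, pieces)
      }
    }
    blocks[[ti]] <- m
  }
  X <- do.call(cbind, blocks)
  assign <- rep(seq_along(terms), vapply(blocks, ncol, integer(1)))
  list(X = X, assign = assign, terms = terms)
}

sse_of <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Multifactor fixed-effects ANOVA with partial F tests
#'
#' Fits a linear model of the response on all requested terms plus an
#' intercept and reports, for each term, the incremental F statistic of
#' dropping that term from the full model.
#'
#' @param dataset A `lag_pair_dataset`.
#' @param terms Character vector of term specifications (see
#'   [encode_design()]); `preset_table_terms()` provides a menu of composite
#'   high-order interactions.
#' @param alpha Significance level used for the `significant` flag.
#' @param response Column name of the response. A factor column is converted
#'   to its ordinal code; a numeric column is used as is. Default `"D0"`.
#' @return An `effect_table` data.frame
#'   `(term, F, p, df_num, df_den, significant)`.
#' @export
fixed_effects_anova <- function(dataset, terms, alpha = 0.05,
                                response = "D0") {
  yv <- dataset[[response]]
  if (is.null(yv)) {
    stop_scanseq(sprintf("response column '%s' not found", response),
                 "scanseq_argument_error")
  }
  y <- if (is.factor(yv)) as.numeric(yv) - 1 else as.numeric(yv)
  des <- encode_design(dataset, terms)
  X <- des$X
  n <- nrow(dataset)

  # drop constant (zero-variance) columns: empty interaction cells
  keep <- apply(X, 2, function(cc) stats::var(cc) > 0)
  if (any(!keep)) {
    warning(sprintf("dropping %d constant design column(s) from sparse cells",
                    sum(!keep)), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    des$assign <- des$assign[keep]
  }
  Xf <- cbind(`(Intercept)` = 1, X)
  if (n <= ncol(Xf)) {
    stop_scanseq(sprintf("need more rows (%d) than design columns (%d)",
                         n, ncol(Xf)),
                 "scanseq_argument_error")
  }
  qr_full <- qr(Xf)
  if (qr_full$rank < ncol(Xf)) {
    aliased <- colnames(Xf)[qr_full$pivot[(qr_full$rank + 1):ncol(Xf)]]
    atl <- unique(des$assign[match(aliased, colnames(X))])
    stop_scanseq(sprintf("rank-deficient design; aliased term(s): %s",
                         paste(terms[stats::na.omit(atl)], collapse = ", ")),
                 "scanseq_rank_deficiency")
  }
  sse_full <- sse_of(Xf, y)
  df_full <- n - ncol(Xf)
  tss <- sum((y - mean(y))^2)
  denom <- max(sse_full, .Machine$double.eps * max(tss, 1))

  rows <- lapply(seq_along(terms), function(ti) {
    in_term <- des$assign == ti
    ddf <- sum(in_term)
    if (ddf == 0L) {
      return(data.frame(term = terms[ti], F = NA_real_, p = NA_real_,
                        df_num = 0L, df_den = df_full, significant = NA))
    }
    Xr <- cbind(1, X[, !in_term, drop = FALSE])
    sse_red <- sse_of(Xr, y)
    Fstat <- max(0, (sse_red - sse_full) / ddf) / (denom / df_full)
    p <- stats::pf(Fstat, ddf, df_full, lower.tail = FALSE)
    data.frame(term = terms[ti], F = Fstat, p = p, df_num = ddf,
               df_den = df_full, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_table", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Preset composite interaction terms
#'
#' The menu of high-order interaction terms used in the reference analysis
#' of lagged reader effects (FD, density group and prior decisions up to lag
#' 5). A full factorial over all 16 factors is combinatorially impossible
#' and is refused by [encode_design()]'s size checks; this preset covers the
#' reported composite effects.
#'
#' @param max_lag Drop terms referencing lags beyond this depth.
#' @return Character vector of term specifications.
#' @export
preset_table_terms <- function(max_lag = 5) {
  terms <- c(
    "F0:P0:F1:D1:F2:P2:D2",
    "F0:F1:F3:F4:F5",
    "F0:F2:F3:F4",
    "F0:P0:F1:P1:D1:D2",
    "F0:F1:F2:F3:F4:F5",
    "F0:F3:F4:F5",
    "P0:F0:F1:P1:D1:F2:P2:D2:F3:P3:D3",
    "P0:F0:F1:P1:D1:P2:D2",
    "P0:F1:P1:D1",
    "F0:F1:P1:D1:F2:P2:D2",
    "P0:F0:F1:P1:D1:F2:P2:D2:P3:D3",
    "D1:D2:D3:D4",
    "P0:F0:F1:P1:D1",
    "F0:D1:F2:P2:D2",
    "F0:P1:D1:F2:P2:D2",
    "P0:F0:F1:P1:D1:F2:P2:D2:P3",
    "F0:F1:F3:F4",
    "P0:F0:F1:P1:D1:F2:P2:D2:F3:P3:D3:F4:P4:D4",
    "D1:D2:D3:D5",
    "P0:F0:F1:P1:D1:F2:P2:D2:F3:P3:D3:F4:P4:D4:P5:F5",
    "P0:F0:F1:P1:D1:F2:P2:D2:F3:D3",
    "F1:P1:D1:F2:P2:D2",
    "P0:F1:D1:F2:P2:D2"
  )
  depth <- vapply(terms, function(tt)
    max(as.integer(substr(parse_term(tt), 2, 2))), integer(1))
  unname(terms[depth <= max_lag])
}
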