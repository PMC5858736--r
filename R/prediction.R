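# Within-reader leave-one-case-out prediction of the current decision from
# current and lagged features, scored by support-weighted f-score against a
# random-chance (marginal-guessing) baseline.

#' Classifier specification
#'
#' @param family `"random_forest"` (bagged CART, Gini splits, sqrt(p)
#'   features per split — authored in-package), `"majority"` (predicts the
#'   training majority class) or `"stratified_random"` (guesses from the
#'   training label distribution).
#' @param ntree Trees per forest.
#' @param mtry Features per split; default `floor(sqrt(p))`.
#' @param min_node Minimum node size before a leaf is forced.
#' @param seed Integer seed (required for stochastic families).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("random_forest", "majority",
                                  "stratified_random"),
                       ntree = 500, mtry = NULL, min_node = 1, seed = 1L) {
  family <- match.arg(family)
  if (family != "majority" && is.null(seed)) {
    stop_scanseq("stochastic model families require a seed",
                 "scanseq_argument_error")
  }
  structure(list(family = family, ntree = as.integer(ntree), mtry = mtry,
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "model_spec")
}

# one-hot feature matrix from a lag-pair dataset (FD left raw: trees are
# scale-free; categorical features expanded to full indicator sets)
lag_feature_matrix <- function(dataset) {
  feats <- setdiff(names(dataset), "D0")
  cols <- lapply(feats, function(nm) {
    v <- dataset[[nm]]
    if (is.numeric(v)) {
      matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      m <- vapply(levels(f), function(L) as.numeric(f == L),
                  numeric(length(f)))
      colnames(m) <- paste0(nm, ".", levels(f))
      m
    }
  })
  do.call(cbind, cols)
}

#' Leave-one-case-out predictions
#'
#' Refits the model once per row, training on every other row, and predicts
#' the held-out row: exactly `n` predictions for `n` rows. Deterministic
#' given the spec's seed.
#'
#' @param dataset A `lag_pair_dataset` (response `D0`, >= 10 rows, >= 2
#'   observed classes).
#' @param spec A [model_spec()].
#' @return Factor of per-row held-out predictions with the levels of `D0`.
#' @export
loocv_predict <- function(dataset, spec = model_spec()) {
  n <- nrow(dataset)
  if (n < 10L) {
    stop_scanseq("need >= 10 rows for leave-one-case-out evaluation",
                 "scanseq_argument_error")
  }
  y <- factor(dataset$D0)
  if (nlevels(droplevels(y)) < 2L) {
    stop_scanseq("response has a single class", "scanseq_degenerate_labels")
  }
  levs <- levels(y)
  yi <- as.integer(y) - 1L
  X <- lag_feature_matrix(dataset)
  preds <- integer(n)

  for (k in seq_len(n)) {
    tr <- setdiff(seq_len(n), k)
    fold_seed <- substream_seed(spec$seed, "fold", k)
    if (spec$family == "random_forest") {
      mtry <- spec$mtry %||% max(1L, floor(sqrt(ncol(X))))
      preds[k] <- rf_fit_predict_cpp(X[tr, , drop = FALSE], yi[tr],
                                     X[k, , drop = FALSE],
                                     nclass = length(levs),
                                     ntree = spec$ntree, mtry = as.integer(mtry),
                                     min_node = spec$min_node,
                                     seed = fold_seed)
    } else if (spec$family == "majority") {
      tab <- tabulate(yi[tr] + 1L, nbins = length(levs))
      preds[k] <- which.max(tab) - 1L
    } else { # stratified_random
      preds[k] <- with_seed(fold_seed, sample(yi[tr], 1L))
    }
  }
  factor(levs[preds + 1L], levels = levs)
}

#' Support-weighted f-score
#'
#' Per-class f = 2PR/(P+R) (0 when P + R = 0), weighted by each class's
#' share of the truth labels.
#'
#' @param truth,predicted Equal-length category vectors.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' weighted_f_score(c("M","M","B","N"), c("M","B","B","N"))  # 0.75
weighted_f_score <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1L) {
    stop_scanseq("truth and predicted must have equal length >= 1",
                 "scanseq_argument_error")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- unique(truth)
  n <- length(truth)
  f_sum <- 0
  for (cl in classes) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    P <- if (tp + fp > 0) tp / (tp + fp) else 0
    R <- tp / (tp + fn)  # support > 0 since cl drawn from truth
    f <- if (P + R > 0) 2 * P * R / (P + R) else 0
    f_sum <- f_sum + (sum(truth == cl) / n) * f
  }
  f_sum
}

#' Random-chance baseline f-score
#'
#' Mean weighted f-score of predictions drawn from the empirical label
#' distribution of `truth` (marginal guessing). Uniform guessing cannot
#' reproduce the label-skew dependence that real chance baselines show, so
#' the marginal form is the default and only form.
#'
#' @param truth Category vector (non-empty).
#' @param reps Monte-Carlo repetitions (>= 100).
#' @param seed Integer seed.
#' @return Mean weighted f-score over `reps` random guess vectors.
#' @export
random_chance_baseline <- function(truth, reps = 1000, seed = 1L) {
  if (length(truth) < 1L) {
    stop_scanseq("truth must be non-empty", "scanseq_argument_error")
  }
  if (reps < 100) {
    stop_scanseq("reps must be >= 100", "scanseq_argument_error")
  }
  truth <- as.character(truth)
  n <- length(truth)
  with_seed(seed, {
    mean(vapply(seq_len(reps), function(i) {
      weighted_f_score(truth, sample(truth, n, replace = TRUE))
    }, numeric(1)))
  })
}

#' Per-reader, per-lag prediction report
#'
#' For every reader and every requested lag depth, builds the lag-pair
#' dataset, runs leave-one-case-out prediction, and scores it; then appends
#' per-tier average rows (arithmetic mean over the tier's readers). The
#' random-chance column is each reader's marginal baseline on the lag-0
#' truth labels.
#'
#' @param study A `reader_study`.
#' @param lags Integer lags to sweep (subset of 0..5).
#' @param spec A [model_spec()].
#' @param fd_table Optional precomputed [study_fd_table()].
#' @param grid_size Rasterization grid when FD must be computed.
#' @param baseline_reps Repetitions for [random_chance_baseline()].
#' @return A `prediction_report` data.frame
#'   `(reader_id, tier, lag, f_weighted, baseline, n, is_average)`.
#' @export
sweep_lags <- function(study, lags = 0:5, spec = model_spec(),
                       fd_table = NULL, grid_size = 512,
                       baseline_reps = 1000) {
  ann <- annotate_readings(study, fd_table = fd_table, grid_size = grid_size)
  per <- split_readers(ann)
  tiers <- stats::setNames(as.character(study$readers$tier),
                           study$readers$reader_id)
  rows <- list()
  for (rid in names(per)) {
    base <- NULL
    for (i in lags) {
      ds <- build_lag_pairs(per[[rid]], i)
      pred <- loocv_predict(ds, spec)
      f <- weighted_f_score(ds$D0, pred)
      if (is.null(base)) {
        base <- random_chance_baseline(
          build_lag_pairs(per[[rid]], 0L)$D0, reps = baseline_reps,
          seed = substream_seed(spec$seed, "baseline", rid))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        reader_id = rid, tier = tiers[[rid]], lag = i, f_weighted = f,
        baseline = base, n = nrow(ds), is_average = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  for (tt in intersect(c("N", "A", "E"), unique(out$tier))) {
    sub <- out[out$tier == tt & !out$is_average, ]
    for (i in lags) {
      si <- sub[sub$lag == i, ]
      out <- rbind(out, data.frame(
        reader_id = paste0("Avg.", tt), tier = tt, lag = i,
        f_weighted = mean(si$f_weighted), baseline = mean(si$baseline),
        n = sum(si$n), is_average = TRUE, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("prediction_report", "data.frame")
  out
}

#' Format a prediction report as a wide table
#'
#' One row per reader (and per-tier `Avg.` rows), one column per lag, plus
#' the random-chance column, f-scores rounded to 2 decimals for display.
#'
#' @param report A `prediction_report` from [sweep_lags()].
#' @return A wide data.frame.
#' @export
format_report_table <- function(report) {
  lags <- sort(unique(report$lag))
  ids <- unique(report$reader_id)
  rows <- lapply(ids, function(rid) {
    sub <- report[report$reader_id == rid, ]
    vals <- vapply(lags, function(i) sub$f_weighted[sub$lag == i][1],
                   numeric(1))
    df <- data.frame(Reader = rid, stringsAsFactors = FALSE)
    for (j in seq_along(lags)) {
      df[[if (lags[j] == 0) "Cn" else sprintf("Cn-%d", lags[j])]] <-
        round(vals[j], 2)
    }
    df$RandomChance <- round(sub$baseline[1], 2)
    df
  })
  do.call(rbind, rows)
}
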