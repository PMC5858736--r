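# Sample autocorrelation with 95% significance bands.

#' Autocorrelation function with significance band
#'
#' Computes the standard biased sample ACF,
#' `r_k = sum_t (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`,
#' for lags `1..max_lag`, together with the large-sample white-noise 95%
#' band `+/- 1.96 / sqrt(n)`. The biased (1/n) normalization is the one the
#' band is calibrated for. Decision sequences are analyzed on their ordinal
#' codes (0-6); behavior sequences on FD.
#'
#' @param series Numeric vector, `length(series) >= max_lag + 2`, with
#'   positive variance.
#' @param max_lag Largest lag `K >= 1`.
#' @return An `acf_result` list: `lags`, `r`, `band`, `significant`
#'   (logical, `|r_k| > band`), `n`.
#' @export
#' @examples
#' autocorrelation(arima.sim(list(ar = 0.5), 500), max_lag = 10)
autocorrelation <- function(series, max_lag = 20) {
  series <- as.numeric(series)
  n <- length(series)
  if (!is.numeric(max_lag) || max_lag < 1 || n < max_lag + 2) {
    stop_scanseq("need length(series) >= max_lag + 2 and max_lag >= 1",
                 "scanseq_argument_error")
  }
  if (anyNA(series)) {
    stop_scanseq("series contains NA", "scanseq_argument_error")
  }
  xc <- series - mean(series)
  denom <- sum(xc^2)
  if (denom <= 0) {
    stop_scanseq("series has zero variance", "scanseq_degenerate_series")
  }
  max_lag <- as.integer(max_lag)
  r <- vapply(seq_len(max_lag), function(k) {
    sum(xc[1:(n - k)] * xc[(k + 1):n]) / denom
  }, numeric(1))
  band <- 1.96 / sqrt(n)
  structure(list(lags = seq_len(max_lag), r = r, band = band,
                 significant = abs(r) > band, n = n),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result> n = %d, band = +/-%.4f\n", x$n, x$band))
  print(round(stats::setNames(x$r, paste0("r", x$lags)), 3))
  invisible(x)
}

#' Per-reader ACF of decision and behavior series
#'
#' Splits annotated readings by reader and computes, per session-spanning
#' sequence (the paper-style per-reader series), the ACF of the ordinal
#' decision codes and of the scanpath FD.
#'
#' @param readings Annotated readings (see [annotate_readings()]).
#' @param max_lag Largest lag.
#' @return data.frame `(reader_id, series, lag, r, band, significant)`.
#' @export
study_acf_table <- function(readings, max_lag = 20) {
  per <- split_readers(readings)
  rows <- lapply(names(per), function(rid) {
    df <- per[[rid]]
    res <- list(decision = autocorrelation(df$decision_code, max_lag),
                fd = autocorrelation(df$fd, max_lag))
    do.call(rbind, lapply(names(res), function(sn) {
      a <- res[[sn]]
      data.frame(reader_id = rid, series = sn, lag = a$lags, r = a$r,
                 band = a$band, significant = a$significant,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
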