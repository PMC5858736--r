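# Lag-structured datasets: pair the current decision D0 with behavior (FD),
# density group and decisions of up to five preceding cases. Session breaks
# restart the lag structure: no row ever spans a segment boundary, so a
# reader with s interruptions contributes sum over the s+1 segments of
# max(0, segment_length - i) rows at lag depth i.

#' Attach FD and analysis codings to a study's readings
#'
#' Joins the per-reading FD table onto the readings and adds the decision
#' coding of the reported rating and the density group of the interpreted
#' case.
#'
#' @param study A `reader_study`.
#' @param fd_table Output of [study_fd_table()]; computed on the fly when
#'   `NULL` (requires gaze data).
#' @param grid_size Used when `fd_table` is `NULL`.
#' @param coding Decision coding, `"7"` or `"6"`.
#' @return The readings data.frame with columns `fd`, `decision_cat`,
#'   `decision_group`, `decision_code`, `density`, `density_group`, ordered
#'   by reader then `order_index`.
#' @export
annotate_readings <- function(study, fd_table = NULL, grid_size = 512,
                              coding = "7") {
  rd <- study$readings
  if (is.null(fd_table)) fd_table <- study_fd_table(study, grid_size)
  key <- function(df) paste(df$reader_id, df$case_id, sep = "\r")
  m <- match(key(rd), key(fd_table))
  if (anyNA(m)) {
    stop_scanseq("FD missing for one or more readings", "scanseq_data_error")
  }
  rd$fd <- fd_table$fd[m]
  cod <- map_decision(rd$decision, coding = coding)
  rd$decision_cat <- cod$category
  rd$decision_group <- cod$group
  rd$decision_code <- cod$ordinal_code
  mc <- match(rd$case_id, study$cases$case_id)
  rd$density <- study$cases$density[mc]
  rd$density_group <- map_density(rd$density)
  rd[order(rd$reader_id, rd$order_index), ]
}

#' Build the lag-pair dataset for one reader
#'
#' For lag depth `i`, each row pairs the current decision `D0` with the
#' current and lagged scanpath FD (`F0..Fi`), density group (`P0..Pi`) and
#' the previous decisions (`D1..Di`), all taken strictly from within the same
#' session segment.
#'
#' @param readings Annotated readings (see [annotate_readings()]) for a
#'   single reader, sorted by `order_index`, with `fd` present.
#' @param i Lag depth, integer 0..5.
#' @return A `lag_pair_dataset` data.frame with columns `D0`, then
#'   `F0, P0`, `F1, P1, D1`, ..., plus attributes `lag`, `n_segments`.
#' @export
#' @examples
#' st <- generate_study(c(N = 1), n_cases = 12, gaze = FALSE, seed = 3)
#' rd <- st$readings
#' rd$fd <- seq_len(nrow(rd))  # stand-in FD
#' rd <- cbind(rd, map_decision(rd$decision)[, c("category", "group")],
#'             decision_code = map_decision(rd$decision)$ordinal_code)
build_lag_pairs <- function(readings, i) {
  if (!is.numeric(i) || length(i) != 1L || i < 0 || i > 5 || i != floor(i)) {
    stop_scanseq("lag depth i must be an integer in 0..5",
                 "scanseq_argument_error")
  }
  i <- as.integer(i)
  if (length(unique(readings$reader_id)) > 1L) {
    stop_scanseq("build_lag_pairs expects readings from a single reader; use split_readers()",
                 "scanseq_argument_error")
  }
  if (is.null(readings$fd) || anyNA(readings$fd)) {
    stop_scanseq("FD missing for one or more readings", "scanseq_data_error")
  }
  if (is.unsorted(readings$order_index)) {
    readings <- readings[order(readings$order_index), ]
  }
  if (is.null(readings$decision_code)) {
    cod <- map_decision(readings$decision)
    readings$decision_cat <- cod$category
    readings$decision_code <- cod$ordinal_code
  }
  if (is.null(readings$density_group) && !is.null(readings$density)) {
    readings$density_group <- map_density(readings$density)
  }

  segs <- split(seq_len(nrow(readings)), readings$session_segment)
  rows <- lapply(segs, function(ii) {
    len <- length(ii)
    if (len <= i) return(NULL)
    pos <- ii[(i + 1L):len]           # current index n within segment
    out <- data.frame(D0 = readings$decision_cat[pos])
    for (j in 0:i) {
      lagpos <- pos - j
      out[[paste0("F", j)]] <- readings$fd[lagpos]
      out[[paste0("P", j)]] <- readings$density_group[lagpos]
      if (j >= 1L) out[[paste0("D", j)]] <- readings$decision_cat[lagpos]
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    # empty dataset with the right columns
    cols <- c("D0", unlist(lapply(0:i, function(j)
      c(paste0("F", j), paste0("P", j), if (j >= 1) paste0("D", j)))))
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  rownames(out) <- NULL
  structure(out, lag = i, n_segments = length(segs),
            class = c("lag_pair_dataset", "data.frame"))
}

#' Split annotated readings by reader
#' @param readings Annotated readings table.
#' @return Named list of per-reader data.frames sorted by order index.
#' @export
split_readers <- function(readings) {
  lapply(split(readings, readings$reader_id),
         function(df) df[order(df$order_index), ])
}
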