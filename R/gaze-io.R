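# Tabular I/O for the pipeline's plain-text formats.
#
# Dialect: tab-separated values; metadata as leading '#key<TAB>value' lines;
# one header row of column names. Coordinates are pixels, origin top-left,
# y increasing downward, 0-based continuous. Numeric fields are written with
# 6 decimals, so round trips are exact to that precision.

GAZE_COLS <- c("reader_id", "case_id", "t", "x", "y", "display")
READINGS_COLS <- c("reader_id", "case_id", "order_index", "session_segment",
                   "decision")
CASES_COLS <- c("case_id", "pathology", "density", "truth_rating")

fmt_num <- function(x) formatC(x, format = "f", digits = 6, drop0trailing = FALSE)

write_tsv_with_meta <- function(path, df, meta = list(), num_cols = character(0)) {
  out <- df
  for (cc in intersect(num_cols, names(out))) out[[cc]] <- fmt_num(out[[cc]])
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("#%s\t%s", k, format(meta[[k]])), con)
  }
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_with_meta <- function(path) {
  if (!file.exists(path)) {
    stop_scanseq(sprintf("file not found: %s", path), "scanseq_io_error")
  }
  lines <- readLines(path)
  n_meta <- 0L
  meta <- list()
  while (n_meta < length(lines) && startsWith(lines[n_meta + 1L], "#")) {
    n_meta <- n_meta + 1L
    kv <- strsplit(sub("^#", "", lines[n_meta]), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (length(kv) > 1L) kv[2] else ""
  }
  if (n_meta >= length(lines)) {
    stop_scanseq("missing header row", "scanseq_schema_error")
  }
  header <- strsplit(lines[n_meta + 1L], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(n_meta + 1L)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(header))) {
      bad <- which(nf != length(header))[1]
      stop_scanseq(sprintf("malformed row at line %d of %s: expected %d fields, got %d",
                           bad + n_meta + 1L, path, length(header), nf[bad]),
                   "scanseq_parse_error")
    }
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(df) <- header
  } else {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(header)),
                                        header))
  }
  list(meta = meta, data = df, n_meta = n_meta)
}

# coerce character column to numeric; error names the first offending line
coerce_num_col <- function(df, col, path, n_meta) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad)) {
    stop_scanseq(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                         df[[col]][bad[1]], col, bad[1] + n_meta + 1L, path),
                 "scanseq_parse_error")
  }
  v
}

check_schema <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_scanseq(sprintf("missing column(s) %s in %s",
                         paste(miss, collapse = ", "), path),
                 "scanseq_schema_error")
  }
}

#' Write / read a gaze table
#'
#' The gaze table holds raw multi-display gaze rows
#' `(reader_id, case_id, t, x, y, display)` with the sampling rate and the
#' display geometry in `#`-prefixed metadata lines. Unknown extra columns are
#' preserved on round trip.
#'
#' @param path File path.
#' @param gaze data.frame with at least the gaze columns.
#' @param rate Sampling rate (Hz) for the header.
#' @param geometry A [display_geometry()].
#' @return `write_gaze` returns `path` invisibly; `read_gaze` returns a list
#'   with `data` (data.frame), `rate` and `geometry`.
#' @export
write_gaze <- function(path, gaze, rate = 60, geometry = display_geometry()) {
  check_schema(gaze, GAZE_COLS, "gaze table")
  meta <- list(rate = rate, display_width = geometry$width,
               display_height = geometry$height,
               n_displays = geometry$n_displays)
  write_tsv_with_meta(path, gaze, meta, num_cols = c("t", "x", "y"))
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  raw <- read_tsv_with_meta(path)
  check_schema(raw$data, GAZE_COLS, path)
  df <- raw$data
  for (cc in c("t", "x", "y")) df[[cc]] <- coerce_num_col(df, cc, path, raw$n_meta)
  df$display <- as.integer(coerce_num_col(df, "display", path, raw$n_meta))
  geo <- display_geometry(
    width = as.numeric(raw$meta$display_width %||% 1280),
    height = as.numeric(raw$meta$display_height %||% 1024),
    n_displays = as.integer(raw$meta$n_displays %||% 2))
  list(data = df, rate = as.numeric(raw$meta$rate %||% 60), geometry = geo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a readings table
#'
#' Rows `(reader_id, case_id, order_index, session_segment, decision)`, one
#' per reader-case interpretation event.
#'
#' @param path File path.
#' @param readings data.frame with at least the readings columns.
#' @return `write_readings` returns `path` invisibly; `read_readings` a
#'   data.frame.
#' @export
write_readings <- function(path, readings) {
  check_schema(readings, READINGS_COLS, "readings table")
  write_tsv_with_meta(path, readings, num_cols = "duration")
}

#' @rdname write_readings
#' @export
read_readings <- function(path) {
  raw <- read_tsv_with_meta(path)
  check_schema(raw$data, READINGS_COLS, path)
  df <- raw$data
  df$order_index <- as.integer(coerce_num_col(df, "order_index", path, raw$n_meta))
  df$session_segment <- as.integer(coerce_num_col(df, "session_segment", path,
                                                  raw$n_meta))
  if ("duration" %in% names(df)) {
    df$duration <- coerce_num_col(df, "duration", path, raw$n_meta)
  }
  if (anyDuplicated(df[c("reader_id", "order_index")])) {
    stop_scanseq("duplicate (reader_id, order_index) in readings table",
                 "scanseq_schema_error")
  }
  df
}

#' Write / read a cases table
#'
#' Rows `(case_id, pathology, density, truth_rating)`.
#' @param path File path.
#' @param cases data.frame with at least the cases columns.
#' @return `write_cases` returns `path` invisibly; `read_cases` a data.frame.
#' @export
write_cases <- function(path, cases) {
  check_schema(cases, CASES_COLS, "cases table")
  out <- cases
  out$pathology <- as.character(out$pathology)
  write_tsv_with_meta(path, out)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  raw <- read_tsv_with_meta(path)
  check_schema(raw$data, CASES_COLS, path)
  df <- raw$data
  df$density <- as.integer(coerce_num_col(df, "density", path, raw$n_meta))
  df$pathology <- factor(df$pathology, levels = pathology_levels())
  df
}

#' Assemble one reading's scanpath into the global display frame
#'
#' Maps samples from both displays into a single coordinate frame (display 2
#' is offset horizontally by the display-1 width), merges them and sorts by
#' time. Ties on `t` keep input order (stable sort), so assembly is invariant
#' to shuffling the input rows of distinct timestamps.
#'
#' @param gaze_rows data.frame with columns `t, x, y, display` for a single
#'   reading (>= 1 row).
#' @param geometry A [display_geometry()].
#' @param rate Sampling rate recorded on the result.
#' @return A `gaze_stream` in the global frame (all rows `display = 1`,
#'   x in `[0, n_displays * width)`).
#' @export
assemble_scanpath <- function(gaze_rows, geometry = display_geometry(),
                              rate = 60) {
  if (is.null(gaze_rows) || nrow(gaze_rows) == 0L) {
    stop_scanseq("cannot assemble an empty scanpath", "scanseq_empty_scanpath")
  }
  check_schema(gaze_rows, c("t", "x", "y", "display"), "gaze rows")
  gx <- gaze_rows$x + (as.integer(gaze_rows$display) - 1L) * geometry$width
  ord <- order(gaze_rows$t)  # stable in R
  global <- display_geometry(width = geometry$width * geometry$n_displays,
                             height = geometry$height, n_displays = 1L)
  new_gaze_stream(t = gaze_rows$t[ord], x = gx[ord], y = gaze_rows$y[ord],
                  display = 1L, rate = rate, geometry = global)
}
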