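# Minkowski-Bouligand (box-counting) fractal dimension of a scanpath.
#
# The trajectory of time-ordered raw gaze samples is rasterized onto a square
# power-of-two occupancy grid (consecutive samples joined by conservative
# line segments: every cell a segment touches is occupied), box counts
# N(eps) are taken over aligned non-overlapping eps x eps blocks at dyadic
# scales, and the dimension is the OLS slope of log N(eps) vs log(1/eps)
# over the non-saturated scales.

#' Rasterize a scanpath onto an occupancy grid
#'
#' The global display frame is scaled into the grid preserving aspect ratio
#' (letterboxed), and consecutive samples are connected by discrete line
#' segments; every grid cell touched by any segment becomes occupied.
#'
#' @param stream A `gaze_stream` (see [assemble_scanpath()]), or any
#'   data.frame with `x`, `y` columns in a frame described by `frame`.
#' @param grid_size Grid side `G` (power of two, >= 4).
#' @param frame Optional `c(width, height)` of the coordinate frame; defaults
#'   to the stream's geometry (global width = width * n_displays).
#' @return An `occupancy_grid`: logical `G x G` matrix (rows = y), with
#'   attribute `n_occupied`.
#' @export
rasterize_scanpath <- function(stream, grid_size = 512, frame = NULL) {
  if (is.null(stream) || nrow(stream) == 0L) {
    stop_scanseq("cannot rasterize an empty scanpath", "scanseq_empty_scanpath")
  }
  if (!is_power_of_two(grid_size) || grid_size < 4) {
    stop_scanseq("grid_size must be a power of two >= 4",
                 "scanseq_argument_error")
  }
  if (is.null(frame)) {
    geo <- attr(stream, "geometry")
    if (is.null(geo)) {
      frame <- c(max(stream$x) + 1, max(stream$y) + 1)
    } else {
      frame <- c(geo$width * geo$n_displays, geo$height)
    }
  }
  scale <- grid_size / max(frame)  # aspect-preserving; short side letterboxed
  gx <- clamp(stream$x * scale, 0, grid_size - 1e-9)
  gy <- clamp(stream$y * scale, 0, grid_size - 1e-9)
  occ <- raster_supercover_cpp(as.numeric(gx), as.numeric(gy),
                               as.integer(grid_size))
  structure(occ, n_occupied = sum(occ), class = "occupancy_grid")
}

default_scales <- function(G) 2^(1:(log2(G) - 2))  # {2, 4, ..., G/4}

#' Box counts of an occupancy grid at dyadic scales
#'
#' For each scale `eps`, counts the number of aligned, non-overlapping
#' `eps x eps` blocks containing at least one occupied cell.
#'
#' @param grid An `occupancy_grid` (logical square matrix).
#' @param scales Strictly increasing box sides; each must divide the grid
#'   side. Default `{2, 4, ..., G/4}`.
#' @return A `box_count_curve` list: `scales`, `counts`, `n_occupied`.
#' @export
box_count <- function(grid, scales = NULL) {
  G <- nrow(grid)
  if (is.null(scales)) scales <- default_scales(G)
  scales <- as.integer(scales)
  if (any(G %% scales != 0L)) {
    stop_scanseq("every scale must divide the grid size",
                 "scanseq_argument_error")
  }
  cells <- which(grid, arr.ind = TRUE)
  if (nrow(cells) == 0L) {
    stop_scanseq("grid has no occupied cells", "scanseq_argument_error")
  }
  r0 <- cells[, 1L] - 1L
  c0 <- cells[, 2L] - 1L
  counts <- vapply(scales, function(eps) {
    nb <- G %/% eps
    length(unique((r0 %/% eps) * nb + (c0 %/% eps)))
  }, integer(1))
  structure(list(scales = scales, counts = counts, n_occupied = nrow(cells)),
            class = "box_count_curve")
}

#' Fractal dimension from a box-count curve
#'
#' Fits `log N(eps) ~ log(1/eps)` by ordinary least squares over the usable
#' scales. Saturated scales are excluded: where `N(eps) = 1` (bottom
#' saturation) only the first such scale is kept, and where `N(eps)` equals
#' the number of occupied cells (top saturation: refinement exhausted) only
#' the coarsest such scale is kept. A curve with `N(eps) = 1` everywhere is
#' the degenerate point case and returns `fd = 0` exactly. Otherwise at least
#' 3 usable scales are required.
#'
#' @param curve A `box_count_curve` from [box_count()].
#' @return An `fd_result` list: `fd`, `r2`, `scales_used`.
#' @export
fractal_dimension <- function(curve) {
  eps <- as.numeric(curve$scales)
  N <- as.numeric(curve$counts)
  if (all(N == 1)) {
    return(structure(list(fd = 0, r2 = 1, scales_used = curve$scales),
                     class = "fd_result"))
  }
  keep <- rep(TRUE, length(N))
  ones <- which(N == 1)          # at the large-eps end (N non-increasing)
  if (length(ones) > 1L) keep[ones[-1L]] <- FALSE
  if (!is.null(curve$n_occupied)) {
    sat <- which(N == curve$n_occupied)  # at the small-eps end
    if (length(sat) > 1L) keep[utils::head(sat, -1L)] <- FALSE
  }
  eps <- eps[keep]
  N <- N[keep]
  if (length(N) < 3L) {
    stop_scanseq(sprintf("only %d usable scale(s) after saturation filtering (need >= 3)",
                         length(N)),
                 "scanseq_insufficient_scales")
  }
  lx <- log(1 / eps)
  ly <- log(N)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  fd <- unname(fit$coefficients[2])
  ssr <- sum(fit$residuals^2)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(list(fd = fd, r2 = r2, scales_used = as.integer(eps)),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> fd = %.4f (r2 = %.4f, %d scales)\n",
              x$fd, x$r2, length(x$scales_used)))
  invisible(x)
}

#' Fractal dimension of a scanpath (convenience wrapper)
#'
#' Rasterize, box-count and fit in one call.
#'
#' @inheritParams rasterize_scanpath
#' @param scales Passed to [box_count()].
#' @return An `fd_result`.
#' @export
#' @examples
#' s <- generate_scanpath(duration = 5, complexity = 0.6, seed = 2)
#' scanpath_fd(s)
scanpath_fd <- function(stream, grid_size = 512, scales = NULL, frame = NULL) {
  fractal_dimension(box_count(rasterize_scanpath(stream, grid_size, frame),
                              scales))
}

#' Per-reading FD table for a study
#'
#' Assembles each reading's scanpath into the global frame and computes its
#' fractal dimension.
#'
#' @param study A `reader_study` with gaze data, or a list with `gaze`
#'   (long gaze table), `geometry` and `rate`.
#' @param grid_size Grid side for rasterization.
#' @return data.frame `(reader_id, case_id, fd, r2, n_scales)`.
#' @export
study_fd_table <- function(study, grid_size = 512) {
  if (is.null(study$gaze)) {
    stop_scanseq("study has no gaze data", "scanseq_argument_error")
  }
  key <- paste(study$gaze$reader_id, study$gaze$case_id, sep = "\r")
  idx <- split(seq_len(nrow(study$gaze)), key)
  rows <- lapply(idx, function(ii) {
    g <- study$gaze[ii, ]
    sp <- assemble_scanpath(g, geometry = study$geometry, rate = study$rate)
    fd <- scanpath_fd(sp, grid_size = grid_size)
    data.frame(reader_id = g$reader_id[1], case_id = g$case_id[1],
               fd = fd$fd, r2 = fd$r2, n_scales = length(fd$scales_used),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
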