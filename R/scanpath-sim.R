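# Synthetic gaze scanpaths: a fixation-saccade random walk standing in for
# recorded eye-position data. Not a biophysical model: its one job is to give
# the complexity knob a monotone effect on box-counting fractal dimension.

#' Dual-display geometry
#'
#' @param width,height Per-display pixel dimensions.
#' @param n_displays Number of side-by-side displays (1 or 2).
#' @return A `display_geometry` list. The global frame concatenates displays
#'   horizontally: global x in `[0, n_displays * width)`, origin top-left,
#'   y increasing downward.
#' @export
display_geometry <- function(width = 1280, height = 1024, n_displays = 2) {
  assert_scalar_number(width, "width", 1)
  assert_scalar_number(height, "height", 1)
  if (!n_displays %in% 1:2) {
    stop_scanseq("n_displays must be 1 or 2", "scanseq_argument_error")
  }
  structure(list(width = width, height = height,
                 n_displays = as.integer(n_displays)),
            class = "display_geometry")
}

new_gaze_stream <- function(t, x, y, display, rate, geometry) {
  structure(
    data.frame(t = t, x = x, y = y, display = as.integer(display)),
    rate = rate, geometry = geometry,
    class = c("gaze_stream", "data.frame")
  )
}

#' @export
print.gaze_stream <- function(x, ...) {
  geo <- attr(x, "geometry")
  cat(sprintf("<gaze_stream> %d samples @ %g Hz, %d display(s) %gx%g\n",
              nrow(x), attr(x, "rate"), geo$n_displays, geo$width, geo$height))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Simulate a gaze scanpath for one case reading
#'
#' Generates an alternating sequence of fixation clusters (Gaussian dwell
#' jitter around a fixation center) and saccadic jumps (straight-line
#' transitions), sampled at a fixed rate. The `complexity` knob increases
#' both the expected number of fixation clusters (Poisson) and their spatial
#' dispersion, so the box-counting fractal dimension of the resulting
#' trajectory increases with it on average.
#'
#' @param case One-row case data.frame (used only to seed difficulty; may be
#'   `NULL`).
#' @param profile One-row reader profile (uses `complexity_gain`; may be
#'   `NULL`).
#' @param duration Viewing time in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0); eye trackers in this setting run at
#'   60 Hz.
#' @param bounds A [display_geometry()].
#' @param complexity Complexity knob in `[0, 1]`. If `NULL`, derived from the
#'   case's density and the profile's `complexity_gain`.
#' @param seed Integer seed; output is deterministic given all arguments.
#' @return A `gaze_stream`: data.frame `(t, x, y, display)` with attributes
#'   `rate` and `geometry`. `x`, `y` are display-local pixel coordinates
#'   (origin top-left), `display` in 1..2; sample count is
#'   `floor(duration * rate)`.
#' @export
#' @examples
#' s <- generate_scanpath(duration = 10, rate = 60, complexity = 0.5, seed = 1)
#' nrow(s)  # 600
generate_scanpath <- function(case = NULL, profile = NULL,
                              duration = 20, rate = 60,
                              bounds = display_geometry(),
                              complexity = NULL, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(rate) || rate <= 0) {
    stop_scanseq("duration and rate must be positive", "scanseq_argument_error")
  }
  if (is.null(complexity)) {
    dens <- if (!is.null(case)) as.integer(case$density[1]) else 2L
    gain <- if (!is.null(profile)) profile$complexity_gain[1] else 0.5
    complexity <- clamp(0.2 + gain * (dens - 1) / 3, 0, 1)
  }
  assert_scalar_number(complexity, "complexity", 0, 1)

  n <- floor(duration * rate)
  W <- bounds$width * bounds$n_displays
  H <- bounds$height
  with_seed(seed, {
    # number of fixation clusters grows with complexity; at least 2
    n_fix <- max(2L, stats::rpois(1L, lambda = 3 + 45 * complexity))
    # fixation centers: uniform over a central active region whose extent
    # grows with complexity (dispersion part of the knob)
    half_w <- (0.25 + 0.75 * complexity) * W / 2
    half_h <- (0.25 + 0.75 * complexity) * H / 2
    cx <- stats::runif(n_fix, W / 2 - half_w, W / 2 + half_w)
    cy <- stats::runif(n_fix, H / 2 - half_h, H / 2 + half_h)

    sacc_len <- 3L                         # ~50 ms saccade at 60 Hz
    n_sacc <- (n_fix - 1L) * sacc_len
    n_dwell <- max(n_fix, n - n_sacc)
    # allocate dwell samples across fixations (each gets >= 1)
    alloc <- rep(n_dwell %/% n_fix, n_fix)
    extra <- n_dwell - sum(alloc)
    if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L

    jitter_sd <- 4 + 26 * complexity
    xs <- vector("list", 2L * n_fix - 1L)
    ys <- vector("list", 2L * n_fix - 1L)
    for (f in seq_len(n_fix)) {
      k <- alloc[f]
      xs[[2L * f - 1L]] <- cx[f] + stats::rnorm(k, 0, jitter_sd)
      ys[[2L * f - 1L]] <- cy[f] + stats::rnorm(k, 0, jitter_sd)
      if (f < n_fix) {
        frac <- seq_len(sacc_len) / (sacc_len + 1)
        xs[[2L * f]] <- cx[f] + frac * (cx[f + 1L] - cx[f])
        ys[[2L * f]] <- cy[f] + frac * (cy[f + 1L] - cy[f])
      }
    }
    gx <- clamp(unlist(xs), 0, W - 1e-6)[seq_len(n)]
    gy <- clamp(unlist(ys), 0, H - 1e-6)[seq_len(n)]
    display <- ifelse(gx >= bounds$width & bounds$n_displays == 2L, 2L, 1L)
    lx <- gx - (display - 1L) * bounds$width
    new_gaze_stream(t = (seq_len(n) - 1L) / rate, x = lx, y = gy,
                    display = display, rate = rate, geometry = bounds)
  })
}
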