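# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive: the oracles must not share code paths with the package.

# --- scanpath fixtures -------------------------------------------------------

# a bare gaze_stream-like data.frame in an explicit frame
make_stream <- function(x, y, rate = 60, width = NULL, height = NULL) {
  df <- data.frame(t = (seq_along(x) - 1) / rate, x = x, y = y, display = 1L)
  class(df) <- c("gaze_stream", "data.frame")
  attr(df, "rate") <- rate
  if (!is.null(width)) {
    attr(df, "geometry") <- display_geometry(width = width, height = height,
                                             n_displays = 1)
  }
  df
}

# Koch snowflake edge (iteration k) as a polyline from (0,0) to (1,0)
koch_polyline <- function(k) {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  for (iter in seq_len(k)) {
    out <- list()
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      d <- (b - a) / 3
      p1 <- a + d
      p2 <- a + 2 * d
      # rotate d by -60 degrees (peak points "up" in screen coords)
      rot <- c(d[1] * cos(-pi / 3) - d[2] * sin(-pi / 3),
               d[1] * sin(-pi / 3) + d[2] * cos(-pi / 3))
      peak <- p1 + rot
      out[[i]] <- rbind(a, p1, peak, p2)
    }
    pts <- rbind(do.call(rbind, out), pts[nrow(pts), ])
  }
  pts
}

# --- rasterization oracle ----------------------------------------------------

# min Chebyshev distance from point (cx, cy) to segment (x0,y0)-(x1,y1) via
# ternary search (the objective is convex in the segment parameter)
cheb_dist_seg <- function(cx, cy, x0, y0, x1, y1) {
  f <- function(t) {
    px <- x0 + t * (x1 - x0)
    py <- y0 + t * (y1 - y0)
    max(abs(px - cx), abs(py - cy))
  }
  lo <- 0; hi <- 1
  for (i in 1:80) {
    m1 <- lo + (hi - lo) / 3
    m2 <- hi - (hi - lo) / 3
    if (f(m1) <= f(m2)) hi <- m2 else lo <- m1
  }
  f((lo + hi) / 2)
}

# brute-force supercover: all cells whose closed unit square a segment
# touches, i.e. cells with center within half a cell (Chebyshev) of it
oracle_raster <- function(px, py, G) {
  occ <- matrix(FALSE, G, G)
  clampi <- function(v) pmin(pmax(v, 1), G)
  for (i in seq_along(px)) {
    occ[clampi(floor(py[i]) + 1), clampi(floor(px[i]) + 1)] <- TRUE
  }
  for (i in seq_len(length(px) - 1)) {
    x0 <- px[i]; y0 <- py[i]; x1 <- px[i + 1]; y1 <- py[i + 1]
    cr <- clampi(c(floor(min(y0, y1)), floor(max(y0, y1))) + 1)
    cc <- clampi(c(floor(min(x0, x1)), floor(max(x0, x1))) + 1)
    for (r in cr[1]:cr[2]) {
      for (cl in cc[1]:cc[2]) {
        d <- cheb_dist_seg(cl - 0.5, r - 0.5, x0, y0, x1, y1)
        if (d < 0.5 - 1e-9) occ[r, cl] <- TRUE
      }
    }
  }
  occ
}

# --- box-count oracle --------------------------------------------------------

# double-loop block scan
oracle_box_count <- function(grid, scales) {
  G <- nrow(grid)
  vapply(scales, function(eps) {
    nb <- G %/% eps
    cnt <- 0L
    for (bi in seq_len(nb)) {
      for (bj in seq_len(nb)) {
        rows <- ((bi - 1) * eps + 1):(bi * eps)
        cols <- ((bj - 1) * eps + 1):(bj * eps)
        if (any(grid[rows, cols])) cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
}

# --- ANOVA oracle ------------------------------------------------------------

# classical one-way ANOVA from explicit group means and sums of squares
oracle_oneway <- function(y, g) {
  g <- as.factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  sse <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  Fv <- (ssb / df1) / (sse / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

# --- chance-baseline oracle --------------------------------------------------

# exact expectation of the weighted f-score under marginal guessing by
# enumerating all |classes|^n prediction vectors
oracle_chance_exact <- function(truth) {
  classes <- unique(truth)
  n <- length(truth)
  p_class <- table(factor(truth, classes)) / n
  grids <- do.call(expand.grid, rep(list(classes), n))
  tot <- 0
  for (i in seq_len(nrow(grids))) {
    pred <- as.character(unlist(grids[i, ]))
    prob <- prod(p_class[pred])
    tot <- tot + prob * weighted_f_score(truth, pred)
  }
  tot
}

# --- misc --------------------------------------------------------------------

# small annotated single-reader readings table with deterministic columns
tiny_readings <- function(n = 12, segments = 1, seed = 42) {
  st <- generate_study(c(N = 1), n_cases = n, gaze = FALSE,
                       session_breaks = if (segments > 1)
                         list(N1 = floor(n / segments * seq_len(segments - 1)))
                       else NULL,
                       seed = seed)
  rd <- st$readings
  cod <- map_decision(rd$decision)
  rd$decision_cat <- cod$category
  rd$decision_group <- cod$group
  rd$decision_code <- cod$ordinal_code
  rd$density <- st$cases$density[match(rd$case_id, st$cases$case_id)]
  rd$density_group <- map_density(rd$density)
  rd$fd <- with_seed_local(seed, runif(n, 1, 2))
  rd
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
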