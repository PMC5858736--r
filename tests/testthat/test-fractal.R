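# fractal: rasterization, box counting, dimension estimation

test_that("single samples and straight runs rasterize exactly", {
  s1 <- make_stream(10.5, 20.5, width = 64, height = 64)
  g <- rasterize_scanpath(s1, grid_size = 64)
  expect_equal(sum(g), 1)

  # two samples on the same row k cells apart -> k + 1 occupied cells
  s2 <- make_stream(c(3.5, 11.5), c(7.5, 7.5), width = 64, height = 64)
  g2 <- rasterize_scanpath(s2, grid_size = 64)
  expect_equal(sum(g2), 9)  # cells 3..11 inclusive

  empty <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      display = integer(0))
  expect_error(rasterize_scanpath(empty), class = "scanseq_empty_scanpath")
  expect_error(rasterize_scanpath(s1, grid_size = 48),
               class = "scanseq_argument_error")
})

test_that("rasterization equals the brute-force supercover oracle", {
  set.seed(31)
  for (rep in 1:5) {
    G <- 64
    n <- 100
    px <- runif(n, 0.2, G - 0.2)
    py <- runif(n, 0.2, G - 0.2)
    s <- make_stream(px, py, width = G, height = G)
    got <- unclass(rasterize_scanpath(s, grid_size = G))
    attr(got, "n_occupied") <- NULL
    want <- oracle_raster(px, py, G)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("box counts match trivial closed forms", {
  full <- matrix(TRUE, 64, 64)
  bc <- box_count(full, scales = c(2, 4, 8, 16))
  expect_equal(bc$counts, c(1024L, 256L, 64L, 16L))
  expect_equal(bc$counts[bc$scales == 4], 256L)  # (G/eps)^2

  single <- matrix(FALSE, 64, 64)
  single[10, 17] <- TRUE
  bc1 <- box_count(single)
  expect_true(all(bc1$counts == 1L))

  expect_error(box_count(full, scales = c(3)), class = "scanseq_argument_error")
  expect_error(box_count(matrix(FALSE, 8, 8)), class = "scanseq_argument_error")
})

test_that("box counts equal a double-loop block-scan oracle on random grids", {
  set.seed(17)
  for (rep in 1:6) {
    G <- 64
    grid <- matrix(runif(G * G) < runif(1, 0.02, 0.3), G, G)
    if (!any(grid)) grid[1, 1] <- TRUE
    scales <- c(2L, 4L, 8L, 16L)
    expect_equal(box_count(grid, scales)$counts,
                 oracle_box_count(grid, scales), ignore_attr = TRUE)
  }
})

test_that("box-count curves obey monotonicity and nesting bounds", {
  set.seed(23)
  for (rep in 1:10) {
    G <- 128
    grid <- matrix(runif(G * G) < runif(1, 0.01, 0.2), G, G)
    if (!any(grid)) grid[5, 5] <- TRUE
    bc <- box_count(grid)
    expect_true(all(diff(bc$counts) <= 0))          # N(eps) non-increasing
    expect_true(all(bc$counts >= 1))
    # a box at 2*eps covers at most 4 boxes at eps
    k <- length(bc$counts)
    expect_true(all(bc$counts[-k] <= 4 * bc$counts[-1]))
  }
})

test_that("counts are invariant to translation by the largest scale", {
  G <- 128
  set.seed(5)
  grid <- matrix(FALSE, G, G)
  pts <- cbind(sample(40:60, 30, TRUE), sample(40:60, 30, TRUE))
  grid[pts] <- TRUE
  eps_max <- G / 4
  shifted <- matrix(FALSE, G, G)
  shifted[pts + eps_max] <- TRUE
  expect_equal(box_count(grid)$counts, box_count(shifted)$counts)
})

test_that("fractal dimension recovers exact and analytic cases", {
  # filled grid: N(eps) = (G/eps)^2 exactly -> fd = 2
  fd_full <- fractal_dimension(box_count(matrix(TRUE, 64, 64)))
  expect_equal(fd_full$fd, 2.0, tolerance = 1e-10)

  # single point -> fd = 0
  single <- matrix(FALSE, 64, 64)
  single[3, 3] <- TRUE
  expect_equal(fractal_dimension(box_count(single))$fd, 0.0)

  # diagonal line spanning the grid
  n <- 512
  diag_s <- make_stream(seq(0.5, 511.5, length.out = n),
                        seq(0.5, 511.5, length.out = n),
                        width = 512, height = 512)
  fd_diag <- scanpath_fd(diag_s, grid_size = 512)
  expect_gte(fd_diag$fd, 0.95)
  expect_lte(fd_diag$fd, 1.05)

  # Koch polyline iteration 5: analytic similarity dimension log4/log3
  pts <- koch_polyline(5)
  expect_gte(nrow(pts), 1025)
  ks <- make_stream(pts[, 1] * 500 + 6, pts[, 2] * 500 + 200,
                    width = 512, height = 512)
  fd_koch <- scanpath_fd(ks, grid_size = 512)
  expect_lt(abs(fd_koch$fd - log(4) / log(3)), 0.1)
})

test_that("dimension estimates stay in planar bounds on arbitrary inputs", {
  for (seed in 1:20) {
    s <- generate_scanpath(duration = 2, complexity = runif(1), seed = seed)
    fd <- scanpath_fd(s, grid_size = 256)
    expect_gte(fd$fd, 0)
    expect_lte(fd$fd, 2.05)
    expect_true(fd$r2 >= 0 && fd$r2 <= 1)
  }
})

test_that("insufficient usable scales raise the dedicated error", {
  g <- matrix(FALSE, 16, 16)
  g[1, 1] <- TRUE
  g[9, 9] <- TRUE
  # occupied = 2 and N(eps) = 2 at every scale: every scale is top-saturated,
  # only the coarsest survives -> < 3 usable scales
  bc <- box_count(g, scales = c(2L, 4L))
  expect_error(fractal_dimension(bc), class = "scanseq_insufficient_scales")
})
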