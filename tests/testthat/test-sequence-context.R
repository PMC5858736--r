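# sequence_context: codings, lag pairs, autocorrelation

test_that("decision coding maps ratings to groups and ordinal codes", {
  m <- map_decision(c(NA, "2", "3", "4A", "4B", "4C", "5"))
  expect_equal(as.character(m$group), c("N", "B", "B", "M", "M", "M", "M"))
  expect_equal(m$ordinal_code, 0:6)
  expect_equal(as.character(m$category[1]), "none")
  expect_error(map_decision("banana"), class = "scanseq_coding_error")

  m6 <- map_decision(c("4C", "5"), coding = "6")
  expect_equal(as.character(m6$category), c("4C/5", "4C/5"))
  expect_equal(m6$ordinal_code, c(5L, 5L))
})

test_that("density grouping merges heterogeneous and dense", {
  g <- map_density(1:4)
  expect_equal(as.character(g),
               c("fatty", "fibroglandular", "hetero_dense", "hetero_dense"))
  expect_error(map_density(5), class = "scanseq_coding_error")
  expect_error(map_density(0), class = "scanseq_coding_error")
})

test_that("lag-pair datasets have the segment-aware row counts", {
  rd <- tiny_readings(n = 100, segments = 1, seed = 1)
  expect_equal(nrow(build_lag_pairs(rd, 0)), 100)
  expect_equal(nrow(build_lag_pairs(rd, 5)), 95)

  rd2 <- tiny_readings(n = 100, segments = 2, seed = 2)  # 50 + 50
  expect_equal(nrow(build_lag_pairs(rd2, 3)), 94)        # 47 + 47

  # m never increases with i; i = 0 is the identity row set
  d0 <- build_lag_pairs(rd, 0)
  expect_equal(as.character(d0$D0), as.character(rd$decision_cat))
  m_prev <- Inf
  for (i in 0:5) {
    m <- nrow(build_lag_pairs(rd, i))
    expect_lte(m, m_prev)
    m_prev <- m
  }
})

test_that("lag rows never span a session boundary", {
  rd <- tiny_readings(n = 40, segments = 4, seed = 3)  # breaks at 10,20,30
  ds <- build_lag_pairs(rd, 2)
  expect_equal(nrow(ds), 4 * (10 - 2))
  # F1/F2 of each row must come from the same segment: reconstruct by value
  fd_by_order <- rd$fd[order(rd$order_index)]
  seg_by_order <- rd$session_segment[order(rd$order_index)]
  for (r in seq_len(nrow(ds))) {
    n_idx <- match(ds$F0[r], fd_by_order)
    l2_idx <- match(ds$F2[r], fd_by_order)
    expect_equal(n_idx - l2_idx, 2)
    expect_equal(seg_by_order[n_idx], seg_by_order[l2_idx])
  }
})

test_that("lag pairs demand FD and a single reader", {
  rd <- tiny_readings(12)
  rd_nofd <- rd
  rd_nofd$fd <- NULL
  expect_error(build_lag_pairs(rd_nofd, 1), class = "scanseq_data_error")
  rd2 <- rbind(rd, transform(rd, reader_id = "X9"))
  expect_error(build_lag_pairs(rd2, 1), class = "scanseq_argument_error")
  expect_error(build_lag_pairs(rd, 6), class = "scanseq_argument_error")
})

test_that("the ACF matches closed forms and conventions", {
  # alternating +/-1, n = 100: r_1 = -99/100 exactly under 1/n normalization
  x <- rep(c(1, -1), 50)
  a <- autocorrelation(x, max_lag = 3)
  expect_equal(a$r[1], -0.99)
  expect_equal(a$band, 1.96 / 10)
  expect_true(a$significant[1])

  # lag-0 autocorrelation is identically 1 (internal convention check)
  xc <- x - mean(x)
  expect_equal(sum(xc * xc) / sum(xc^2), 1)

  expect_error(autocorrelation(rep(2, 50), 5),
               class = "scanseq_degenerate_series")
  expect_error(autocorrelation(1:5, 10), class = "scanseq_argument_error")
})

test_that("the ACF recovers AR(1) structure at large n", {
  set.seed(77)
  x <- as.numeric(arima.sim(list(ar = 0.5), n = 10000))
  a <- autocorrelation(x, max_lag = 5)
  expect_gte(a$r[1], 0.47)
  expect_lte(a$r[1], 0.53)
  expect_gte(a$r[2], 0.25 - 0.04)  # phi^2
})

test_that("biased decision sequences light up lag 1; unbiased stay in band", {
  sig1 <- function(alpha, s) {
    st <- generate_study(c(N = 1), n_cases = 1000, bias_alpha = alpha,
                         accuracy = c(N = 0.5), gaze = FALSE, seed = s)
    autocorrelation(map_decision(st$readings$decision)$ordinal_code, 5)$significant[1]
  }
  hit75 <- mean(vapply(1:50, function(s) sig1(0.75, s), logical(1)))
  expect_gte(hit75, 0.9)
  hit0 <- mean(vapply(1:50, function(s) sig1(0, 1000 + s), logical(1)))
  expect_gte(hit0, 0.01)
  expect_lte(hit0, 0.12)
})

test_that("decision and FD series from synthetic studies give finite ACFs", {
  st <- generate_study(c(N = 1, E = 1), n_cases = 30, duration = 3, seed = 12)
  ann <- annotate_readings(st, grid_size = 128)
  tab <- study_acf_table(ann, max_lag = 5)
  expect_true(all(is.finite(tab$r)))
  expect_true(all(abs(tab$r) <= 1 + 1e-12))
  expect_equal(nrow(tab), 2 * 2 * 5)
})
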