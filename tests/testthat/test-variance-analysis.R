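# variance_analysis: design encoding and partial-F fixed-effects ANOVA

test_that("design encoding expands factors as specified", {
  rd <- tiny_readings(n = 60, seed = 4)
  ds <- build_lag_pairs(rd, 1)
  # continuous: one standardized column
  d1 <- encode_design(ds, "F0")
  expect_equal(ncol(d1$X), 1)
  expect_equal(mean(d1$X[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(d1$X[, 1]), 1, tolerance = 1e-12)
  # 3-level categorical: 2 treatment columns
  d2 <- encode_design(ds, "P1")
  expect_equal(ncol(d2$X), 2)
  expect_true(all(d2$X %in% c(0, 1)))
  # interaction: product columns
  d3 <- encode_design(ds, "F0:P1")
  expect_equal(ncol(d3$X), 2)
  expect_equal(d3$X[, 1], d1$X[, 1] * d2$X[, 1])

  expect_error(encode_design(ds, "F0:F0"),
               class = "scanseq_specification_error")
  expect_error(encode_design(ds, "F3"),
               class = "scanseq_specification_error")  # beyond lag depth
  expect_error(encode_design(ds, "Q1"),
               class = "scanseq_specification_error")
})

test_that("one-way ANOVA matches the hand sums-of-squares oracle", {
  # 12-row fixture, one 3-level factor
  y <- c(1, 2, 3, 2, 4, 5, 6, 5, 7, 8, 9, 8)
  g <- factor(rep(c("fatty", "fibroglandular", "hetero_dense"), each = 4),
              levels = density_groups())
  ds <- data.frame(D0 = y, P0 = g, F0 = 0)
  attr(ds, "lag") <- 0L
  et <- fixed_effects_anova(ds, "P0", response = "D0")
  want <- oracle_oneway(y, g)
  expect_equal(et$F, want$F, tolerance = 1e-10)   # F = 54 by hand
  expect_equal(et$p, want$p, tolerance = 1e-10)
  expect_equal(et$df_num, 2L)
  expect_equal(et$df_den, 9L)
  expect_equal(want$F, 54, tolerance = 1e-10)
})

test_that("partial F tests are invariant to row permutation", {
  rd <- tiny_readings(n = 80, seed = 9)
  ds <- build_lag_pairs(rd, 1)
  et1 <- suppressWarnings(fixed_effects_anova(ds, c("F0", "P0", "D1")))
  shuf <- ds[sample(nrow(ds)), ]
  attr(shuf, "lag") <- attr(ds, "lag")
  et2 <- suppressWarnings(fixed_effects_anova(shuf, c("F0", "P0", "D1")))
  expect_equal(et1$F, et2$F, tolerance = 1e-9)
  expect_equal(et1$p, et2$p, tolerance = 1e-9)
})

test_that("an exact linear response is handled without crashing", {
  rd <- tiny_readings(n = 60, seed = 10)
  ds <- build_lag_pairs(rd, 1)
  ds$resp <- 3 * ds$F0 - 1
  et <- suppressWarnings(
    fixed_effects_anova(ds, c("F0", "P0"), response = "resp"))
  expect_lt(et$p[et$term == "F0"], 1e-8)
  expect_lt(et$F[et$term == "P0"], 1e-3)
  expect_true(all(is.finite(et$F)))
})

test_that("rank-deficient designs name the aliased terms", {
  rd <- tiny_readings(n = 50, seed = 11)
  ds <- build_lag_pairs(rd, 1)
  ds$F1 <- ds$F0  # perfect aliasing
  err <- expect_error(fixed_effects_anova(ds, c("F0", "F1")),
                      class = "scanseq_rank_deficiency")
  expect_match(conditionMessage(err), "F1")
})

test_that("adding a pure-noise term barely moves existing F statistics", {
  set.seed(12)
  reps <- 20
  relchange <- numeric(0)
  for (r in seq_len(reps)) {
    rd <- tiny_readings(n = 90, seed = 100 + r)
    ds <- build_lag_pairs(rd, 1)
    # non-null response driven by F0
    ds$resp <- as.numeric(scale(ds$F0)) + rnorm(nrow(ds), 0, 1)
    base <- suppressWarnings(
      fixed_effects_anova(ds, c("F0", "P0"), response = "resp"))
    ds$F1 <- rnorm(nrow(ds))  # overwrite with pure noise column
    plus <- suppressWarnings(
      fixed_effects_anova(ds, c("F0", "P0", "F1"), response = "resp"))
    relchange <- c(relchange,
                   abs(plus$F[1:2] - base$F[1:2]) / pmax(base$F[1:2], 1e-9))
  }
  expect_lt(median(relchange), 0.10)
})

test_that("bias injection makes D1 significant; its absence does not", {
  run1 <- function(alpha, s) {
    st <- generate_study(c(N = 1), n_cases = 100, bias_alpha = alpha,
                         accuracy = c(N = 0.5), duration = 4, seed = s)
    ann <- annotate_readings(st, grid_size = 256)
    ds <- build_lag_pairs(split_readers(ann)[[1]], 1)
    et <- suppressWarnings(fixed_effects_anova(ds, c("F0", "P0", "D1")))
    et$p[et$term == "D1"] < 0.05
  }
  hits <- mean(vapply(1:12, function(s) run1(0.75, s), logical(1)))
  expect_gte(hits, 0.8)
  nulls <- mean(vapply(1:12, function(s) run1(0, 400 + s), logical(1)))
  expect_lte(nulls, 0.25)  # 12 replicates; the 50-replicate bound is in acceptance
})

test_that("the preset term menu parses and respects lag depth", {
  terms <- preset_table_terms()
  expect_gt(length(terms), 20)
  t1 <- preset_table_terms(max_lag = 1)
  expect_true(all(vapply(t1, function(tt)
    max(as.integer(substr(strsplit(tt, ":")[[1]], 2, 2))), integer(1)) <= 1))
})
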