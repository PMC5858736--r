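# synthetic_study: case quotas, scanpaths, decisions, full studies

test_that("case sets follow exact largest-remainder quotas", {
  cs <- generate_case_set(100, seed = 1)
  tab <- table(cs$pathology)
  expect_equal(unname(tab[c("malignant", "benign", "normal")]),
               as.table(c(50L, 25L, 25L)), ignore_attr = TRUE)

  cs4 <- generate_case_set(4, seed = 2)
  expect_equal(as.vector(table(cs4$pathology)[c("malignant", "benign", "normal")]),
               c(2L, 1L, 1L))

  # property: quotas exact for random compositions and sizes
  set.seed(7)
  for (rep in 1:25) {
    w <- runif(3)
    w <- w / sum(w)
    comp <- c(normal = w[1], benign = w[2], malignant = w[3])
    n <- sample(1:200, 1)
    cs <- generate_case_set(n, composition = comp, seed = rep)
    got <- as.vector(table(cs$pathology))
    # independent largest-remainder computation
    q <- n * w
    base <- floor(q)
    need <- n - sum(base)
    if (need > 0) {
      add <- order(q - base, decreasing = TRUE)[seq_len(need)]
      base[add] <- base[add] + 1
    }
    expect_equal(got, as.integer(base))
    expect_equal(nrow(cs), n)
  }
})

test_that("truth ratings are consistent with pathology", {
  cs <- generate_case_set(60, seed = 3)
  expect_true(all(cs$truth_rating[cs$pathology == "normal"] == "none"))
  expect_true(all(cs$truth_rating[cs$pathology == "benign"] %in% c("2", "3")))
  expect_true(all(cs$truth_rating[cs$pathology == "malignant"] %in%
                    c("4A", "4B", "4C", "5")))
  expect_true(all(cs$density %in% 1:4))
})

test_that("invalid compositions and sizes are rejected", {
  expect_error(generate_case_set(10, composition = c(malignant = 0.7, benign = 0.7)),
               class = "scanseq_composition_error")
  expect_error(generate_case_set(0), class = "scanseq_argument_error")
  expect_error(generate_case_set(10, density_weights = c(0.5, 0.5, 0.5, 0.5)),
               class = "scanseq_composition_error")
})

test_that("generation is deterministic given the seed", {
  expect_identical(generate_case_set(50, seed = 11), generate_case_set(50, seed = 11))
  s1 <- generate_scanpath(duration = 3, complexity = 0.5, seed = 5)
  s2 <- generate_scanpath(duration = 3, complexity = 0.5, seed = 5)
  expect_identical(s1, s2)
  st1 <- generate_study(c(N = 1, E = 1), n_cases = 8, duration = 2, seed = 9)
  st2 <- generate_study(c(N = 1, E = 1), n_cases = 8, duration = 2, seed = 9)
  expect_identical(st1$readings, st2$readings)
  expect_identical(st1$gaze, st2$gaze)
})

test_that("scanpaths have the forced sample count and stay in bounds", {
  s <- generate_scanpath(duration = 10, rate = 60, complexity = 0.5, seed = 1)
  expect_equal(nrow(s), 600)
  geo <- attr(s, "geometry")
  for (seed in 1:10) {
    cx <- runif(1)
    s <- generate_scanpath(duration = 1, complexity = cx, seed = seed)
    expect_true(all(s$x >= 0 & s$x < geo$width))
    expect_true(all(s$y >= 0 & s$y < geo$height))
    expect_true(all(s$display %in% 1:2))
    expect_true(all(diff(s$t) > 0))
  }
  expect_error(generate_scanpath(duration = 0), class = "scanseq_argument_error")
  expect_error(generate_scanpath(rate = -1), class = "scanseq_argument_error")
})

test_that("complexity knob raises FD on average and couples monotonically", {
  lo <- vapply(1:50, function(s)
    scanpath_fd(generate_scanpath(duration = 4, complexity = 0.1, seed = s),
                grid_size = 256)$fd, numeric(1))
  hi <- vapply(1:50, function(s)
    scanpath_fd(generate_scanpath(duration = 4, complexity = 0.9, seed = s),
                grid_size = 256)$fd, numeric(1))
  expect_lt(mean(lo), mean(hi))

  cx <- seq(0.02, 0.98, length.out = 200)
  fd <- vapply(seq_along(cx), function(i)
    scanpath_fd(generate_scanpath(duration = 4, complexity = cx[i],
                                  seed = 5000 + i), grid_size = 256)$fd,
    numeric(1))
  expect_gte(cor(cx, fd, method = "spearman"), 0.5)
})

test_that("decision model honors degenerate parameters", {
  prof <- data.frame(accuracy = 1, bias_alpha = 0)
  cs <- generate_case_set(20, seed = 4)
  for (i in seq_len(20)) {
    d <- generate_decision(cs[i, ], prof, previous_decision = "5", seed = i)
    grp <- as.character(map_decision(d)$group)
    truth_grp <- c(normal = "N", benign = "B",
                   malignant = "M")[as.character(cs$pathology[i])]
    expect_equal(grp, unname(truth_grp))
  }
})

test_that("repeat probability is monotone in bias_alpha", {
  rep_prob <- function(alpha, seed) {
    st <- generate_study(c(N = 1), n_cases = 150, bias_alpha = alpha,
                         accuracy = c(N = 0.5), gaze = FALSE, seed = seed)
    g <- map_decision(st$readings$decision)$group
    mean(g[-1] == g[-length(g)])
  }
  alphas <- c(0, 0.25, 0.5, 0.75)
  p <- vapply(alphas, function(a)
    mean(vapply(1:30, function(s) rep_prob(a, s), numeric(1))), numeric(1))
  expect_true(all(diff(p) >= 0))
  # alpha = 0.5 repeat rate must clearly exceed the alpha = 0 rate
  expect_gte(p[3] - p[1], 0.2)
})

test_that("studies permute one shared case set and count readings correctly", {
  st <- generate_study(c(N = 1, A = 2, E = 1), n_cases = 25, gaze = FALSE,
                       seed = 6)
  expect_equal(nrow(st$readings), 4 * 25)
  for (rid in unique(st$readings$reader_id)) {
    ids <- st$readings$case_id[st$readings$reader_id == rid]
    expect_setequal(ids, st$cases$case_id)
  }
  # distinct permutations per reader (overwhelmingly likely)
  ords <- split(st$readings$case_id, st$readings$reader_id)
  expect_false(identical(ords[[1]], ords[[2]]))
})

test_that("session breaks segment the sequence and restart the chain", {
  st <- generate_study(c(N = 1), n_cases = 100, gaze = FALSE,
                       session_breaks = list(N1 = 50), seed = 8)
  seg <- st$readings$session_segment[order(st$readings$order_index)]
  expect_equal(seg, rep(0:1, each = 50))
  expect_error(
    generate_study(c(N = 1), n_cases = 10, gaze = FALSE,
                   session_breaks = list(N1 = 10), seed = 1),
    class = "scanseq_argument_error")
})
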