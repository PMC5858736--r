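# Synthetic case sets: stimulus metadata only (no pixels).

#' Default case-mix composition
#'
#' Half the cases malignant, the rest split evenly between normal and benign,
#' matching the standard enriched screening reader-study design.
#' @return Named numeric vector of pathology fractions.
#' @export
default_composition <- function() {
  c(malignant = 0.5, benign = 0.25, normal = 0.25)
}

#' Default parenchymal-density weights
#'
#' Approximate population frequencies of BI-RADS density grades 1-4
#' (fatty / scattered fibroglandular / heterogeneously dense / extremely
#' dense): roughly 10/40/40/10 percent.
#' @return Numeric vector of length 4 summing to 1.
#' @export
default_density_weights <- function() c(0.10, 0.40, 0.40, 0.10)

pathology_levels <- function() c("normal", "benign", "malignant")

# truth ratings compatible with each pathology
truth_rating_sets <- function() {
  list(normal = "none", benign = c("2", "3"),
       malignant = c("4A", "4B", "4C", "5"))
}

#' Generate a synthetic case set
#'
#' Allocates pathologies and densities by exact largest-remainder quotas, then
#' draws each case's ground-truth rating uniformly within its pathology's
#' rating set. Deterministic given `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param composition Named fractions over `normal`, `benign`, `malignant`;
#'   must sum to 1 within 1e-9.
#' @param density_weights Fractions over density grades 1-4; must sum to 1
#'   within 1e-9.
#' @param seed Integer seed.
#' @return data.frame with columns `case_id`, `pathology`, `density`,
#'   `truth_rating`.
#' @export
#' @examples
#' cs <- generate_case_set(100, seed = 1)
#' table(cs$pathology)
generate_case_set <- function(n,
                              composition = default_composition(),
                              density_weights = default_density_weights(),
                              seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop_scanseq("`n` must be a single integer >= 1", "scanseq_argument_error")
  }
  n <- as.integer(n)
  paths <- pathology_levels()
  if (is.null(names(composition)) || !all(names(composition) %in% paths)) {
    stop_scanseq("composition must be named with pathologies (normal/benign/malignant)",
                 "scanseq_composition_error")
  }
  comp <- stats::setNames(numeric(3), paths)
  comp[names(composition)] <- composition
  if (abs(sum(comp) - 1) > 1e-9 || any(comp < 0)) {
    stop_scanseq("composition fractions must be non-negative and sum to 1",
                 "scanseq_composition_error")
  }
  if (length(density_weights) != 4 || abs(sum(density_weights) - 1) > 1e-9 ||
      any(density_weights < 0)) {
    stop_scanseq("density_weights must be 4 non-negative fractions summing to 1",
                 "scanseq_composition_error")
  }

  quota_path <- largest_remainder(n, comp)          # order: normal, benign, malignant
  quota_dens <- largest_remainder(n, density_weights)

  with_seed(substream_seed(seed, "cases"), {
    pathology <- rep(paths, times = quota_path)
    density <- sample(rep(1:4, times = quota_dens))  # shuffle density over cases
    sets <- truth_rating_sets()
    truth <- vapply(pathology, function(p) {
      s <- sets[[p]]
      s[sample.int(length(s), 1L)]
    }, character(1))
    data.frame(
      case_id = sprintf("case%03d", seq_len(n)),
      pathology = factor(pathology, levels = paths),
      density = as.integer(density),
      truth_rating = truth,
      stringsAsFactors = FALSE
    )
  })
}

#' Build reader profiles by experience tier
#'
#' Readers belong to three experience tiers: new trainee (N), advanced
#' trainee (A) and expert (E). `accuracy` is the probability that the base
#' (bias-free) decision draw matches the true pathology; `bias_alpha` is the
#' sequential context-bias strength (the probability that the current decision
#' simply repeats the previous decision's pathology group);
#' `complexity_gain` scales how strongly case difficulty (parenchymal
#' density) drives scanpath complexity.
#'
#' @param n_per_tier Named counts, e.g. `c(N = 3, A = 4, E = 3)`.
#' @param accuracy Named per-tier accuracies in `[0,1]`.
#' @param bias_alpha Context-bias strength in `[0,1]`, recycled per reader.
#' @param complexity_gain Difficulty-to-complexity gain, recycled per reader.
#' @return data.frame with one row per reader.
#' @export
generate_reader_profiles <- function(n_per_tier = c(N = 3, A = 4, E = 3),
                                     accuracy = c(N = 0.55, A = 0.65, E = 0.75),
                                     bias_alpha = 0,
                                     complexity_gain = 0.5) {
  tiers <- c("N", "A", "E")
  if (is.null(names(n_per_tier)) || !all(names(n_per_tier) %in% tiers)) {
    stop_scanseq("n_per_tier must be named with tiers N/A/E",
                 "scanseq_argument_error")
  }
  if (any(bias_alpha < 0 | bias_alpha > 1) || any(accuracy < 0 | accuracy > 1)) {
    stop_scanseq("accuracy and bias_alpha must lie in [0, 1]",
                 "scanseq_argument_error")
  }
  tier <- unlist(mapply(rep, names(n_per_tier), n_per_tier, SIMPLIFY = FALSE),
                 use.names = FALSE)
  ids <- unlist(lapply(tiers, function(tt) {
    k <- sum(tier == tt)
    if (k) sprintf("%s%d", tt, seq_len(k)) else character(0)
  }))
  tier <- sort(factor(tier, levels = tiers))
  n <- length(tier)
  data.frame(
    reader_id = ids,
    tier = tier,
    accuracy = unname(accuracy[as.character(tier)]),
    bias_alpha = rep_len(bias_alpha, n),
    complexity_gain = rep_len(complexity_gain, n),
    stringsAsFactors = FALSE
  )
}
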