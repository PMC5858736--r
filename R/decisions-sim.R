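# Synthetic diagnostic decisions with an injectable sequential context bias.
#
# Decision mechanism: with probability (1 - bias_alpha) the reader draws from
# a base model -- the true pathology with probability `accuracy`, otherwise a
# confusable pathology chosen uniformly among the other two -- then reports a
# rating drawn uniformly within the drawn pathology's rating set. With
# probability bias_alpha the reader instead repeats the *pathology group* of
# the previous decision (rating again uniform within that group). The bias
# acts at the group level, which is what the grouped downstream analyses are
# designed to recover.

draw_rating_in_group <- function(group) {
  s <- group_rating_sets()[[group]]
  s[sample.int(length(s), 1L)]
}

#' Simulate one diagnostic decision
#'
#' @param case One-row case data.frame (needs `pathology`).
#' @param profile One-row reader profile (needs `accuracy`, `bias_alpha`).
#' @param previous_decision Previous reported rating (character) or `NULL`
#'   for the first reading of a session segment.
#' @param seed Integer seed.
#' @return A single rating in `{"none","2","3","4A","4B","4C","5"}`.
#' @export
generate_decision <- function(case, profile, previous_decision = NULL,
                              seed = 1L) {
  acc <- profile$accuracy[1]
  alpha <- profile$bias_alpha[1]
  assert_scalar_number(acc, "accuracy", 0, 1)
  assert_scalar_number(alpha, "bias_alpha", 0, 1)
  truth_group <- c(normal = "N", benign = "B",
                   malignant = "M")[as.character(case$pathology[1])]
  with_seed(seed, {
    biased <- !is.null(previous_decision) && stats::runif(1) < alpha
    if (biased) {
      grp <- as.character(map_decision(previous_decision)$group)
    } else {
      grp <- truth_group
      if (stats::runif(1) >= acc) {
        grp <- sample(setdiff(pathology_groups(), truth_group), 1L)
      }
    }
    draw_rating_in_group(grp)
  })
}

#' Simulate a complete reader study
#'
#' Generates one shared case set, an independent random case permutation per
#' reader, per-reading gaze scanpaths, and sequential decisions whose context
#' bias is controlled by each reader's `bias_alpha`. Session breaks restart
#' the decision chain (the first reading of a segment has no previous
#' decision).
#'
#' Per-reading randomness is drawn from substreams keyed on
#' `(seed, reader_id, case_id)`, so regenerating a single reading never
#' shifts any other.
#'
#' @param n_readers_per_tier Named counts per tier, e.g. `c(N=3, A=4, E=3)`.
#' @param n_cases Number of cases in the shared set.
#' @param session_breaks Named list mapping reader_id to strictly increasing
#'   order indices in `[1, n_cases - 1]` where a new session starts, or a
#'   single unnamed vector applied to every reader, or `NULL`.
#' @param composition,density_weights Passed to [generate_case_set()].
#' @param accuracy,bias_alpha,complexity_gain Passed to
#'   [generate_reader_profiles()].
#' @param duration Mean viewing time per case in seconds (per-reading times
#'   are lognormal around this mean).
#' @param rate Gaze sampling rate in Hz.
#' @param bounds A [display_geometry()].
#' @param gaze If `FALSE`, skip scanpath generation (decisions only; much
#'   faster for decision-sequence simulations).
#' @param seed Master integer seed.
#' @return A `reader_study` list with elements `cases`, `readers`,
#'   `readings` (reader_id, case_id, order_index, session_segment, decision,
#'   duration) and `gaze` (long table reader_id, case_id, t, x, y, display),
#'   plus `rate`, `geometry` and `params`.
#' @export
#' @examples
#' st <- generate_study(c(N = 1, A = 1, E = 1), n_cases = 10,
#'                      duration = 2, seed = 1)
#' nrow(st$readings)  # 30
generate_study <- function(n_readers_per_tier = c(N = 3, A = 4, E = 3),
                           n_cases = 100,
                           session_breaks = NULL,
                           composition = default_composition(),
                           density_weights = default_density_weights(),
                           accuracy = c(N = 0.55, A = 0.65, E = 0.75),
                           bias_alpha = 0,
                           complexity_gain = 0.5,
                           duration = 20, rate = 60,
                           bounds = display_geometry(),
                           gaze = TRUE,
                           seed = 1L) {
  cases <- generate_case_set(n_cases, composition, density_weights, seed = seed)
  readers <- generate_reader_profiles(n_readers_per_tier, accuracy,
                                      bias_alpha, complexity_gain)

  break_for <- function(rid) {
    br <- if (is.list(session_breaks)) session_breaks[[rid]] else session_breaks
    if (is.null(br)) return(integer(0))
    br <- as.integer(sort(br))
    if (any(duplicated(br)) || any(br < 1L) || any(br > n_cases - 1L)) {
      stop_scanseq(sprintf("invalid session break index for reader %s", rid),
                   "scanseq_argument_error")
    }
    br
  }

  readings <- vector("list", nrow(readers))
  gaze_tabs <- if (gaze) vector("list", nrow(readers)) else NULL

  for (r in seq_len(nrow(readers))) {
    prof <- readers[r, ]
    rid <- prof$reader_id
    br <- break_for(rid)
    perm <- with_seed(substream_seed(seed, "order", rid),
                      sample.int(n_cases))
    seg <- findInterval(seq_len(n_cases) - 1L, br)  # 0-based order index
    dur <- with_seed(substream_seed(seed, "dur", rid),
                     stats::rlnorm(n_cases, log(duration) - 0.3^2 / 2, 0.3))

    decision <- character(n_cases)
    prev <- NULL
    for (k in seq_len(n_cases)) {
      if (k > 1L && seg[k] != seg[k - 1L]) prev <- NULL  # session restart
      cs <- cases[perm[k], ]
      decision[k] <- generate_decision(
        cs, prof, previous_decision = prev,
        seed = substream_seed(seed, "dec", rid, cs$case_id))
      prev <- decision[k]
    }

    readings[[r]] <- data.frame(
      reader_id = rid,
      case_id = cases$case_id[perm],
      order_index = seq_len(n_cases) - 1L,
      session_segment = seg,
      decision = decision,
      duration = dur,
      stringsAsFactors = FALSE
    )

    if (gaze) {
      gl <- vector("list", n_cases)
      for (k in seq_len(n_cases)) {
        cs <- cases[perm[k], ]
        sp <- generate_scanpath(cs, prof, duration = dur[k], rate = rate,
                                bounds = bounds,
                                seed = substream_seed(seed, "scan", rid,
                                                      cs$case_id))
        gl[[k]] <- data.frame(reader_id = rid, case_id = cs$case_id,
                              t = sp$t, x = sp$x, y = sp$y,
                              display = sp$display,
                              stringsAsFactors = FALSE)
      }
      gaze_tabs[[r]] <- do.call(rbind, gl)
    }
  }

  structure(list(
    cases = cases,
    readers = readers,
    readings = do.call(rbind, readings),
    gaze = if (gaze) do.call(rbind, gaze_tabs) else NULL,
    rate = rate,
    geometry = bounds,
    params = list(n_readers_per_tier = n_readers_per_tier, n_cases = n_cases,
                  session_breaks = session_breaks, bias_alpha = bias_alpha,
                  accuracy = accuracy, complexity_gain = complexity_gain,
                  duration = duration, rate = rate, seed = seed)
  ), class = "reader_study")
}

#' @export
print.reader_study <- function(x, ...) {
  cat(sprintf("<reader_study> %d readers x %d cases = %d readings%s\n",
              nrow(x$readers), nrow(x$cases), nrow(x$readings),
              if (is.null(x$gaze)) " (no gaze)" else
                sprintf(", %d gaze samples", nrow(x$gaze))))
  invisible(x)
}
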