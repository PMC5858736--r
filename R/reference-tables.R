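# Published per-reader reference values shipped as plain text, used for
# in-table arithmetic checks (tier averages, improvement over chance).

#' Published per-reader f-score reference table
#'
#' The per-reader weighted f-scores of the lagged decision-prediction task
#' as published for the 10-reader, 100-case reference study, with the
#' random-chance baseline column. Used only for arithmetic cross-checks
#' (tier averages, improvement over chance); the underlying human data are
#' not available.
#'
#' @return data.frame with columns `reader`, `tier`, `Cn`, `Cn-1` .. `Cn-5`,
#'   `random_chance`.
#' @export
reference_fscores <- function() {
  path <- system.file("extdata", "table2_fscores.tsv", package = "scanseq",
                      mustWork = TRUE)
  raw <- read_tsv_with_meta(path)
  df <- raw$data
  for (cc in setdiff(names(df), c("reader", "tier"))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df
}

#' Tier-average rows of the reference f-score table
#'
#' Arithmetic means over each tier's readers, rounded to 2 decimals the way
#' the published averages are displayed.
#'
#' @param digits Rounding for display (default 2).
#' @return data.frame of per-tier averages.
#' @export
reference_tier_averages <- function(digits = 2) {
  df <- reference_fscores()
  num <- setdiff(names(df), c("reader", "tier"))
  rows <- lapply(c("N", "A", "E"), function(tt) {
    sub <- df[df$tier == tt, num]
    out <- data.frame(tier = tt, stringsAsFactors = FALSE)
    for (cc in num) out[[cc]] <- round(mean(sub[[cc]]), digits)
    out
  })
  do.call(rbind, rows)
}

#' Percent improvement over a chance baseline
#'
#' `100 * (f - chance) / chance`, the headline summary statistic of the
#' prediction analysis.
#'
#' @param f Achieved (mean) f-score.
#' @param chance Chance baseline f-score.
#' @return Percent improvement.
#' @export
#' @examples
#' improvement_over_chance(0.54, 0.33)  # ~64
improvement_over_chance <- function(f, chance) {
  assert_scalar_number(chance, "chance", 1e-12)
  100 * (f - chance) / chance
}
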