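# Decision and density codings shared by the whole pipeline.
#
# Reported ratings follow the BI-RADS assessment lexicon restricted to the
# categories used in screening review: an unmarked case ("none") plus ratings
# 2, 3, 4A, 4B, 4C and 5. Ratings collapse onto three pathology groups:
#   none          -> N (normal)
#   {2, 3}        -> B (benign)
#   {4A,4B,4C,5}  -> M (malignant)
# The ordinal code is the rank of the rating in severity order (0-6).

#' Decision rating categories
#'
#' The seven decision categories in severity order, or the six-level coding in
#' which ratings 4C and 5 are merged.
#'
#' @param coding `"7"` (default) or `"6"` for the merged `{4C,5}` coding.
#' @return Character vector of category labels.
#' @export
decision_levels <- function(coding = c("7", "6")) {
  coding <- match.arg(as.character(coding), c("7", "6"))
  if (coding == "7") c("none", "2", "3", "4A", "4B", "4C", "5")
  else c("none", "2", "3", "4A", "4B", "4C/5")
}

#' Pathology group labels
#' @return `c("N", "B", "M")` (normal, benign, malignant).
#' @export
pathology_groups <- function() c("N", "B", "M")

# rating sets per pathology group, used by the simulator and the codings
group_rating_sets <- function() {
  list(N = "none", B = c("2", "3"), M = c("4A", "4B", "4C", "5"))
}

#' Map a reported rating to its decision coding
#'
#' Maps a rating (or an absent rating, meaning the case was left unmarked) to
#' its category, three-level pathology group and ordinal severity code.
#' Vectorized; `NA` is treated as absent.
#'
#' @param rating Character vector with entries in
#'   `{NA, "none", "2", "3", "4A", "4B", "4C", "5"}`.
#' @param coding `"7"` (default) or `"6"` to merge `{4C, 5}`.
#' @return A data.frame with columns `category` (factor), `group` (factor
#'   N/B/M) and `ordinal_code` (integer, 0-based rank in severity order).
#' @export
#' @examples
#' map_decision(c(NA, "3", "4C"))
map_decision <- function(rating, coding = c("7", "6")) {
  coding <- match.arg(as.character(coding), c("7", "6"))
  rating <- as.character(rating)
  rating[is.na(rating)] <- "none"
  known <- c("none", "2", "3", "4A", "4B", "4C", "5")
  bad <- setdiff(unique(rating), known)
  if (length(bad)) {
    stop_scanseq(sprintf("unknown rating token(s): %s",
                         paste(bad, collapse = ", ")),
                 "scanseq_coding_error")
  }
  if (coding == "6") rating[rating %in% c("4C", "5")] <- "4C/5"
  levs <- decision_levels(coding)
  category <- factor(rating, levels = levs)
  grp <- ifelse(rating == "none", "N",
                ifelse(rating %in% c("2", "3"), "B", "M"))
  data.frame(
    category = category,
    group = factor(grp, levels = pathology_groups()),
    ordinal_code = as.integer(category) - 1L
  )
}

#' Map BI-RADS parenchymal density to its analysis grouping
#'
#' Density grades 1-4 collapse to three groups: 1 = fatty, 2 = fibroglandular,
#' and 3-4 = heterogeneous/dense (merged because dense cases are few).
#'
#' @param density Integer vector with values in 1..4.
#' @return Factor with levels `fatty`, `fibroglandular`, `hetero_dense`.
#' @export
#' @examples
#' map_density(1:4)
map_density <- function(density) {
  density <- as.integer(density)
  if (any(is.na(density)) || any(!density %in% 1:4)) {
    stop_scanseq("density must be an integer in 1..4", "scanseq_coding_error")
  }
  labs <- c("fatty", "fibroglandular", "hetero_dense", "hetero_dense")
  factor(labs[density], levels = c("fatty", "fibroglandular", "hetero_dense"))
}

#' Density group labels
#' @return `c("fatty", "fibroglandular", "hetero_dense")`.
#' @export
density_groups <- function() c("fatty", "fibroglandular", "hetero_dense")
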