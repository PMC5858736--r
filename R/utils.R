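# Internal helpers: seeding, argument checks, small numerics.

#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an arbitrary set of string/number keys
#' into a 31-bit integer seed. Used so that every reading, reader and stage of
#' a synthetic study draws from its own stable stream: regenerating one piece
#' never shifts any other.
#'
#' @param seed Integer master seed.
#' @param ... Keys (coerced to character) identifying the substream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(42, "scan", "R01", "case-007")
substream_seed <- function(seed, ...) {
  keys <- paste(c(as.character(seed), as.character(unlist(list(...)))),
                collapse = "\r")
  h <- 17
  for (ch in utf8ToInt(keys)) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L), kind = "Mersenne-Twister")
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_scanseq <- function(msg, class) {
  stop(structure(class = c(class, "scanseq_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop_scanseq(sprintf("`%s` must be a single finite number in [%s, %s]",
                         name, format(lo), format(hi)),
                 "scanseq_argument_error")
  }
  invisible(x)
}

is_power_of_two <- function(x) {
  x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

# Largest-remainder (Hamilton) apportionment of n items to fractions.
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    rem <- quota - base
    # ties broken by listed order (stable)
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
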