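# Internal helpers: condition classes, seed streams, partition agreement.

abort_invalid <- function(msg) {
  stop(structure(
    class = c("fapnet_invalid_argument", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_degenerate <- function(msg) {
  stop(structure(
    class = c("fapnet_degenerate_input", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Derive an independent integer seed for a sub-stream; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#' Used to compare detected co-expression modules with a reference
#' (e.g. planted) module assignment. 1 means identical partitions, 0 is the
#' expected agreement of independent random partitions.
#'
#' @param a,b vectors of cluster labels (same length, any label type).
#' @return a single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort_invalid("partitions must have equal length")
  tb <- table(a, b)
  n <- sum(tb)
  if (n < 2) abort_invalid("need at least two objects")
  sum_ij <- sum(choose(tb, 2))
  sum_i <- sum(choose(rowSums(tb), 2))
  sum_j <- sum(choose(colSums(tb), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
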