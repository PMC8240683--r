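#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map imap
NULL

# Harmonic mean of two non-negative rates; 0 when both are 0.
harmonic_mean <- function(p, r) {
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Average precision of a score vector against binary labels
#'
#' Area under the precision-recall curve computed as the step-wise sum
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over thresholds taken at every distinct
#' predicted score, in descending order. This is the standard summary used
#' for model selection throughout the package.
#'
#' @param scores numeric vector of predicted scores (higher = more positive).
#' @param labels binary vector (0/1 or logical), same length as `scores`.
#' @return a single number in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels)
  if (n_pos == 0) abort("average_precision: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  pred <- seq_along(lab)
  # collapse ties: evaluate only at the last index of each distinct score
  last_of_score <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  prec <- tp[last_of_score] / pred[last_of_score]
  rec <- tp[last_of_score] / n_pos
  sum(diff(c(0, rec)) * prec)
}

# Precision-recall curve points at every distinct score threshold
# (descending). Returns a tibble with threshold, precision, recall.
pr_curve_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  pred <- seq_along(lab)
  last_of_score <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tibble(
    threshold = sc[last_of_score],
    precision = tp[last_of_score] / pred[last_of_score],
    recall = if (n_pos > 0) tp[last_of_score] / n_pos else rep(0, length(last_of_score))
  )
}

# Deterministic 31-bit hash of a node set (order-independent): polynomial
# rolling hash of the sorted, NUL-joined ids. Used to derive per-seed RNG
# substreams so parallel scheduling never changes results.
node_set_hash <- function(nodes) {
  s <- paste(sort(nodes), collapse = "\x01")
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Combine a global seed with a node-set hash into a substream seed < 2^31.
substream_seed <- function(global_seed, nodes) {
  m <- 2147483647
  as.integer((as.numeric(global_seed) * 2654435761 + node_set_hash(nodes)) %% m)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
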