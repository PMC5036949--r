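# Chinese restaurant process: the partition prior underlying the clustering
# model. A partition of n items into K blocks is represented canonically as an
# integer assignment vector z with labels 1..K in order of first appearance.

#' Canonicalize an assignment vector
#'
#' Relabels cluster assignments so labels are 1..K in order of first
#' appearance. Partition probabilities and NMI are label-invariant, so this is
#' purely a convention.
#'
#' @param z Integer vector of cluster assignments.
#' @return Integer vector with canonical labels.
#' @export
canonicalize_partition <- function(z) {
  match(z, unique(z))
}

#' CRP seating probabilities for the next customer
#'
#' Given a partial partition with cluster sizes `sizes` over `i = sum(sizes)`
#' customers, the next customer joins existing cluster k with probability
#' `N_k / (n0 + i)` and opens a new cluster with probability `n0 / (n0 + i)`.
#'
#' @param sizes Integer vector of current cluster sizes (may be empty).
#' @param n0 Positive concentration (prior count).
#' @return Probability vector of length `length(sizes) + 1`; the last entry is
#'   the new-cluster probability. Entries sum to 1.
#' @examples
#' seating_probabilities(integer(0), 1)   # first customer: new table w.p. 1
#' seating_probabilities(c(2, 1), 3)      # (2/6, 1/6, 3/6)
#' @export
seating_probabilities <- function(sizes, n0) {
  stopifnot(n0 > 0, all(sizes >= 1) || length(sizes) == 0L)
  i <- sum(sizes)
  c(sizes, n0) / (n0 + i)
}

#' Log probability of a partition under the CRP
#'
#' `ln p(z) = K ln n0 - ln n0^(N) + sum_k ln Gamma(N_k)` where `n0^(N)` is the
#' rising factorial `n0 (n0+1) ... (n0+N-1)`, computed stably as
#' `lgamma(n0+N) - lgamma(n0)`. Equals the sum of sequential log seating
#' probabilities for any assignment order consistent with the labels.
#'
#' @param z Integer assignment vector (any labels; canonicalized internally).
#' @param n0 Positive concentration.
#' @return Scalar log probability.
#' @export
partition_log_prob <- function(z, n0) {
  stopifnot(n0 > 0)
  if (length(z) == 0L) stop("empty partition has undefined probability")
  z <- canonicalize_partition(z)
  sizes <- tabulate(z)
  K <- length(sizes)
  N <- length(z)
  K * log(n0) - (lgamma(n0 + N) - lgamma(n0)) + sum(lgamma(sizes))
}

#' Sample a partition from the CRP
#'
#' Sequential draw via the seating rule; customer i+1 joins table k with
#' probability proportional to its size, or a new table with probability
#' proportional to `n0`.
#'
#' @param n Number of items (>= 1).
#' @param n0 Positive concentration.
#' @return Integer assignment vector of length `n` in canonical labeling.
#' @export
sample_partition <- function(n, n0) {
  stopifnot(n >= 1, n0 > 0)
  z <- integer(n)
  sizes <- numeric(0)
  for (i in seq_len(n)) {
    p <- seating_probabilities(sizes, n0)
    k <- sample.int(length(p), 1L, prob = p)
    if (k > length(sizes)) sizes <- c(sizes, 1) else sizes[k] <- sizes[k] + 1
    z[i] <- k
  }
  z
}

#' Expected number of occupied clusters under the CRP
#'
#' The exact expectation `sum_{i=0}^{n-1} n0 / (n0 + i)`; for large `n` this
#' behaves like `n0 log n`, a relation useful for choosing `n0` when the
#' expected number of clusters is known a priori.
#'
#' @param n Number of items (>= 1).
#' @param n0 Positive concentration.
#' @return Scalar expected cluster count (1 <= value <= n).
#' @export
expected_clusters <- function(n, n0) {
  stopifnot(n >= 1, n0 > 0)
  sum(n0 / (n0 + seq_len(n) - 1))
}
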