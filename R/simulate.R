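#' Simulate a contact matrix with planted domains
#'
#' Generates a synthetic single-chromosome contact matrix exhibiting the two
#' dominant features of real chromatin contact data: a power-law decay of
#' expected counts with genomic distance, and contiguous blocks (planted
#' TADs) whose internal contacts are enriched. The expected count is
#' \deqn{\mu_{ij} = A\,(|i-j|+1)^{-\alpha}\,(1 + \beta\,[i,j
#'   \text{ in the same block}])}
#' and observed counts are drawn independently as `Poisson(mu_ij)` on the
#' upper triangle, then mirrored. The `+1` offset keeps the diagonal finite.
#'
#' @param n_bins number of bins.
#' @param block_lengths positive integers summing to `n_bins`; each entry is
#'   the span of one planted domain.
#' @param alpha distance-decay exponent (`> 0`, default 1).
#' @param beta within-block enrichment (`>= 0`, default 6); `beta = 0`
#'   plants no structure.
#' @param intensity base expected count `A` at distance 0 (default 50).
#' @param seed integer seed.
#' @param chrom,bin_size,start_offset metadata for the returned matrix.
#' @return list with `matrix` (a [contact_matrix()]) and `labels` (the
#'   planted 0-based per-bin block labels).
#' @export
#' @examples
#' sim <- simulate_contacts(120, rep(30, 4), seed = 1)
#' table(sim$labels)
simulate_contacts <- function(n_bins, block_lengths, alpha = 1, beta = 6,
                              intensity = 50, seed = 1L, chrom = "chrS",
                              bin_size = 25000L, start_offset = 0L) {
  block_lengths <- as.integer(block_lengths)
  if (any(block_lengths < 1L) || sum(block_lengths) != n_bins) {
    stop("block_lengths must be positive and sum to n_bins")
  }
  if (alpha <= 0) stop("alpha must be positive")
  if (beta < 0) stop("beta must be non-negative")
  if (intensity <= 0) stop("intensity must be positive")
  labels <- rep(seq_along(block_lengths) - 1L, block_lengths)
  dmat <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  same <- outer(labels, labels, "==")
  mu <- intensity * (dmat + 1)^(-alpha) * (1 + beta * same)
  ut <- upper.tri(mu, diag = TRUE)
  x <- matrix(0, n_bins, n_bins)
  x[ut] <- with_seed(seed, stats::rpois(sum(ut), mu[ut]))
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  list(matrix = contact_matrix(x, chrom, bin_size, start_offset),
       labels = labels)
}
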