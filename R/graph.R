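#' Default factorization rank from expected TAD size
#'
#' The rank `k` doubles as the number of clusters, so it is natural to pick
#' it from the chromosome length and the expected size of a domain:
#' `k = max(2, round(n_bins * bin_size / expected_tad_size))`. The default
#' expected size of 1 Mb yields TAD-scale clusters; 500 kb and 2 Mb give
#' subTAD- and metaTAD-scale partitions.
#'
#' @param n_bins number of bins in the matrix.
#' @param bin_size bin width in bp.
#' @param expected_tad_size expected cluster span in bp (default 1 Mb).
#' @return integer rank `k >= 2`.
#' @export
#' @examples
#' choose_k(4000, 25000)            # 100 clusters on a 100 Mb chromosome
choose_k <- function(n_bins, bin_size, expected_tad_size = 1e6) {
  if (expected_tad_size < bin_size) {
    stop("expected_tad_size must be at least one bin (", bin_size, " bp)")
  }
  max(2L, as.integer(round(n_bins * bin_size / expected_tad_size)))
}

#' Linear-chain neighbor graph for graph regularization
#'
#' Bins `i` and `j` are adjacent when `0 < |i - j| <= r_bins`, encoding the
#' prior that factor values should vary smoothly along the chromosome. The
#' Laplacian `L = D - W` (degree matrix `D`, `D_ii = sum_j W_ij`) is the
#' regularizer's quadratic form.
#'
#' @param n_bins number of bins.
#' @param bin_size bin width in bp.
#' @param r_bp neighborhood radius in bp (default 250 kb); converted to bins
#'   as `floor(r_bp / bin_size)`, which must be at least 1.
#' @return list with `W`, `D`, `L` (n x n matrices), `r_bins` and `n_bins`.
#' @export
neighbor_graph <- function(n_bins, bin_size = 1L, r_bp = 250000) {
  if (r_bp < bin_size) {
    stop("radius ", r_bp, " bp is smaller than one bin; the graph would be empty")
  }
  r_bins <- floor(r_bp / bin_size)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  W <- (d > 0 & d <= r_bins) * 1
  D <- diag(rowSums(W))
  structure(list(W = W, D = D, L = D - W,
                 r_bins = as.integer(r_bins), n_bins = as.integer(n_bins)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("Chain neighbor graph: %d bins, radius %d bins, interior degree %d\n",
              x$n_bins, x$r_bins, 2L * x$r_bins))
  invisible(x)
}
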