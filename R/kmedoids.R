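#' Chain-constrained k-medoids segmentation
#'
#' Clusters the rows of a feature matrix (typically the `U` factor of a
#' GRiNCH fit) into exactly contiguous runs of bins, so each cluster is a
#' candidate TAD. Medoids are initialized at evenly spaced bins
#' `floor((2t + 1) * n / (2k))`, `t = 0..k-1`. Each assignment step scans,
#' for every pair of consecutive medoids, all split positions between them
#' and keeps the one minimizing the summed Euclidean distance of rows to
#' their side's medoid (bins before the first medoid join the first cluster,
#' bins after the last join the last). Each update step moves a cluster's
#' medoid to the member minimizing total within-cluster distance. Ties are
#' broken toward the smaller bin index; iteration stops when the labels are
#' unchanged or after `max_iter` rounds.
#'
#' @param u numeric matrix (n x k features); rows are bins in chromosomal
#'   order.
#' @param k number of clusters; `2 <= k <= n`.
#' @param max_iter iteration cap (default 50).
#' @return integer vector of 0-based cluster labels, length n; labels are
#'   `0..m-1` in genomic order and every label occupies one consecutive run.
#'   If clusters collapse during fitting, `m` may be less than `k` (with a
#'   warning).
#' @export
#' @examples
#' u <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
#' chain_kmedoids(u, 2)          # splits exactly at the 10/10 boundary
chain_kmedoids <- function(u, k, max_iter = 50L) {
  u <- as.matrix(u)
  n <- nrow(u)
  if (k > n) stop("k_clusters (", k, ") exceeds the number of bins (", n, ")")
  if (any(!is.finite(u))) stop("feature matrix contains non-finite values")
  if (k == n) return(seq_len(n) - 1L)
  medoids <- unique(as.integer(floor((2 * seq_len(k) - 1) * n / (2 * k))) + 1L)
  if (length(medoids) < k) {
    warning("duplicate initial medoids collapsed; returning ",
            length(medoids), " clusters")
    k <- length(medoids)
  }

  labels_old <- rep(-1L, n)
  labels <- integer(n)
  cost_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # distances of every row to every medoid
    dmat <- vapply(medoids, function(m) {
      sqrt(rowSums((u - rep(u[m, ], each = n))^2))
    }, numeric(n))
    labels[seq_len(medoids[1L])] <- 0L
    if (medoids[k] < n) labels[(medoids[k] + 1L):n] <- k - 1L
    for (t in seq_len(k - 1L)) {
      lo <- medoids[t]; hi <- medoids[t + 1L]
      # split s in [lo, hi-1]: bins lo..s -> t-1, s+1..hi -> t
      seg <- lo:hi
      left_cost <- cumsum(dmat[seg, t])
      right_cost <- rev(cumsum(rev(dmat[seg, t + 1L])))
      tot <- left_cost[-length(seg)] + right_cost[-1L]
      s <- lo + which.min(tot) - 1L
      labels[lo:s] <- t - 1L
      labels[(s + 1L):hi] <- t
    }
    cost_trace <- c(cost_trace, sum(dmat[cbind(seq_len(n), labels + 1L)]))
    if (identical(labels, labels_old)) break
    labels_old <- labels
    # medoid update: member minimizing total within-cluster distance
    new_medoids <- integer(k)
    for (t in seq_len(k)) {
      idx <- which(labels == t - 1L)
      if (length(idx) == 1L) {
        new_medoids[t] <- idx
      } else {
        dd <- as.matrix(stats::dist(u[idx, , drop = FALSE]))
        new_medoids[t] <- idx[which.min(colSums(dd))]
      }
    }
    if (identical(new_medoids, medoids)) break
    medoids <- new_medoids
    if (anyDuplicated(medoids)) {
      medoids <- unique(medoids)
      k <- length(medoids)
      warning("medoids collapsed during fitting; continuing with ", k,
              " clusters")
    }
  }
  structure(relabel_canonical(labels), cost_trace = cost_trace)
}

# relabel so ids run 0..m-1 in order of first (genomic) appearance;
# background NA labels are preserved
relabel_canonical <- function(labels) {
  ok <- !is.na(labels)
  ids <- unique(labels[ok])
  out <- labels
  out[ok] <- match(labels[ok], ids) - 1L
  as.integer(out)
}

#' Convert contiguous cluster labels to TAD intervals
#'
#' @param labels integer per-bin labels in which every cluster occupies one
#'   consecutive run; `NA` marks background (non-TAD) bins and produces no
#'   interval.
#' @return data frame with one row per cluster: `start_bin`, `end_bin`
#'   (inclusive, 0-based) and `cluster_id`, ordered by position.
#' @export
clusters_to_tads <- function(labels) {
  check_contiguous(labels)
  r <- rle(ifelse(is.na(labels), -1L, as.integer(labels)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= 0L
  data.frame(start_bin = starts[keep] - 1L, end_bin = ends[keep] - 1L,
             cluster_id = r$values[keep])
}

check_contiguous <- function(labels) {
  v <- labels[!is.na(labels)]
  if (length(v) && anyDuplicated(rle(v)$values)) {
    stop("labels are not contiguous: some cluster occupies multiple runs")
  }
  invisible(TRUE)
}

#' TAD boundary bins
#'
#' A TAD's boundary set is its first and last bin plus one flanking bin on
#' each side, clipped to the chromosome; the union over TADs is returned
#' deduplicated.
#'
#' @param tads TAD table from [clusters_to_tads()] or [tads()].
#' @param n_bins chromosome length in bins.
#' @return sorted integer vector of 0-based bin indices.
#' @export
#' @examples
#' tad_boundaries(data.frame(start_bin = 3, end_bin = 6, cluster_id = 0), 10)
tad_boundaries <- function(tads, n_bins) {
  b <- c(tads$start_bin - 1L, tads$start_bin, tads$end_bin, tads$end_bin + 1L)
  sort(unique(b[b >= 0L & b < n_bins]))
}
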