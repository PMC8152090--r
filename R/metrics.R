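# Map background (NA) bins to a single reserved cluster so that callers
# that skip genome stretches still yield a full partition for comparison.
labels_with_background <- function(labels) {
  out <- as.integer(labels)
  if (anyNA(out)) out[is.na(out)] <- max(out, -1L, na.rm = TRUE) + 1L
  out
}

#' Rand index between two clusterings
#'
#' Fraction of bin pairs on which two partitions agree: pairs co-clustered
#' in both plus pairs separated in both, over all `choose(n, 2)` pairs. 1 is
#' perfect concordance; identical all-in-one versus all-singletons gives 0.
#' `NA` labels (background bins) are treated as one shared cluster.
#'
#' @param a,b integer label vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
#' @examples
#' rand_index(c(0, 0, 1, 1), c(0, 1, 1, 1))   # 0.5
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  a <- labels_with_background(a); b <- labels_with_background(b)
  n <- length(a)
  ct <- table(a, b)
  s_ij <- sum(choose(ct, 2))
  s_i <- sum(choose(rowSums(ct), 2))
  s_j <- sum(choose(colSums(ct), 2))
  tot <- choose(n, 2)
  (tot + 2 * s_ij - s_i - s_j) / tot
}

#' Mutual information between two clusterings
#'
#' Plug-in estimate `sum p(a,b) log(p(a,b) / (p(a) p(b)))` over the
#' empirical joint label distribution, with natural logarithm and
#' `0 log 0 = 0`. Zero iff the labelings are empirically independent (for
#' example when one side is a single cluster). `NA` labels are treated as
#' one shared background cluster.
#'
#' @inheritParams rand_index
#' @return mutual information in nats, `>= 0`.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  a <- labels_with_background(a); b <- labels_with_background(b)
  p <- table(a, b) / length(a)
  pa <- rowSums(p); pb <- colSums(p)
  terms <- p * log(p / outer(pa, pb))
  sum(terms[p > 0])
}

#' Refine labels to a finer bin size
#'
#' Splits each bin into `factor` constituent bins carrying the same label,
#' so clusterings computed at different resolutions can be compared on a
#' common grid (e.g. 10/25/50 kb partitions refined to 5 kb).
#'
#' @param labels per-bin labels.
#' @param factor integer ratio between the coarse and fine bin size.
#' @return label vector of length `length(labels) * factor`.
#' @export
refine_labels <- function(labels, factor) {
  if (factor < 1 || factor != round(factor)) {
    stop("resolutions must be related by a positive integer factor")
  }
  rep(labels, each = as.integer(factor))
}

#' Per-cluster Davies-Bouldin index
#'
#' Treats each bin's full row of contact counts as a data point. With
#' `d_i` the mean Euclidean distance of cluster members to their centroid
#' and `distance_ij` the distance between centroids, the pairwise similarity
#' is `S_ij = (d_i + d_j) / distance_ij` and `DBI_i = max_{j != i} S_ij`.
#' Smaller values mean better-separated clusters. Coincident centroids give
#' an infinite similarity with a warning.
#'
#' @param x contact matrix (matrix or [contact_matrix()]).
#' @param labels per-bin integer labels (`NA` bins are ignored); at least
#'   two clusters.
#' @return named numeric vector, one DBI per cluster id.
#' @export
dbi_per_cluster <- function(x, labels) {
  x <- as_counts(x)
  ids <- sort(unique(labels[!is.na(labels)]))
  if (length(ids) < 2L) stop("DBI needs at least two clusters")
  cent <- t(vapply(ids, function(id) {
    colMeans(x[labels %in% id, , drop = FALSE])
  }, numeric(ncol(x))))
  d <- vapply(seq_along(ids), function(t) {
    rows <- x[labels %in% ids[t], , drop = FALSE]
    mean(sqrt(rowSums((rows - rep(cent[t, ], each = nrow(rows)))^2)))
  }, 0)
  cdist <- as.matrix(stats::dist(cent))
  if (any(cdist[upper.tri(cdist)] == 0)) {
    warning("coincident cluster centroids; similarity set to Inf")
  }
  S <- outer(d, d, "+") / cdist
  diag(S) <- -Inf
  stats::setNames(apply(S, 1L, max), ids)
}

#' Per-cluster delta contact count
#'
#' `DCC_i = in_i - out_i`, where `in_i` is the mean count over unordered
#' pairs of distinct bins both in cluster `i` (diagonal excluded) and
#' `out_i` the mean count over pairs with exactly one end in the cluster.
#' Higher values mean denser, better-insulated clusters. Singleton clusters
#' have no within-pairs and are reported as `NA` with a warning.
#'
#' @inheritParams dbi_per_cluster
#' @return named numeric vector, one DCC per cluster id.
#' @export
dcc_per_cluster <- function(x, labels) {
  x <- as_counts(x)
  n <- nrow(x)
  ids <- sort(unique(labels[!is.na(labels)]))
  out <- vapply(ids, function(id) {
    idx <- which(labels %in% id)
    m <- length(idx)
    if (m < 2L || m >= n) return(NA_real_)
    rest <- setdiff(seq_len(n), idx)
    inside <- (sum(x[idx, idx]) - sum(diag(x)[idx])) / (m * (m - 1))
    outside <- sum(x[idx, rest]) / (m * length(rest))
    inside - outside
  }, 0)
  if (anyNA(out)) {
    warning("clusters without both within- and cross-pairs reported as NA")
  }
  stats::setNames(out, ids)
}

#' Mean per-bin signal within each TAD
#'
#' @param signal numeric per-bin track (e.g. binned ChIP-seq coverage).
#' @param labels per-bin labels; `NA` bins contribute to no TAD.
#' @return named numeric vector of per-cluster means.
#' @export
mean_signal_per_tad <- function(signal, labels) {
  if (length(signal) != length(labels)) {
    stop("signal track length does not match the number of bins")
  }
  ok <- !is.na(labels)
  means <- tapply(signal[ok], labels[ok], mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Shuffle TAD and gap stretches along the chromosome
#'
#' Builds null TAD sets that preserve the observed length distribution: the
#' chromosome is cut into its TAD stretches and interspersed non-TAD (`NA`)
#' stretches, and the stretches are rearranged in a seeded uniform random
#' order. Every shuffle therefore conserves the multiset of TAD lengths and
#' of gap lengths, and remains a contiguous labeling.
#'
#' @param labels per-bin labels; `NA` marks non-TAD bins.
#' @param n_shuffles number of shuffled assignments (default 10).
#' @param seed integer seed.
#' @return list of `n_shuffles` label vectors, relabeled `0..m-1` in their
#'   new genomic order (gaps stay `NA`).
#' @export
shuffle_tads <- function(labels, n_shuffles = 10L, seed = 1L) {
  r <- rle(ifelse(is.na(labels), -1L, as.integer(labels)))
  n_runs <- length(r$lengths)
  with_seed(seed, lapply(seq_len(n_shuffles), function(s) {
    ord <- sample.int(n_runs)
    vals <- r$values[ord]
    lens <- r$lengths[ord]
    out <- rep(ifelse(vals < 0L, NA_integer_, vals), lens)
    relabel_canonical(out)
  }))
}

#' Empirical significance against a shuffled-TAD null
#'
#' Each observed per-TAD statistic is compared with a pooled null
#' distribution (e.g. the same statistic over shuffled TADs): its p-value is
#' the fraction of null values strictly better than the observation, where
#' "better" is higher for enrichment-type statistics (DCC, mean signal) and
#' lower for DBI. Ties count as not better.
#'
#' @param observed numeric vector of per-TAD statistics.
#' @param null numeric vector of null statistics.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @param alpha significance level (default 0.05).
#' @return list with `p_values` (per TAD) and `significant_fraction`
#'   (`mean(p < alpha)` over non-`NA` observations).
#' @export
empirical_significance <- function(observed, null,
                                   direction = c("higher_is_better",
                                                 "lower_is_better"),
                                   alpha = 0.05) {
  direction <- match.arg(direction)
  null <- null[is.finite(null)]
  if (!length(null)) stop("null distribution is empty")
  p <- vapply(observed, function(o) {
    if (is.na(o)) return(NA_real_)
    if (direction == "higher_is_better") mean(null > o) else mean(null < o)
  }, 0)
  list(p_values = p, significant_fraction = mean(p < alpha, na.rm = TRUE))
}

#' Boundary fold enrichment of binding events
#'
#' `(n_TAD-BIND / n_TAD) / (n_BIND / N)`: the rate of annotated bins among
#' TAD boundary bins over the chromosome-wide rate. 1 means no enrichment.
#'
#' @param boundaries 0-based boundary bin indices (see [tad_boundaries()]).
#' @param annotation 0/1 per-bin indicator (see [read_bed_annotation()]).
#' @return fold enrichment (scalar).
#' @export
fold_enrichment <- function(boundaries, annotation) {
  N <- length(annotation)
  n_bind <- sum(annotation)
  n_tad <- length(boundaries)
  if (n_bind == 0L) stop("no annotated bins; fold enrichment undefined")
  if (n_tad == 0L) stop("no boundary bins; fold enrichment undefined")
  n_tb <- sum(annotation[boundaries + 1L])
  (n_tb / n_tad) / (n_bind / N)
}

#' Hypergeometric boundary enrichment test
#'
#' Upper-tail hypergeometric probability `P[X >= n_TAD-BIND]` of seeing at
#' least the observed number of annotated boundary bins when `n_TAD` bins
#' are drawn without replacement from `N` bins of which `n_BIND` are
#' annotated. Pass lists of vectors to aggregate counts across chromosomes
#' before testing.
#'
#' @param boundaries 0-based boundary indices, or a list of such vectors.
#' @param annotation 0/1 indicator, or a list parallel to `boundaries`.
#' @return p-value.
#' @export
hypergeom_enrichment <- function(boundaries, annotation) {
  if (!is.list(boundaries)) boundaries <- list(boundaries)
  if (!is.list(annotation)) annotation <- list(annotation)
  stopifnot(length(boundaries) == length(annotation))
  N <- sum(lengths(annotation))
  n_bind <- sum(vapply(annotation, sum, 0))
  n_tad <- sum(lengths(boundaries))
  if (n_bind == 0 || n_tad == 0) stop("enrichment undefined without annotated or boundary bins")
  n_tb <- sum(mapply(function(b, a) sum(a[b + 1L]), boundaries, annotation))
  stats::phyper(n_tb - 1, n_bind, N - n_bind, n_tad, lower.tail = FALSE)
}

#' Jaccard index of two sets
#'
#' `|A ∩ B| / |A ∪ B|`; defined as 0 (with a warning) when both sets are
#' empty. Elements may be bin indices, or interaction pairs encoded as
#' strings such as `"i:j"`.
#'
#' @param a,b vectors interpreted as sets (duplicates ignored).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both sets empty; Jaccard index defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Area under the precision-recall curve
#'
#' Sweeps a threshold over the prediction scores from high to low (tied
#' scores are added as one group), computes precision and recall against the
#' truth set at each threshold, and accumulates the step-wise area
#' `sum (R_t - R_{t-1}) * P_t`. A scoring that ranks every true pair above
#' every other pair attains 1; a constant scoring attains the prevalence of
#' the truth set.
#'
#' @param truth data frame (or 2-column matrix) of true interaction pairs
#'   `(bin_i, bin_j)`; must be non-empty.
#' @param predictions data frame with columns `bin_i`, `bin_j`, `score`; the
#'   prediction universe must cover the evaluation domain.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(truth, predictions) {
  truth <- as.data.frame(truth)
  if (nrow(truth) == 0L) stop("truth set is empty")
  tkey <- paste(pmin(truth[[1L]], truth[[2L]]),
                pmax(truth[[1L]], truth[[2L]]), sep = ":")
  pkey <- paste(pmin(predictions[[1L]], predictions[[2L]]),
                pmax(predictions[[1L]], predictions[[2L]]), sep = ":")
  if (anyDuplicated(pkey)) stop("duplicate prediction pairs")
  is_pos <- pkey %in% tkey
  ord <- order(predictions[[3L]], decreasing = TRUE)
  score <- predictions[[3L]][ord]
  pos <- is_pos[ord]
  grp_last <- which(score != c(score[-1L], NA) | seq_along(score) == length(score))
  tp <- cumsum(pos)[grp_last]
  pp <- grp_last
  n_pos <- sum(is_pos)
  recall <- tp / n_pos
  precision <- tp / pp
  sum(diff(c(0, recall)) * precision)
}

#' Match clusters across two conditions by bin overlap
#'
#' Flags clusters that split or merge between two partitions of the same
#' chromosome: a cluster in `a` is reported when it overlaps at least
#' `split_min` clusters in `b` with a Jaccard index of at least `j_min`
#' (computed on bin sets). Background (`NA`) bins are ignored.
#'
#' @param a,b per-bin label vectors of equal length.
#' @param j_min Jaccard threshold (default 0.2).
#' @param split_min minimum number of qualifying matches (default 2).
#' @return data frame with columns `cluster_a`, `cluster_b`, `jaccard`,
#'   listing every qualifying match of every flagged cluster (zero rows if
#'   none).
#' @export
match_clusters <- function(a, b, j_min = 0.2, split_min = 2L) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  ids_a <- sort(unique(a[!is.na(a)]))
  ids_b <- sort(unique(b[!is.na(b)]))
  rows <- list()
  for (ia in ids_a) {
    bins_a <- which(a %in% ia)
    jj <- vapply(ids_b, function(ib) {
      jaccard_index(bins_a, which(b %in% ib))
    }, 0)
    hit <- which(jj >= j_min)
    if (length(hit) >= split_min) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_a = ia, cluster_b = ids_b[hit], jaccard = jj[hit])
    }
  }
  if (!length(rows)) {
    return(data.frame(cluster_a = integer(), cluster_b = integer(),
                      jaccard = numeric()))
  }
  do.call(rbind, rows)
}
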