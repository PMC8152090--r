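test_that("rand index endpoints and oracle agreement", {
  a <- random_contiguous_labels(30, 4)
  expect_equal(rand_index(a, a), 1)
  expect_equal(rand_index(rep(0, 20), 0:19), 0)
  expect_equal(rand_index(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0.5)
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:3, n, replace = TRUE)
    expect_equal(rand_index(a, b), oracle_rand(a, b), tolerance = 1e-12)
  }
  expect_error(rand_index(1:3, 1:4), "length")
})

test_that("mutual information: zero for constants, ln 2 for balanced match,
           symmetric, oracle agreement", {
  a <- random_contiguous_labels(24, 3)
  expect_equal(mutual_information(a, rep(0, 24)), 0)
  b <- rep(0:1, each = 10)
  expect_equal(mutual_information(b, b), log(2), tolerance = 1e-12)
  set.seed(62)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:3, n, replace = TRUE)
    expect_equal(mutual_information(a, b), oracle_mi(a, b), tolerance = 1e-12)
    expect_equal(mutual_information(a, b), mutual_information(b, a))
  }
})

test_that("label refinement repeats labels and preserves agreement", {
  expect_equal(refine_labels(c(0, 1), 2), c(0, 0, 1, 1))
  expect_equal(refine_labels(c(0, 1, 1), 1), c(0, 1, 1))
  a <- random_contiguous_labels(20, 4)
  expect_equal(rand_index(refine_labels(a, 5), refine_labels(a, 5)), 1)
  expect_error(refine_labels(c(0, 1), 2.5), "integer")
})

test_that("DBI: zero for zero-scatter blocks, oracle agreement", {
  x <- rbind(cbind(matrix(5, 2, 2), matrix(0, 2, 2)),
             cbind(matrix(0, 2, 2), matrix(5, 2, 2)))
  dbi <- dbi_per_cluster(x, c(0, 0, 1, 1))
  expect_equal(unname(dbi), c(0, 0))
  set.seed(63)
  for (rep in 1:10) {
    x <- matrix(rpois(144, 6), 12); x <- x + t(x)
    labels <- random_contiguous_labels(12, 3, min_run = 2L)
    expect_equal(unname(dbi_per_cluster(x, labels)), oracle_dbi(x, labels),
                 tolerance = 1e-9)
  }
  expect_error(dbi_per_cluster(x, rep(0, 12)), "two clusters")
  xc <- matrix(1, 6, 6)
  expect_warning(dbi_per_cluster(xc, rep(0:1, each = 3)), "coincident")
})

test_that("DCC: uniform matrices give zero, block contrast gives the gap,
           oracle agreement", {
  n <- 9
  labels <- rep(0:2, each = 3)
  x <- matrix(1, n, n)
  for (t in 0:2) x[labels == t, labels == t] <- 5
  expect_equal(unname(dcc_per_cluster(x, labels)), rep(4, 3))
  expect_equal(unname(dcc_per_cluster(matrix(3, n, n), labels)), rep(0, 3))
  set.seed(64)
  for (rep in 1:10) {
    x <- matrix(rpois(144, 6), 12); x <- x + t(x)
    labels <- random_contiguous_labels(12, 3, min_run = 2L)
    expect_equal(unname(dcc_per_cluster(x, labels)), oracle_dcc(x, labels),
                 tolerance = 1e-9)
  }
  expect_warning(out <- dcc_per_cluster(x, c(0, rep(1, 11))), "NA")
  expect_true(is.na(out["0"]))
})

test_that("TAD shuffles conserve stretch-length multisets and contiguity", {
  labels <- c(rep(0L, 3), NA, NA, rep(1L, 5))
  shufs <- shuffle_tads(labels, n_shuffles = 10, seed = 5)
  expect_length(shufs, 10)
  for (s in shufs) {
    tt <- clusters_to_tads(s)
    expect_equal(sort(tt$end_bin - tt$start_bin + 1L), c(3L, 5L))
    expect_equal(sum(is.na(s)), 2L)
    gap_runs <- rle(is.na(s))
    expect_equal(sum(gap_runs$lengths[gap_runs$values]), 2L)
  }
  expect_identical(shuffle_tads(labels, 5, seed = 9),
                   shuffle_tads(labels, 5, seed = 9))
  # property: random contiguous labelings keep their length multiset
  set.seed(66)
  for (rep in 1:20) {
    l <- random_contiguous_labels(40, 5)
    s <- shuffle_tads(l, n_shuffles = 1, seed = rep)[[1]]
    expect_equal(sort(table(s)), sort(table(l)), ignore_attr = TRUE)
  }
})

test_that("empirical p-values are strict-inequality fractions", {
  expect_equal(
    empirical_significance(5, c(1, 2, 3, 4), "higher_is_better")$p_values,
    0)
  expect_equal(
    empirical_significance(3.5, c(1, 2, 3, 4), "higher_is_better")$p_values,
    0.25)
  # ties count as not better
  expect_equal(
    empirical_significance(3, c(1, 2, 3, 4), "higher_is_better")$p_values,
    0.25)
  expect_equal(
    empirical_significance(2, c(1, 2, 3, 4), "lower_is_better")$p_values,
    0.25)
  expect_error(empirical_significance(1, numeric(0), "higher_is_better"),
               "empty")
})

test_that("null calibration: observed values from the null give ~alpha", {
  set.seed(71)
  n_tads <- 2000L; len <- 5L; gap <- 2L
  vals <- as.vector(rbind(seq_len(n_tads) - 1L, NA_integer_))
  labels <- rep(vals, times = rep(c(len, gap), n_tads))
  signal <- rnorm(length(labels))
  null <- unlist(lapply(shuffle_tads(labels, 10, seed = 72), function(l) {
    mean_signal_per_tad(signal, l)
  }))
  obs <- mean_signal_per_tad(signal, labels)
  frac <- empirical_significance(obs, null,
                                 "higher_is_better")$significant_fraction
  expect_lt(abs(frac - 0.05), 0.03)
})

test_that("per-TAD signal means equal direct averaging", {
  expect_equal(unname(mean_signal_per_tad(c(0, 0, 6, 6),
                                          rep(0:1, each = 2))), c(0, 6))
  expect_equal(unname(mean_signal_per_tad(rep(3, 10),
                                          random_contiguous_labels(10, 3))),
               rep(3, 3))
  set.seed(67)
  sig <- rnorm(30); labels <- random_contiguous_labels(30, 4)
  direct <- sapply(0:3, function(t) mean(sig[labels == t]))
  expect_equal(unname(mean_signal_per_tad(sig, labels)), direct)
  expect_error(mean_signal_per_tad(1:3, 1:4), "length")
})

test_that("fold enrichment follows the boundary-rate ratio", {
  ann <- integer(100); ann[1:10] <- 1L
  boundaries <- c(0:3, 20:35)            # 20 boundary bins, 4 annotated
  expect_equal(fold_enrichment(boundaries, ann), 2)
  expect_equal(fold_enrichment(boundaries, rep(1L, 100)), 1)
  expect_error(fold_enrichment(boundaries, integer(100)), "no annotated")
  expect_error(fold_enrichment(integer(0), ann), "no boundary")
  # random boundaries are unenriched on average
  set.seed(68)
  fe <- replicate(1000, fold_enrichment(sample(0:99, 20), ann))
  expect_lt(abs(mean(fe) - 1), 0.05)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  ann <- c(rep(1L, 5), rep(0L, 5))
  expect_equal(hypergeom_enrichment(0:4, ann), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(5:9, ann), 1)
  # monotone in the overlap, all else fixed
  p <- sapply(0:5, function(o) {
    b <- c(seq_len(o) - 1L, 5L + seq_len(5L - o) - 1L)
    hypergeom_enrichment(b, ann)
  })
  expect_true(all(diff(p) <= 1e-12))
  # aggregation across chromosomes pools the counts
  expect_equal(hypergeom_enrichment(list(0:4, 0:4), list(ann, ann)),
               stats::phyper(9, 10, 10, 10, lower.tail = FALSE))
})

test_that("jaccard index handles the standard cases", {
  expect_equal(jaccard_index(1:3, 1:3), 1)
  expect_equal(jaccard_index(1:3, 4:6), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(j <- jaccard_index(integer(0), integer(0)), "empty")
  expect_equal(j, 0)
})

test_that("AUPR: perfect ranking, constant scores, and oracle agreement", {
  truth <- data.frame(i = 1:5, j = 2:6)
  preds <- data.frame(i = 1:10, j = 2:11,
                      score = c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(aupr(truth, preds), 1)
  preds$score <- 0.5
  expect_equal(aupr(truth, preds), 0.5)   # prevalence
  set.seed(69)
  for (rep in 1:10) {
    pairs <- t(combn(12, 2))[sample(66, 50), ]
    truth <- pairs[sample(50, 12), ]
    preds <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        score = round(runif(50), 2))
    tkey <- paste(truth[, 1], truth[, 2], sep = ":")
    pkey <- paste(preds$i, preds$j, sep = ":")
    expect_equal(aupr(as.data.frame(truth), preds),
                 oracle_aupr(tkey, pkey, preds$score), tolerance = 1e-9)
  }
  expect_error(aupr(data.frame(i = integer(), j = integer()), preds),
               "empty")
})

test_that("cluster matching flags splits at the Jaccard threshold", {
  a <- rep(0L, 10)
  b <- rep(0:1, each = 5)
  m <- match_clusters(a, b)
  expect_equal(nrow(m), 2L)
  expect_equal(m$jaccard, c(0.5, 0.5))
  # identical partitions yield no flags
  expect_equal(nrow(match_clusters(b, b)), 0L)
  # matches just below the threshold are not flagged
  a2 <- rep(0L, 100)
  b2 <- c(rep(0L, 19), rep(1L, 19), rep(2L, 62))
  expect_equal(nrow(match_clusters(a2, b2, j_min = 0.2)), 0L)
})
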