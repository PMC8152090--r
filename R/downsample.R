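#' Distance-stratified profile of a contact matrix
#'
#' For each genomic distance `d` (in bins, `d = 0` is the diagonal),
#' summarizes the upper triangle: the mean of the non-zero counts, and how
#' many entries at that distance are non-zero versus zero. These profiles
#' drive depth matching in [downsample_matrix()].
#'
#' @param x contact matrix (matrix or [contact_matrix()]).
#' @return data frame with columns `d`, `mean_nonzero` (0 where no non-zero
#'   entry exists), `n_nonzero`, `n_zero`; one row per `d` in
#'   `0..(n_bins - 1)`.
#' @export
distance_profile <- function(x) {
  x <- as_counts(x)
  n <- nrow(x)
  idx <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  d <- idx[, 2L] - idx[, 1L]
  v <- x[idx]
  nz <- v != 0
  sums <- vapply(0:(n - 1L), function(dd) sum(v[d == dd & nz]), 0)
  n_nz <- vapply(0:(n - 1L), function(dd) sum(d == dd & nz), 0L)
  n_z <- vapply(0:(n - 1L), function(dd) sum(d == dd & !nz), 0L)
  data.frame(d = 0:(n - 1L),
             mean_nonzero = ifelse(n_nz > 0, sums / pmax(n_nz, 1L), 0),
             n_nonzero = n_nz, n_zero = n_z)
}

#' Scale a distance profile to emulate a shallower library
#'
#' Convenience constructor for downsampling targets: multiplies each
#' stratum's non-zero mean by `mean_factor` and its zero count by
#' `zero_factor` (moving entries from the non-zero to the zero tally, capped
#' at the stratum size).
#'
#' @param profile a [distance_profile()] table.
#' @param mean_factor multiplier for `mean_nonzero` (e.g. 0.2).
#' @param zero_factor multiplier for `n_zero` (e.g. 2).
#' @return a profile table of the same shape.
#' @export
scale_profile <- function(profile, mean_factor = 1, zero_factor = 1) {
  tot <- as.integer(profile$n_nonzero + profile$n_zero)
  nz_new <- as.integer(pmin(round(profile$n_zero * zero_factor), tot))
  data.frame(d = profile$d,
             mean_nonzero = profile$mean_nonzero * mean_factor,
             n_nonzero = tot - nz_new, n_zero = nz_new)
}

#' Distance-stratified downsampling of a contact matrix
#'
#' Emulates a lower-depth experiment: every non-zero entry at distance `d`
#' is scaled by `mu_l(d) / mu_h(d)` (the target and source non-zero means),
#' and then `z_d = max(0, zeros_target(d) - zeros_source(d))` surviving
#' non-zero entries per distance are chosen uniformly at random and set to
#' zero, symmetrically. Scaling never zeroes an entry and the output is kept
#' real-valued (set `round_counts = TRUE` to re-integerize).
#'
#' @param x high-depth contact matrix (matrix or [contact_matrix()]).
#' @param target a [distance_profile()]-shaped table with a record for every
#'   distance present in `x`.
#' @param seed seed for the sparsification draw.
#' @param round_counts round the scaled counts to integers (default FALSE).
#' @return numeric matrix of downsampled counts, symmetric and non-negative.
#' @export
downsample_matrix <- function(x, target, seed = 1L, round_counts = FALSE) {
  x <- as_counts(x)
  n <- nrow(x)
  src <- distance_profile(x)
  if (!all(src$d[src$n_nonzero > 0] %in% target$d)) {
    stop("target profile lacks records for distances present in the matrix")
  }
  out <- x
  with_seed(seed, {
    for (row in seq_len(nrow(src))) {
      dd <- src$d[row]
      if (src$n_nonzero[row] == 0L) {
        trow <- target[target$d == dd, , drop = FALSE]
        if (nrow(trow) == 1L && trow$mean_nonzero > 0) {
          warning("no non-zero source entries at distance ", dd,
                  "; stratum skipped")
        }
        next
      }
      trow <- target[target$d == dd, , drop = FALSE]
      mu_h <- src$mean_nonzero[row]
      mu_l <- trow$mean_nonzero
      ii <- seq_len(n - dd)
      cells <- cbind(ii, ii + dd)
      nzc <- cells[x[cells] != 0, , drop = FALSE]
      if (mu_h > 0 && mu_l > 0) {
        out[nzc] <- x[nzc] / (mu_h / mu_l)
      }
      z_d <- max(0L, trow$n_zero - src$n_zero[row])
      z_d <- min(z_d, nrow(nzc))
      if (z_d > 0L) {
        kill <- nzc[sample.int(nrow(nzc), z_d), , drop = FALSE]
        out[kill] <- 0
      }
    }
  })
  if (round_counts) out <- round(out)
  # mirror the processed upper triangle
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}
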