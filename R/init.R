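# Seeded evaluation that leaves the caller's RNG stream untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Randomized truncated SVD
#'
#' Halko-Martinsson-Tropp randomized range finder with power iterations:
#' project onto `X %*% Omega` for a seeded Gaussian test matrix `Omega` with
#' `k + oversample` columns, orthonormalize, optionally apply power
#' iterations to sharpen the spectrum, and take the exact SVD of the small
#' projected matrix. Deterministic given `seed`.
#'
#' @param x numeric matrix (n x m).
#' @param k number of singular triplets to return; at most `min(n, m)`.
#' @param seed integer seed for the Gaussian test matrix.
#' @param oversample extra random directions beyond `k` (default 10).
#' @param n_power_iter power iterations (default 2).
#' @return list with `u` (n x k), `d` (length k, non-increasing), `v` (m x k).
#' @export
randomized_svd <- function(x, k, seed = 1L, oversample = 10L,
                           n_power_iter = 2L) {
  x <- as_counts(x)
  n <- nrow(x); m <- ncol(x)
  if (k > min(n, m)) stop("k must not exceed the matrix dimension")
  p <- min(m, k + oversample)
  omega <- with_seed(seed, matrix(stats::rnorm(m * p), m, p))
  q <- qr.Q(qr(x %*% omega))
  for (i in seq_len(n_power_iter)) {
    q <- qr.Q(qr(crossprod(x, q)))
    q <- qr.Q(qr(x %*% q))
  }
  b <- crossprod(q, x)           # p x m
  s <- svd(b, nu = k, nv = k)
  list(u = q %*% s$u, d = s$d[seq_len(k)], v = s$v)
}

#' NNDSVD initialization for non-negative factorization
#'
#' Non-negative Double Singular Value Decomposition: builds initial factors
#' from the leading singular triplets of `x`. The first columns are
#' `sqrt(d1) * |u1|` and `sqrt(d1) * |v1|`; for each later triplet the
#' sign-consistent positive/negative part pair with the larger norm product
#' is kept and rescaled to carry that triplet's energy. Exact zeros are then
#' replaced by `mean(x) / 100` (the dense-fill variant), because zeros are
#' absorbing states under multiplicative updates.
#'
#' @param x non-negative matrix.
#' @param k rank.
#' @param seed seed passed to [randomized_svd()].
#' @param ... further arguments for [randomized_svd()].
#' @return list with non-negative `u` and `v` (both n x k).
#' @export
nndsvd_init <- function(x, k, seed = 1L, ...) {
  x <- as_counts(x)
  if (all(x == 0)) stop("cannot initialize from an all-zero matrix")
  s <- randomized_svd(x, k, seed = seed, ...)
  n <- nrow(x); m <- ncol(x)
  U <- matrix(0, n, k); V <- matrix(0, m, k)
  # leading singular vectors of a non-negative matrix have a constant sign
  U[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
  V[, 1L] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
  for (j in seq_len(k)[-1L]) {
    uu <- s$u[, j]; vv <- s$v[, j]
    up <- pmax(uu, 0); un <- pmax(-uu, 0)
    vp <- pmax(vv, 0); vn <- pmax(-vv, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      mu <- nup * nvp
      if (mu > 0) {
        U[, j] <- sqrt(s$d[j] * mu) * up / nup
        V[, j] <- sqrt(s$d[j] * mu) * vp / nvp
      }
    } else {
      mu <- nun * nvn
      U[, j] <- sqrt(s$d[j] * mu) * un / nun
      V[, j] <- sqrt(s$d[j] * mu) * vn / nvn
    }
  }
  # numerical noise below machine precision counts as zero for the fill
  fill <- mean(x) / 100
  thr <- .Machine$double.eps * s$d[1L]
  U[U <= thr] <- fill
  V[V <= thr] <- fill
  list(u = U, v = V)
}
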