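#' Graph-regularized NMF objective
#'
#' `||X - U V'||_F^2 + lambda * Tr(V' L V) + lambda * Tr(U' L U)`, the
#' reconstruction error plus Laplacian smoothness penalties on both factors.
#' Columns that are constant along the chromosome incur no penalty because
#' constant vectors lie in the Laplacian null space.
#'
#' @param x contact matrix (matrix or [contact_matrix()]).
#' @param u,v factor matrices (n x k, non-negative).
#' @param L graph Laplacian, from [neighbor_graph()].
#' @param lambda regularization strength, `>= 0`.
#' @return the objective value (scalar).
#' @export
gnmf_objective <- function(x, u, v, L, lambda) {
  x <- as_counts(x)
  if (nrow(u) != nrow(x) || nrow(v) != ncol(x) || ncol(u) != ncol(v)) {
    stop("factor shapes do not conform with the input matrix")
  }
  r <- x - tcrossprod(u, v)
  obj <- sum(r * r)
  if (lambda != 0) {
    obj <- obj + lambda * (sum(v * (L %*% v)) + sum(u * (L %*% u)))
  }
  obj
}

#' Fit GRiNCH: graph-regularized NMF with TAD calling
#'
#' Decomposes a symmetric contact count matrix `X` as `X ~ U V'` with
#' non-negative factors that are encouraged to vary smoothly along the
#' chromosome, then segments the chromosome into contiguous clusters (TADs)
#' by chain-constrained k-medoids on the rows of `U`. The reconstruction
#' `(U V' + V U') / 2` doubles as a smoothed, imputed version of the input
#' (see [fitted.grinch()]).
#'
#' @details The factors are initialized with NNDSVD ([nndsvd_init()]) and
#' refined by multiplicative updates that extend the classical Frobenius-norm
#' rules with graph terms:
#' \deqn{u_{ik} \leftarrow u_{ik}\,\frac{(XV + \lambda W U)_{ik}}
#'       {(U V^\top V + \lambda D U + \epsilon)_{ik}}}
#' and symmetrically for `V`, where `W` is the chain adjacency within radius
#' `r`, `D` its degree matrix, and `eps = 1e-10` guards empty denominators.
#' `lambda = 0` recovers plain unregularized NMF. The objective
#' ([gnmf_objective()]) is evaluated every `check_every` iterations and the
#' fit stops once its relative decrease falls below `tol`, or at `max_iter`.
#'
#' `U` and `V` are kept as separate matrices; for a symmetric input they
#' agree up to scaling but are not forced to coincide.
#'
#' @param x a [contact_matrix()] or a plain symmetric non-negative matrix.
#' @param k factorization rank = number of TADs; defaults to
#'   [choose_k()] with `expected_tad_size`.
#' @param r neighborhood radius in bp (default 250 kb). For a plain matrix
#'   with `bin_size = 1`, `r` is in bins.
#' @param lambda regularization strength (default 1).
#' @param expected_tad_size expected TAD span in bp, used when `k` is `NULL`
#'   (default 1 Mb).
#' @param max_iter maximum multiplicative-update iterations (default 300).
#' @param tol relative objective-decrease threshold (default 1e-4).
#' @param check_every iterations between objective evaluations (default 10).
#' @param seed seed for the randomized SVD behind the initialization.
#' @param call_tads if `TRUE` (default) run the chain-constrained k-medoids
#'   segmentation on `U` after the factorization.
#' @param kmedoids_max_iter iteration cap for the segmentation (default 50).
#'
#' @return An object of class `grinch`: a list with the input (`x`), factors
#'   `u`, `v`, the objective trace (`trace`: data frame of iteration and
#'   objective), `final_objective`, `n_iter`, per-bin 0-based `labels`, the
#'   TAD table (`tads`), the `graph`, and the resolved parameters (`params`).
#' @seealso [fitted.grinch()], [tads()], [chain_kmedoids()]
#' @export
#' @examples
#' sim <- simulate_contacts(n_bins = 120, block_lengths = rep(30, 4),
#'                          seed = 1)
#' fit <- grinch(sim$matrix, k = 4, r = 10)
#' fit
#' head(tads(fit))
grinch <- function(x, k = NULL, r = 250000, lambda = 1,
                   expected_tad_size = 1e6, max_iter = 300, tol = 1e-4,
                   check_every = 10L, seed = 1L, call_tads = TRUE,
                   kmedoids_max_iter = 50L) {
  if (!inherits(x, "contact_matrix")) x <- contact_matrix(x)
  X <- x$counts
  n <- x$n_bins
  if (is.null(k)) k <- choose_k(n, x$bin_size, expected_tad_size)
  if (k < 2L || k >= n) stop("k must satisfy 2 <= k < n_bins, got ", k)
  if (lambda < 0) stop("lambda must be non-negative")
  g <- neighbor_graph(n, x$bin_size, r)

  init <- nndsvd_init(X, k, seed = seed)
  U <- init$u; V <- init$v
  W <- g$W; deg <- diag(g$D)
  eps <- 1e-10

  obj <- gnmf_objective(X, U, V, g$L, lambda)
  trace <- data.frame(iter = 0L, objective = obj)
  n_iter <- max_iter
  for (it in seq_len(max_iter)) {
    U <- U * (X %*% V + lambda * (W %*% U)) /
      (U %*% crossprod(V) + lambda * (deg * U) + eps)
    V <- V * (crossprod(X, U) + lambda * (W %*% V)) /
      (V %*% crossprod(U) + lambda * (deg * V) + eps)
    if (any(!is.finite(U)) || any(!is.finite(V))) {
      stop("non-finite factor entries at iteration ", it)
    }
    if (it %% check_every == 0L || it == max_iter) {
      new_obj <- gnmf_objective(X, U, V, g$L, lambda)
      trace <- rbind(trace, data.frame(iter = it, objective = new_obj))
      if (abs(obj - new_obj) < tol * abs(obj)) {
        n_iter <- it
        obj <- new_obj
        break
      }
      obj <- new_obj
      n_iter <- it
    }
  }

  fit <- structure(
    list(x = x, u = U, v = V, trace = trace, final_objective = obj,
         n_iter = n_iter, labels = NULL, tads = NULL, graph = g,
         params = list(k = k, r = r, r_bins = g$r_bins, lambda = lambda,
                       max_iter = max_iter, tol = tol,
                       check_every = check_every, seed = seed),
         call = match.call()),
    class = "grinch")
  if (call_tads) {
    fit$labels <- chain_kmedoids(U, k, max_iter = kmedoids_max_iter)
    fit$tads <- clusters_to_tads(fit$labels)
  }
  fit
}

#' @export
print.grinch <- function(x, ...) {
  cat("GRiNCH fit\n")
  cat(sprintf("  %s: %d bins of %s bp\n", x$x$chrom, x$x$n_bins,
              format(x$x$bin_size, big.mark = ",")))
  cat(sprintf("  rank k = %d, radius = %d bins, lambda = %g\n",
              x$params$k, x$params$r_bins, x$params$lambda))
  cat(sprintf("  converged after %d iterations, objective %.6g\n",
              x$n_iter, x$final_objective))
  if (!is.null(x$tads)) {
    cat(sprintf("  %d TADs called, median span %d bins\n", nrow(x$tads),
                as.integer(stats::median(x$tads$end_bin - x$tads$start_bin + 1))))
  }
  invisible(x)
}

#' @export
summary.grinch <- function(object, ...) {
  spans <- if (!is.null(object$tads)) {
    object$tads$end_bin - object$tads$start_bin + 1L
  } else integer()
  res <- object$x$counts - fitted(object)
  out <- list(
    params = object$params, n_bins = object$x$n_bins,
    bin_size = object$x$bin_size,
    n_iter = object$n_iter, final_objective = object$final_objective,
    relative_error = sqrt(sum(res^2) / sum(object$x$counts^2)),
    n_tads = length(spans), tad_span_bins = summary(spans))
  class(out) <- "summary.grinch"
  out
}

#' @export
print.summary.grinch <- function(x, ...) {
  cat(sprintf("GRiNCH fit: %d bins, k = %d, radius %d bins, lambda = %g\n",
              x$n_bins, x$params$k, x$params$r_bins, x$params$lambda))
  cat(sprintf("  objective %.6g after %d iterations\n", x$final_objective,
              x$n_iter))
  cat(sprintf("  relative reconstruction error ||X - UV'||/||X|| = %.4f\n",
              x$relative_error))
  if (x$n_tads > 0) {
    cat(sprintf("  %d TADs; span (bins):\n", x$n_tads))
    print(x$tad_span_bins)
  }
  invisible(x)
}

#' Extract the factor matrices
#'
#' @param object a [grinch()] fit.
#' @param ... ignored.
#' @return list with `u` and `v`.
#' @export
coef.grinch <- function(object, ...) list(u = object$u, v = object$v)

#' Smoothed (completed) contact matrix from a fit
#'
#' The low-rank reconstruction serves as a smoothed, imputed contact matrix:
#' structural zeros inside a domain borrow strength from their neighborhood.
#' Because `U` and `V` differ numerically, the product is symmetrized as
#' `(U V' + V U') / 2`.
#'
#' @param object a [grinch()] fit.
#' @param ... ignored.
#' @return numeric matrix of smoothed counts, same dimension as the input.
#' @export
fitted.grinch <- function(object, ...) {
  s <- tcrossprod(object$u, object$v)
  (s + t(s)) / 2
}

#' @export
residuals.grinch <- function(object, ...) object$x$counts - fitted(object)

#' @rdname fitted.grinch
#' @param newdata ignored; the reconstruction is defined for the fitted
#'   matrix only.
#' @export
predict.grinch <- function(object, newdata = NULL, ...) {
  if (!is.null(newdata)) {
    stop("a GRiNCH fit reconstructs its own input; refit to smooth another matrix")
  }
  fitted(object)
}

#' Extract the TAD table from a fit
#'
#' @param object a [grinch()] fit.
#' @return data frame with `start_bin`, `end_bin` (inclusive, 0-based) and
#'   `cluster_id`.
#' @export
tads <- function(object) {
  if (is.null(object$tads)) stop("fit was run with call_tads = FALSE")
  object$tads
}

#' Plot a GRiNCH fit
#'
#' Heatmap of the (log1p) contact counts with the called TADs outlined on
#' the diagonal.
#'
#' @param x a [grinch()] fit.
#' @param smoothed plot the reconstructed matrix instead of the input.
#' @param ... passed to [graphics::image()].
#' @export
plot.grinch <- function(x, smoothed = FALSE, ...) {
  m <- if (smoothed) fitted(x) else x$x$counts
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), log1p(m)[, n:1],
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "bin", ylab = "bin", axes = FALSE, ...)
  graphics::axis(1); graphics::axis(2, at = pretty(seq_len(n)),
                                    labels = rev(pretty(seq_len(n))))
  if (!is.null(x$tads)) {
    for (r in seq_len(nrow(x$tads))) {
      a <- x$tads$start_bin[r] + 0.5
      b <- x$tads$end_bin[r] + 1.5
      graphics::rect(a, n - b + 1, b, n - a + 1, border = "blue", lwd = 1.5)
    }
  }
  invisible(x)
}
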