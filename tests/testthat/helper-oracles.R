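# Brute-force reference implementations, kept deliberately naive (explicit
# loops, no shared code with the package internals) so they can serve as
# independent oracles.

oracle_objective <- function(x, u, v, L, lambda) {
  n <- nrow(x); k <- ncol(u)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(ncol(x))) {
    acc <- acc + (x[i, j] - sum(u[i, ] * v[j, ]))^2
  }
  reg <- 0
  for (c in seq_len(k)) {
    reg <- reg + sum(v[, c] * (L %*% v[, c])) + sum(u[, c] * (L %*% u[, c]))
  }
  acc + lambda * reg
}

oracle_mean_filter <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    a <- max(1, i - r):min(n, i + r)
    b <- max(1, j - r):min(m, j + r)
    out[i, j] <- mean(x[a, b])
  }
  out
}

oracle_gaussian_filter <- function(x, sigma, prefactor = FALSE) {
  n <- nrow(x); m <- ncol(x)
  hw <- floor(4 * sigma)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    num <- 0; wsum <- 0
    for (a in max(1, i - hw):min(n, i + hw)) {
      for (b in max(1, j - hw):min(m, j + hw)) {
        w <- exp(-((i - a)^2 + (j - b)^2) / (2 * sigma^2))
        num <- num + w * x[a, b]
        wsum <- wsum + w
      }
    }
    out[i, j] <- if (prefactor) num / (2 * pi * sigma^2) else num / wsum
  }
  out
}

oracle_dbi <- function(x, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  cent <- list(); scatter <- numeric(k)
  for (t in seq_len(k)) {
    rows <- which(labels == ids[t])
    cent[[t]] <- colMeans(x[rows, , drop = FALSE])
    dd <- 0
    for (r in rows) dd <- dd + sqrt(sum((x[r, ] - cent[[t]])^2))
    scatter[t] <- dd / length(rows)
  }
  out <- numeric(k)
  for (t in seq_len(k)) {
    best <- -Inf
    for (s in seq_len(k)) {
      if (s == t) next
      dist_ts <- sqrt(sum((cent[[t]] - cent[[s]])^2))
      best <- max(best, (scatter[t] + scatter[s]) / dist_ts)
    }
    out[t] <- best
  }
  out
}

oracle_dcc <- function(x, labels) {
  ids <- sort(unique(labels))
  n <- nrow(x)
  out <- numeric(length(ids))
  for (t in seq_along(ids)) {
    inside <- c(); outside <- c()
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      pin <- labels[p] == ids[t]; qin <- labels[q] == ids[t]
      if (pin && qin) inside <- c(inside, x[p, q])
      else if (pin || qin) outside <- c(outside, x[p, q])
    }
    out[t] <- mean(inside) - mean(outside)
  }
  out
}

oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (p in 1:(n - 1)) for (q in (p + 1):n) {
    same_a <- a[p] == a[q]; same_b <- b[p] == b[q]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / choose(n, 2)
}

oracle_mi <- function(a, b) {
  n <- length(a)
  acc <- 0
  for (va in unique(a)) for (vb in unique(b)) {
    pab <- sum(a == va & b == vb) / n
    if (pab > 0) {
      acc <- acc + pab * log(pab / ((sum(a == va) / n) * (sum(b == vb) / n)))
    }
  }
  acc
}

# AUPR by explicit threshold enumeration over the distinct scores
oracle_aupr <- function(truth_keys, pred_keys, scores) {
  is_pos <- pred_keys %in% truth_keys
  npos <- sum(is_pos)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0; area <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(is_pos & sel)
    precision <- tp / sum(sel)
    recall <- tp / npos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

oracle_distance_profile <- function(x) {
  n <- nrow(x)
  out <- data.frame(d = 0:(n - 1), mean_nonzero = 0, n_nonzero = 0L,
                    n_zero = 0L)
  for (i in 1:n) for (j in i:n) {
    d <- j - i
    row <- d + 1
    if (x[i, j] != 0) {
      out$n_nonzero[row] <- out$n_nonzero[row] + 1L
      out$mean_nonzero[row] <- out$mean_nonzero[row] + x[i, j]
    } else {
      out$n_zero[row] <- out$n_zero[row] + 1L
    }
  }
  out$mean_nonzero <- ifelse(out$n_nonzero > 0,
                             out$mean_nonzero / pmax(out$n_nonzero, 1L), 0)
  out
}

# random contiguous labeling of n bins into m runs (each of >= min_run bins)
random_contiguous_labels <- function(n, m, min_run = 1L) {
  repeat {
    cuts <- sort(sample(seq_len(n - 1), m - 1))
    lens <- diff(c(0, cuts, n))
    if (all(lens >= min_run)) return(rep(seq_len(m) - 1L, lens))
  }
}
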