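test_that("choose_k follows the chromosome-length / expected-size rule", {
  expect_equal(choose_k(4000, 25000, 1e6), 100L)
  expect_equal(choose_k(40, 25000, 5e5), 2L)
  expect_equal(choose_k(10, 25000, 1e9), 2L)   # floor at 2
  expect_error(choose_k(100, 25000, 10000), "at least one bin")
})

test_that("neighbor graph has chain structure and a proper Laplacian", {
  g <- neighbor_graph(5, 1, 1)
  expect_equal(g$W, (abs(outer(1:5, 1:5, "-")) == 1) * 1)
  expect_equal(diag(g$D), c(1, 2, 2, 2, 1))
  expect_equal(rowSums(g$L), rep(0, 5))
  ev <- eigen(g$L, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))

  # radius clipped by chromosome ends: fully connected off-diagonal
  g2 <- neighbor_graph(4, 1, 10)
  expect_equal(g2$W, 1 - diag(4))

  # 250 kb at 25 kb resolution -> 10 bins, interior degree 20
  g3 <- neighbor_graph(50, 25000, 250000)
  expect_equal(g3$r_bins, 10L)
  expect_equal(g3$D[25, 25], 20)
  expect_error(neighbor_graph(10, 25000, 10000), "empty")
})

test_that("randomized SVD recovers exact spectra and is deterministic", {
  # diagonal 2x2: exact singular values
  s <- randomized_svd(diag(c(4, 1)), 2, seed = 1, oversample = 0)
  expect_equal(s$d, c(4, 1), tolerance = 1e-10)
  expect_true(all(diff(s$d) <= 0))

  # rank-1 matrix: sigma recovered to 1e-6 relative
  set.seed(5)
  u <- rnorm(20); u <- u / sqrt(sum(u^2))
  x <- 3.7 * tcrossprod(u)
  s1 <- randomized_svd(x, 1, seed = 2)
  expect_equal(s1$d, 3.7, tolerance = 1e-6)

  # same seed -> identical output; matches exact svd on random matrices
  set.seed(6)
  for (rep in 1:3) {
    x <- matrix(rpois(400, 5), 20)
    a <- randomized_svd(x, 4, seed = 9)
    b <- randomized_svd(x, 4, seed = 9)
    expect_identical(a, b)
    expect_equal(a$d, svd(x)$d[1:4], tolerance = 1e-6)
  }
  expect_error(randomized_svd(diag(3), 4, seed = 1), "exceed")
})

test_that("NNDSVD initialization is non-negative, deterministic, near-SVD", {
  sim <- simulate_contacts(60, c(20, 20, 20), seed = 2)
  x <- sim$matrix$counts
  init <- nndsvd_init(x, 5, seed = 3)
  expect_true(all(init$u >= 0) && all(init$v >= 0))
  expect_true(all(init$u > 0))   # dense fill removed exact zeros
  expect_identical(init, nndsvd_init(x, 5, seed = 3))

  # identity: factors approach sqrt of the singular structure, columns
  # aligned with coordinate axes up to the zero-fill constant
  ii <- nndsvd_init(diag(2) + 0, 2, seed = 1, oversample = 0)
  fill <- mean(diag(2) + 0) / 100
  expect_equal(sort(abs(ii$u[, 1])), sort(c(fill, 1)), tolerance = 1e-6)
  expect_equal(abs(det(round(ii$u))), 1)  # columns are (near) e1, e2

  expect_error(nndsvd_init(matrix(0, 4, 4), 2), "all-zero")
})

test_that("objective matches a brute-force evaluation and its edge cases", {
  set.seed(11)
  g <- neighbor_graph(10, 1, 2)
  for (rep in 1:5) {
    x <- matrix(rpois(100, 4), 10)
    u <- matrix(runif(30), 10); v <- matrix(runif(30), 10)
    lam <- sample(c(0, 1, 10), 1)
    expect_equal(gnmf_objective(x, u, v, g$L, lam),
                 oracle_objective(x, u, v, g$L, lam),
                 tolerance = 1e-9)
  }
  # exact factorization, lambda = 0 -> zero objective
  u <- matrix(runif(20), 10)
  x <- tcrossprod(u)
  expect_equal(gnmf_objective(x, u, u, g$L, 0), 0, tolerance = 1e-9)
  # constant columns lie in the Laplacian null space
  uc <- matrix(rep(c(2, 5), each = 10), 10)
  expect_equal(sum(uc * (g$L %*% uc)), 0, tolerance = 1e-12)
  expect_error(gnmf_objective(matrix(1, 4, 4), u, u, g$L, 1), "conform")
})

test_that("multiplicative updates keep factors non-negative and finite", {
  for (s in 1:3) {
    sim <- simulate_contacts(80, c(30, 25, 25), seed = s)
    fit <- grinch(sim$matrix, k = 3, lambda = sample(c(0, 1, 10), 1),
                  seed = s, call_tads = FALSE)
    expect_true(all(fit$u >= 0) && all(fit$v >= 0))
    expect_true(all(is.finite(fit$u)) && all(is.finite(fit$v)))
  }
})

test_that("an exact non-negative factorization is a fixed point at lambda 0", {
  set.seed(21)
  u0 <- matrix(runif(60, 0.5, 2), 20)
  x <- tcrossprod(u0)
  # one manual multiplicative update starting at the true factors
  U <- u0; V <- u0
  U2 <- U * (x %*% V) / (U %*% crossprod(V))
  V2 <- V * (crossprod(x, U2)) / (V %*% crossprod(U2))
  expect_equal(U2, U, tolerance = 1e-12)
  expect_equal(V2, V, tolerance = 1e-12)
})

test_that("fits are deterministic given identical input and seed", {
  sim <- simulate_contacts(60, c(30, 30), seed = 4)
  f1 <- grinch(sim$matrix, k = 2, seed = 17)
  f2 <- grinch(sim$matrix, k = 2, seed = 17)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$v, f2$v)
  expect_identical(f1$labels, f2$labels)
})

test_that("regularization reduces the Laplacian quadratic form of U", {
  for (s in 1:3) {
    sim <- simulate_contacts(120, c(40, 40, 40), seed = s)
    g <- neighbor_graph(120, 25000, 250000)
    f0 <- grinch(sim$matrix, k = 3, lambda = 0, seed = s, call_tads = FALSE)
    f10 <- grinch(sim$matrix, k = 3, lambda = 10, seed = s, call_tads = FALSE)
    expect_lt(sum(f10$u * (g$L %*% f10$u)), sum(f0$u * (g$L %*% f0$u)))
  }
})

test_that("grinch validates its parameters", {
  sim <- simulate_contacts(40, c(20, 20), seed = 1)
  expect_error(grinch(sim$matrix, k = 1), "k must satisfy")
  expect_error(grinch(sim$matrix, k = 40), "k must satisfy")
  expect_error(grinch(sim$matrix, k = 4, lambda = -1), "non-negative")
  expect_error(grinch(sim$matrix, k = 4, r = 100), "smaller than one bin")
})
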