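test_that("context_covariance is the outer product of C", {
  C <- context_matrix(matrix(c(1, -1), 2, 1), standardized = TRUE)
  expect_equal(as_dense(context_covariance(C)),
               matrix(c(1, -1, -1, 1), 2))
  expect_error(context_covariance(context_matrix(matrix(1:4, 2))),
               "standardized")

  # one-hot Sigma is the 0/1 block matrix
  lab <- c("a", "a", "b", "c", "b")
  C1 <- one_hot_contexts(lab, standardize = FALSE)
  expect_equal(tcrossprod(C1$values), outer(lab, lab, "==") * 1,
               ignore_attr = TRUE)
})

test_that("relatedness_context_covariance factors the Hadamard product", {
  # identity kinship, one cell per donor, orthonormal-ish Sigma: R o Sigma
  # with R = I is diag(Sigma)
  set.seed(10)
  N <- 12; d <- 3; k <- 2
  map <- cell_donor_map(rep(paste0("d", 1:d), each = N / d))
  C <- standardize_contexts(matrix(rnorm(N * k), N, k))
  RS <- relatedness_context_covariance(map, C)
  R <- tcrossprod(map$indicator)
  Sg <- tcrossprod(C$values)
  expect_lt(max(abs(as_dense(RS) - R * Sg)), 1e-10)
  expect_lte(ncol(RS$factor), d * k)

  # all cells one donor: R is all-ones, the Hadamard identity
  map1 <- cell_donor_map(rep("d1", N))
  RS1 <- relatedness_context_covariance(map1, C)
  expect_lt(max(abs(as_dense(RS1) - Sg)), 1e-10)

  # with a nontrivial kinship
  Kd <- crossprod(matrix(rnorm(d * d), d)) / d + diag(d) * 0.5
  RSk <- relatedness_context_covariance(map, C, kinship = Kd)
  Rk <- map$indicator %*% Kd %*% t(map$indicator)
  expect_lt(max(abs(as_dense(RSk) - Rk * Sg)), 1e-10)

  expect_error(relatedness_context_covariance(map, C,
                 kinship = matrix(c(1, 2, 2, -5), 2)), "donors")
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(relatedness_context_covariance(map, C, kinship = bad),
               "positive semi-definite")
})

test_that("gxc_covariance matches diag(g) Sigma diag(g)", {
  set.seed(11)
  N <- 10; k <- 3
  C <- standardize_contexts(matrix(rnorm(N * k), N, k))
  g <- rbinom(N, 2, 0.4)
  GC <- gxc_covariance(g, C)
  expect_lt(max(abs(as_dense(GC) -
                      diag(g) %*% tcrossprod(C$values) %*% diag(g))), 1e-10)
  expect_equal(as_dense(gxc_covariance(rep(0, N), C)), matrix(0, N, N))
  expect_equal(as_dense(gxc_covariance(rep(1, N), C)),
               as_dense(context_covariance(C)))
})

test_that("solve_and_logdet agrees with dense Cholesky", {
  set.seed(12)
  # diagonal-only case
  B <- matrix(rnorm(10), 5, 2)
  sl <- solve_and_logdet(composite_cov(list(), noise = 2.5), B)
  expect_equal(sl$solve, B / 2.5)
  expect_equal(sl$logdet, 5 * log(2.5))

  # rank-1 + noise
  w <- rnorm(5)
  K1 <- composite_cov(list(lowrank_cov(matrix(w), scale = 1.7)), noise = 0.4)
  sl1 <- solve_and_logdet(K1, B)
  Kd <- 1.7 * tcrossprod(w) + diag(0.4, 5)
  expect_equal(sl1$solve, solve(Kd, B), tolerance = 1e-10)
  expect_equal(sl1$logdet, as.numeric(determinant(Kd)$modulus),
               tolerance = 1e-10)

  # determinant lemma: |I + ww'| = 1 + ||w||^2
  K2 <- composite_cov(list(lowrank_cov(matrix(w))), noise = 1)
  expect_equal(solve_and_logdet(K2, B)$logdet, log(1 + sum(w^2)),
               tolerance = 1e-12)
})

test_that("low-rank algebra matches dense on random composite instances", {
  set.seed(13)
  for (rep in 1:8) {
    N <- sample(20:200, 1); d <- sample(2:10, 1); k <- sample(1:6, 1)
    map <- cell_donor_map(sample(paste0("d", 1:d), N, replace = TRUE))
    C <- standardize_contexts(matrix(rnorm(N * k), N, k))
    v <- runif(3, 0.05, 2)
    K <- composite_cov(list(
      lowrank_cov(relatedness_context_covariance(map, C)$factor, v[1]),
      lowrank_cov(C$values, v[2])), noise = v[3])
    Kd <- as_dense(K)
    B <- matrix(rnorm(N * 2), N, 2)
    sl <- solve_and_logdet(K, B)
    expect_lt(max(abs(sl$solve - solve(Kd, B))) / max(abs(solve(Kd, B))),
              1e-8)
    expect_lt(abs(sl$logdet - as.numeric(determinant(Kd)$modulus)) /
                max(1, abs(sl$logdet)), 1e-8)
    # PSD: smallest eigenvalue of the dense realization
    ev <- eigen(Kd, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * sum(diag(Kd)))
  }
})

test_that("runtime scales linearly in N at fixed rank (smoke)", {
  set.seed(14)
  time_at <- function(N) {
    d <- 10; k <- 5
    map <- cell_donor_map(rep(paste0("d", 1:d), each = N / d))
    C <- standardize_contexts(matrix(rnorm(N * k), N, k))
    K <- composite_cov(list(
      lowrank_cov(relatedness_context_covariance(map, C)$factor, 0.3),
      lowrank_cov(C$values, 0.3)), noise = 0.4)
    y <- rnorm(N)
    # median of 5 to damp allocator noise
    median(vapply(1:5, function(i) {
      t0 <- proc.time()[["elapsed"]]
      solve_and_logdet(K, y)
      proc.time()[["elapsed"]] - t0
    }, 0))
  }
  t1 <- time_at(10000)
  t2 <- time_at(20000)
  # trend check only (generous bound: linear would give ~2.0)
  expect_lt(t2, max(2.6 * t1, t1 + 0.05))
})
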