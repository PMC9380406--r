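# Dense-matrix oracles, deliberately independent of the package's low-rank
# code paths: everything here materializes N x N matrices and uses base R
# solve()/determinant() directly.

dense_K <- function(v_rc, v_c, v_n, R, Sg) {
  v_rc * (R * Sg) + v_c * Sg + v_n * diag(nrow(Sg))
}

dense_loglik <- function(y, X, K, method = "REML") {
  n <- length(y); p <- ncol(X)
  Ki <- solve(K)
  XtKiX <- t(X) %*% Ki %*% X
  beta <- solve(XtKiX, t(X) %*% Ki %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Ki %*% r)
  ld <- as.numeric(determinant(K)$modulus)
  if (method == "REML") {
    -0.5 * ((n - p) * log(2 * pi) + ld +
              as.numeric(determinant(XtKiX)$modulus) + quad)
  } else {
    -0.5 * (n * log(2 * pi) + ld + quad)
  }
}

dense_score_test <- function(y, X, K, g, Cm) {
  Ki <- solve(K)
  P0 <- Ki - Ki %*% X %*% solve(t(X) %*% Ki %*% X, t(X) %*% Ki)
  F <- g * Cm
  Q <- 0.5 * sum((t(F) %*% P0 %*% y)^2)
  A <- 0.5 * t(F) %*% P0 %*% F
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(Q = Q, lambda = ev[ev > 1e-12 * max(ev)])
}

dense_blup <- function(y, X, K, g, Cm, s2_gxc) {
  Ki <- solve(K)
  beta <- solve(t(X) %*% Ki %*% X, t(X) %*% Ki %*% y)
  r <- y - X %*% beta
  Sg <- tcrossprod(Cm)
  drop(s2_gxc * Sg %*% diag(g) %*% Ki %*% r)
}

# Small random model instance shared by several oracle tests.
make_instance <- function(N = 60, d = 6, k = 3, seed = 1, p_extra = 1) {
  set.seed(seed)
  stopifnot(N %% d == 0)
  map <- cell_donor_map(rep(paste0("d", seq_len(d)), each = N / d))
  C <- standardize_contexts(matrix(rnorm(N * k), N, k))
  g_donor <- rbinom(d, 2, runif(1, 0.2, 0.5))
  if (max(g_donor) == min(g_donor)) g_donor[1] <- g_donor[1] + 1
  g <- g_donor[map$assignment]
  X <- cbind(intercept = 1,
             matrix(rnorm(N * p_extra), N, p_extra,
                    dimnames = list(NULL, paste0("cov", seq_len(p_extra)))),
             g = g)
  R <- tcrossprod(map$indicator)
  Sg <- tcrossprod(C$values)
  v <- c(0.3, 0.3, 0.6) * runif(3, 0.5, 1.5)
  y <- drop(chol_sample(dense_K(v[1], v[2], v[3], R, Sg))) +
    X %*% rnorm(ncol(X), 0, 0.3)
  list(N = N, d = d, k = k, map = map, C = C, g = g, g_donor = g_donor,
       X = X, R = R, Sg = Sg, y = drop(y),
       Sigma = context_covariance(C),
       RSigma = relatedness_context_covariance(map, C))
}

chol_sample <- function(K) {
  t(chol(K + diag(1e-10, nrow(K)))) %*% rnorm(nrow(K))
}

# Scaled benchmark world shared by the acceptance tests (the CI-gate
# configuration: 20 donors x 50 cells, 10 contexts).
scaled_config <- function(...) {
  sim_config(n_donors = 20, cells_per_donor = 50, k_contexts = 10, ...)
}
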