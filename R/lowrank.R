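#' Low-rank covariance term
#'
#' Factored representation of a covariance matrix K = scale * W W'. All model
#' terms (context covariance Sigma = C C', its Hadamard product with donor
#' relatedness, and the GxC term diag(g) Sigma diag(g)) admit such factors with
#' rank far below the number of cells, which is what delivers O(N) algebra:
#' the factor is never expanded to a dense N x N matrix outside test oracles.
#'
#' @param factor N x r numeric factor matrix W.
#' @param scale Nonnegative variance multiplier (default 1).
#' @param description Term label.
#' @return An object of class `lowrank_cov`.
#' @export
lowrank_cov <- function(factor, scale = 1, description = "") {
  factor <- as.matrix(factor)
  storage.mode(factor) <- "double"
  if (scale < 0) stop("scale must be nonnegative")
  structure(list(factor = factor, scale = scale, description = description),
            class = "lowrank_cov")
}

#' @export
print.lowrank_cov <- function(x, ...) {
  cat(sprintf("<lowrank_cov> %s: N=%d rank=%d scale=%g\n",
              if (nzchar(x$description)) x$description else "term",
              nrow(x$factor), ncol(x$factor), x$scale))
  invisible(x)
}

#' Composite covariance: sum of low-rank terms plus diagonal noise
#'
#' Represents K = sum_t scale_t W_t W_t' + noise * I.
#'
#' @param terms List of [lowrank_cov()] objects sharing the same N.
#' @param noise Nonnegative noise variance sigma^2_n.
#' @return An object of class `composite_cov`.
#' @export
composite_cov <- function(terms, noise) {
  if (inherits(terms, "lowrank_cov")) terms <- list(terms)
  if (noise < 0) stop("noise variance must be nonnegative")
  ns <- vapply(terms, function(t) nrow(t$factor), 0L)
  if (length(ns) && length(unique(ns)) != 1L)
    stop("terms disagree on N")
  structure(list(terms = terms, noise = noise), class = "composite_cov")
}

#' Context covariance Sigma = C C'
#'
#' @param C A standardized [context_matrix()].
#' @return A rank-k [lowrank_cov()] whose factor is C itself.
#' @export
context_covariance <- function(C) {
  if (inherits(C, "context_matrix") && !C$standardized)
    stop("context matrix must be standardized first (standardize_contexts)")
  lowrank_cov(as_context_values(C), description = "Sigma = CC'")
}

#' Relatedness-by-context covariance R (Hadamard) Sigma
#'
#' The repeat-structure term of the model: cells of the same (or related)
#' donors share context-dependent deviations, with covariance R * Sigma
#' (elementwise). With R = A A' (A the cell-level expansion of the kinship
#' Cholesky factor) and Sigma = C C', the Hadamard product factorizes as W W'
#' where the columns of W are all elementwise products a_i * c_j, giving rank
#' at most d * k.
#'
#' @param map A [cell_donor_map()].
#' @param C A standardized [context_matrix()].
#' @param kinship Optional d x d PSD donor kinship matrix (rows/cols in the
#'   order of `map$donor_ids`); identity (unrelated donors, pure repeat
#'   structure) when NULL.
#' @return A [lowrank_cov()] for R * Sigma.
#' @export
relatedness_context_covariance <- function(map, C, kinship = NULL) {
  Cm <- as_context_values(C)
  Z <- map$indicator
  d <- ncol(Z); k <- ncol(Cm)
  if (is.null(kinship)) {
    A <- Z
  } else {
    kinship <- as.matrix(kinship)
    if (nrow(kinship) != d || ncol(kinship) != d)
      stop("kinship dimension does not match number of donors")
    if (max(abs(kinship - t(kinship))) > 1e-8) stop("kinship must be symmetric")
    L <- chol_psd(kinship)   # lower triangular, kinship = L L'
    A <- Z %*% L
  }
  # transposed Khatri-Rao: columns a_i * c_j
  W <- A[, rep(seq_len(d), each = k), drop = FALSE] *
    Cm[, rep(seq_len(k), times = d), drop = FALSE]
  lowrank_cov(W, description = "R o Sigma")
}

# Lower-triangular Cholesky of a PSD matrix, with a jitter ladder for matrices
# that are only numerically PSD (near-collinear standardized contexts).
chol_psd <- function(M, jitters = 10^seq(-10, -6)) {
  r <- try(chol(M), silent = TRUE)
  if (!inherits(r, "try-error")) return(t(r))
  for (j in jitters) {
    r <- try(chol(M + diag(j, nrow(M))), silent = TRUE)
    if (!inherits(r, "try-error")) return(t(r))
  }
  stop("matrix is not positive semi-definite (Cholesky failed after jitter up to 1e-6)")
}

#' GxC covariance diag(g) Sigma diag(g)
#'
#' The marginal covariance contribution of the cell-level interaction effect
#' and the derivative of the model covariance with respect to the interaction
#' variance component -- the kernel the score test evaluates.
#'
#' @param g Cell-level genotype (a [genotype_vector()] with `expanded` set, or
#'   numeric length N).
#' @param C A standardized [context_matrix()].
#' @return A rank-k [lowrank_cov()] with factor diag(g) C.
#' @export
gxc_covariance <- function(g, C) {
  gv <- as_genotype_values(g)
  Cm <- as_context_values(C)
  if (length(gv) != nrow(Cm)) stop("genotype and context disagree on N")
  lowrank_cov(gv * Cm, description = "Dg Sigma Dg")
}

#' Solve against and log-determinant of a composite covariance
#'
#' Computes K^{-1} B and log|K| through the Woodbury identity and matrix
#' determinant lemma on the stacked scaled factor, at cost
#' O(N r_total^2 + r_total^3) instead of O(N^3).
#'
#' @param K A [composite_cov()].
#' @param B N x m matrix (or length-N vector).
#' @return List with `solve` (K^{-1} B) and `logdet` (log|K|).
#' @export
solve_and_logdet <- function(K, B) {
  B <- as.matrix(B)
  op <- cov_operator(K, N = nrow(B))
  list(solve = op$solve(B), logdet = op$logdet)
}

# Internal Woodbury operator for K = sn2 * I + U diag(s) U' with s the
# per-column scales of the stacked factor. Returns closures for K^{-1} B and
# quadratic forms plus the log-determinant.
#   K^{-1} = sn2^{-1} (I - U M^{-1} U'),  M = sn2 diag(1/s) + U'U
#   log|K| = (N - r) log sn2 + log|M| + sum log s
cov_operator <- function(K, N = NULL) {
  stopifnot(inherits(K, "composite_cov"))
  sn2 <- K$noise
  keep <- vapply(K$terms, function(t) t$scale > 0 && ncol(t$factor) > 0, TRUE)
  terms <- K$terms[keep]
  if (length(K$terms)) N <- nrow(K$terms[[1]]$factor)
  if (is.null(N)) stop("cannot infer N for a termless covariance")
  if (!length(terms)) {
    if (sn2 <= 0) stop("covariance is identically zero")
    return(list(
      solve = function(B) B / sn2,
      logdet = N * log(sn2),
      N = N, U = NULL, Minv_Ut = function(B) NULL
    ))
  }
  if (sn2 <= 0)
    stop("Woodbury route requires a positive noise component")
  U <- do.call(cbind, lapply(terms, function(t) t$factor))
  s <- unlist(lapply(terms, function(t) rep(t$scale, ncol(t$factor))))
  r <- ncol(U)
  M <- crossprod(U)
  diag(M) <- diag(M) + sn2 / s
  Mc <- try(chol(M), silent = TRUE)
  if (inherits(Mc, "try-error"))
    stop("inner Woodbury matrix is numerically singular; consider adding jitter to the noise variance")
  logdet <- (N - r) * log(sn2) + 2 * sum(log(diag(Mc))) + sum(log(s))
  solve_fun <- function(B) {
    B <- as.matrix(B)
    (B - U %*% chol_solve(Mc, crossprod(U, B))) / sn2
  }
  list(solve = solve_fun, logdet = logdet, N = N, U = U)
}

chol_solve <- function(R, B) backsolve(R, backsolve(R, B, transpose = TRUE))

#' Densify a covariance object (test/oracle use only)
#'
#' @param K A [lowrank_cov()] or [composite_cov()].
#' @return Dense N x N matrix.
#' @export
as_dense <- function(K) {
  if (inherits(K, "lowrank_cov")) return(K$scale * tcrossprod(K$factor))
  if (inherits(K, "composite_cov")) {
    N <- nrow(K$terms[[1]]$factor)
    M <- diag(K$noise, N)
    for (t in K$terms) M <- M + as_dense(t)
    return(M)
  }
  stop("not a covariance object")
}
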