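# ---- cached cross-products -------------------------------------------------
#
# All (restricted) likelihood evaluations for a fixed set of low-rank factors
# reduce, via the Woodbury identity, to an r x r problem on cached
# cross-products: with Ktilde = I + U D U' (U the stacked N x r factor, D the
# per-column variance ratios), every quadratic form a' Ktilde^{-1} b equals
# a'b - (U'a)' M^{-1} (U'b) with M = D^{-1} + U'U, and
# log|Ktilde| = log|M| + sum(log d). The N-dependent work (forming U'U, U'y,
# U'X) happens once per dataset; each optimizer step costs O(r^3).

lmm_cache <- function(y, X, factors) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < p) stop("fixed-effect design is rank-deficient")
  factors <- lapply(factors, as.matrix)
  for (W in factors) if (nrow(W) != n) stop("factor rows must equal length(y)")
  U <- if (length(factors)) do.call(cbind, factors) else matrix(0, n, 0)
  blocks <- rep(seq_along(factors),
                vapply(factors, ncol, 0L))
  list(n = n, p = p, y = y, X = X, U = U, blocks = blocks,
       n_terms = length(factors),
       UtU = crossprod(U), Uty = crossprod(U, y), UtX = crossprod(U, X),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y * y))
}

# Quadratic-form engine at variance ratios `delta` (one per term, >= 0).
# Returns GLS pieces and log|Ktilde|.
lmm_forms <- function(cache, delta) {
  keep <- which(delta[cache$blocks] > 0)
  if (length(keep)) {
    d <- delta[cache$blocks][keep]
    M <- if (length(keep) == length(cache$blocks)) cache$UtU
         else cache$UtU[keep, keep, drop = FALSE]
    diag(M) <- diag(M) + 1 / d
    Mc <- chol(M)
    logdet <- 2 * sum(log(diag(Mc))) + sum(log(d))
    Uty <- cache$Uty[keep, , drop = FALSE]
    UtX <- cache$UtX[keep, , drop = FALSE]
    a_y <- chol_solve(Mc, Uty)
    a_X <- chol_solve(Mc, UtX)
    XtKiX <- cache$XtX - crossprod(UtX, a_X)
    XtKiy <- cache$Xty - crossprod(UtX, a_y)
    ytKiy <- cache$yty - sum(Uty * a_y)
  } else {
    logdet <- 0
    XtKiX <- cache$XtX
    XtKiy <- cache$Xty
    ytKiy <- cache$yty
    Mc <- NULL; keep <- integer(0)
  }
  Rx <- chol(XtKiX)
  beta <- chol_solve(Rx, XtKiy)
  rss <- ytKiy - sum(XtKiy * beta)          # r' Ktilde^{-1} r at GLS beta
  rss <- max(rss, 1e-300)
  list(logdet = logdet, beta = beta, rss = rss, XtKiX = XtKiX, Rx = Rx,
       Mc = Mc, keep = keep)
}

# Profiled negative log-likelihood over log-deltas (overall scale s2 solved in
# closed form). REML drops the fixed-effect dimensions and adds log|X'Ki X|;
# the constant log|X'X| term is omitted (convention, stated in docs).
lmm_negll <- function(log_delta, cache, crit) {
  delta <- exp(log_delta)
  if (any(!is.finite(delta))) return(1e10)
  f <- tryCatch(lmm_forms(cache, delta), error = function(e) NULL)
  if (is.null(f)) return(1e10)
  n <- cache$n; p <- cache$p
  if (crit == "REML") {
    s2 <- f$rss / (n - p)
    # log|K| + log|X'K^-1 X| = (n-p) log s2 + log|Ktilde| + log|X'Ktilde^-1 X|
    0.5 * ((n - p) * log(2 * pi * s2) + f$logdet +
             2 * sum(log(diag(f$Rx))) + (n - p))
  } else {
    s2 <- f$rss / n
    0.5 * (n * log(2 * pi * s2) + f$logdet + n)
  }
}

# Log-likelihood at explicit variances (no profiling); sigma2_n must be > 0.
lmm_loglik_at <- function(cache, variances, sigma2_n, method) {
  if (sigma2_n <= 0) stop("noise variance must be positive")
  delta <- variances / sigma2_n
  f <- lmm_forms(cache, delta)
  n <- cache$n; p <- cache$p
  q <- f$rss / sigma2_n
  if (method == "REML") {
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2_n) + f$logdet +
              2 * sum(log(diag(f$Rx))) + q)
  } else {
    -0.5 * (n * log(2 * pi) + n * log(sigma2_n) + f$logdet + q)
  }
}

# ---- generic variance-component fit ----------------------------------------

#' Fit a Gaussian linear mixed model with low-rank covariance terms
#'
#' Maximizes the REML or ML criterion of
#' y ~ N(X beta, sum_t sigma2_t W_t W_t' + sigma2_n I)
#' over the variance components, with the overall scale profiled out
#' analytically and a multi-start Nelder-Mead search (polished by BFGS) over
#' the log variance ratios.
#'
#' @param y Numeric response (length N) or [expression_vector()].
#' @param X Fixed-effect design (N x p), intercept included by the caller.
#' @param factors List of N x r_t factor matrices, one per variance term.
#' @param method `"REML"` (default) or `"ML"`.
#' @param n_starts Number of optimizer starts (default 3: equal split,
#'   noise-dominant, structure-dominant).
#' @param term_names Names for the variance components (defaults to
#'   `term1..T`).
#' @param extra_starts Optional list of additional log-variance-ratio start
#'   vectors (used e.g. to warm-start an alternative fit from a null fit).
#' @return A `null_fit` object: `beta`, `variances` (named, noise last),
#'   `loglik`, `method`, convergence diagnostics, and cached operators used by
#'   the downstream tests (`Kinv`, `P0`, residuals).
#' @export
fit_lmm <- function(y, X, factors, method = c("REML", "ML"), n_starts = 3,
                    term_names = NULL, extra_starts = NULL) {
  method <- match.arg(method)
  yv <- as_expression_values(y)
  X <- as.matrix(X)
  Tn <- length(factors)
  if (is.null(term_names)) term_names <- paste0("term", seq_len(Tn))
  cache <- lmm_cache(yv, X, factors)
  if (cache$n <= cache$p + 3) stop("too few observations for the design")

  if (Tn == 0L) {
    f <- lmm_forms(cache, numeric(0))
    s2 <- f$rss / (if (method == "REML") cache$n - cache$p else cache$n)
    ll <- -lmm_negll(numeric(0), cache, crit = method)
    return(finish_fit(cache, numeric(0), s2, ll, method, term_names,
                      diag = list(converged = TRUE, starts = 0L,
                                  grad_norm = 0)))
  }

  starts <- list(rep(0, Tn), rep(log(0.1), Tn), rep(log(10), Tn))
  if (n_starts > 3) {
    for (i in seq_len(n_starts - 3))
      starts[[3 + i]] <- stats::rnorm(Tn, 0, 2)
  }
  starts <- if (n_starts >= 1L)
    starts[seq_len(min(n_starts, length(starts)))]
  else list()   # n_starts = 0: caller supplies all starts via extra_starts
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
  if (!length(starts)) stop("no optimizer starts")

  best <- NULL
  for (st in starts) {
    opt <- if (Tn == 1L)
      stats::optim(st, lmm_negll, cache = cache, crit = method,
                   method = "Brent", lower = -25, upper = 25,
                   control = list(reltol = 1e-12))
    else
      stats::optim(st, lmm_negll, cache = cache, crit = method,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 500))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # quasi-Newton polish from the best simplex optimum
  pol <- tryCatch(
    stats::optim(best$par, lmm_negll, cache = cache, crit = method, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 100)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value)
    best <- pol

  g <- numeric_grad(function(p) lmm_negll(p, cache, crit = method), best$par)
  if (!is.finite(best$value))
    stop("variance-component optimization failed to converge (all starts)")

  delta <- exp(best$par)
  f <- lmm_forms(cache, delta)
  s2 <- f$rss / (if (method == "REML") cache$n - cache$p else cache$n)
  finish_fit(cache, delta, s2, -best$value, method, term_names,
             diag = list(converged = sqrt(sum(g^2)) < 1e-4,
                         starts = length(starts), grad_norm = sqrt(sum(g^2))))
}

numeric_grad <- function(fn, par, h = 1e-5) {
  vapply(seq_along(par), function(i) {
    e <- rep(0, length(par)); e[i] <- h
    (fn(par + e) - fn(par - e)) / (2 * h)
  }, 0)
}

# Assemble the fitted object: variances on the raw scale, GLS beta, and the
# Woodbury operators at the optimum for downstream score tests / BLUP.
finish_fit <- function(cache, delta, s2, ll, method, term_names, diag) {
  variances <- c(delta * s2, s2)
  variances[variances < 1e-8] <- 0
  names(variances) <- c(term_names, "sigma2_n")
  f <- lmm_forms(cache, delta)
  beta <- drop(f$beta)
  names(beta) <- colnames(cache$X)
  U <- cache$U; keep <- f$keep; Mc <- f$Mc
  Uk <- if (length(keep)) U[, keep, drop = FALSE] else NULL
  Kinv <- function(B) {
    B <- as.matrix(B)
    if (is.null(Uk)) return(B / s2)
    (B - Uk %*% chol_solve(Mc, crossprod(Uk, B))) / s2
  }
  KiX <- Kinv(cache$X)
  XtKiX_raw <- crossprod(cache$X, KiX)
  RxK <- chol(XtKiX_raw)
  P0 <- function(B) {
    KB <- Kinv(B)
    KB - KiX %*% chol_solve(RxK, crossprod(cache$X, KB))
  }
  r <- cache$y - drop(cache$X %*% beta)
  structure(list(beta = beta, variances = variances, loglik = ll,
                 method = method, diagnostics = diag,
                 Kinv = Kinv, P0 = P0, residual = r,
                 Kinv_residual = drop(Kinv(r)),
                 X = cache$X, y = cache$y, n = cache$n, p = cache$p),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("<null_fit> %s loglik=%.4f n=%d\n", x$method, x$loglik, x$n))
  print(round(x$variances, 6))
  invisible(x)
}

# ---- the model-specific null fit -------------------------------------------

#' Fit the null model of the interaction test
#'
#' Fits y = X beta + u + c + e with u ~ N(0, sigma2_RC R*Sigma),
#' c ~ N(0, sigma2_C Sigma), e ~ N(0, sigma2_n I). For the interaction (GxC)
#' test the genotype enters `X` as a fixed effect; for the association test
#' the null design excludes it.
#'
#' @param y Gaussianized [expression_vector()] or numeric vector.
#' @param X Fixed-effect design with intercept (and genotype, for the
#'   interaction-test null).
#' @param Sigma [lowrank_cov()] for the context covariance (factor C).
#' @param RSigma [lowrank_cov()] for the relatedness-by-context term, or NULL
#'   to omit it (the no-relatedness model variant).
#' @param method `"REML"` (default) or `"ML"`.
#' @param n_starts Optimizer starts (default 3).
#' @return A `null_fit`; variances named `sigma2_RC`, `sigma2_C`, `sigma2_n`
#'   (no `sigma2_RC` entry when `RSigma` is NULL).
#' @export
fit_null <- function(y, X, Sigma, RSigma = NULL, method = c("REML", "ML"),
                     n_starts = 3) {
  method <- match.arg(method)
  if (inherits(y, "expression_vector") && y$state != "gaussianized")
    warning("expression vector is not gaussianized; the model assumes Gaussian phenotypes")
  if (is.null(RSigma)) {
    fit_lmm(y, X, list(Sigma$factor), method = method, n_starts = n_starts,
            term_names = "sigma2_C")
  } else {
    fit_lmm(y, X, list(RSigma$factor, Sigma$factor), method = method,
            n_starts = n_starts, term_names = c("sigma2_RC", "sigma2_C"))
  }
}

#' Construct fitted-model operators at fixed variance components
#'
#' Builds the same object as [fit_null()] but without optimizing: variance
#' components are taken as given (e.g. from a per-gene fit whose design
#' lacked the genotype) and only the fixed effects are estimated by GLS under
#' the implied covariance. This is the approximate fast mode for scanning
#' many variants per gene -- the per-pair refit remains the exact route for
#' final reporting. The result carries `approximate = TRUE` in its
#' diagnostics.
#'
#' @inheritParams fit_null
#' @param variances Named or positional (sigma2_RC, sigma2_C, sigma2_n)
#'   vector, sigma2_n > 0; typically `fit$variances` from a genotype-free
#'   null fit of the same gene.
#' @return A `null_fit` evaluated (not optimized) at `variances`.
#' @export
fit_at_variances <- function(y, X, Sigma, RSigma = NULL, variances,
                             method = c("REML", "ML")) {
  method <- match.arg(method)
  yv <- as_expression_values(y)
  factors <- if (is.null(RSigma)) list(Sigma$factor)
             else list(RSigma$factor, Sigma$factor)
  term_names <- if (is.null(RSigma)) "sigma2_C"
                else c("sigma2_RC", "sigma2_C")
  cache <- lmm_cache(yv, as.matrix(X), factors)
  v <- as.numeric(variances)
  sn2 <- v[length(v)]
  if (sn2 <= 0) stop("noise variance must be positive")
  ll <- lmm_loglik_at(cache, v[-length(v)], sn2, method)
  fit <- finish_fit(cache, v[-length(v)] / sn2, sn2, ll, method, term_names,
                    diag = list(converged = NA, starts = 0L,
                                grad_norm = NA, approximate = TRUE))
  fit
}

#' Evaluate the (restricted) log-likelihood at given variance components
#'
#' Fixed effects are profiled out by generalized least squares; the value is
#' deterministic in its inputs. Exposed mainly for diagnostics and testing.
#'
#' @inheritParams fit_null
#' @param variances Named or positional numeric vector
#'   (sigma2_RC, sigma2_C, sigma2_n), all >= 0, sigma2_n > 0.
#' @return Log-likelihood value (REML convention omits the constant |X'X|
#'   term).
#' @export
profile_loglik <- function(y, X, Sigma, RSigma = NULL, variances,
                           method = c("REML", "ML")) {
  method <- match.arg(method)
  yv <- as_expression_values(y)
  if (is.null(RSigma)) {
    cache <- lmm_cache(yv, as.matrix(X), list(Sigma$factor))
    v <- variances[seq_len(length(variances) - 1L)]
  } else {
    cache <- lmm_cache(yv, as.matrix(X), list(RSigma$factor, Sigma$factor))
    v <- variances[seq_len(length(variances) - 1L)]
  }
  sn2 <- variances[[length(variances)]]
  lmm_loglik_at(cache, as.numeric(v), sn2, method)
}
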