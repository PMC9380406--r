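# P-values for Q ~ sum_i lambda_i chisq_1 (the score test's null law).
#
# Primary route: numerical inversion of the characteristic function
# (Imhof/Davies integrand) via adaptive quadrature. Fallback: Liu's 3-moment
# noncentral-chi-square approximation, used when the inversion fails, returns
# a value outside (0, 1), or the tail is beyond quadrature resolution.

wsumchisq_cf_pval <- function(q, lambda, rel.tol = 1e-12) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    # continuous limit at u = 0: (sum(lambda) - q) / 2
    out[u == 0] <- (sum(lambda) - q) / 2
    out
  }
  res <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = rel.tol, abs.tol = 1e-14,
                     subdivisions = 10000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) return(NA_real_)
  p <- 0.5 + res$value / pi
  # trust the quadrature only if its own error estimate resolves p
  if (res$abs.error / pi > max(1e-12, 0.005 * abs(p))) return(NA_real_)
  p
}

wsumchisq_liu_pval <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + delta; sigmaX <- sqrt(2) * a
  tstar <- (q - muQ) / sigmaQ
  stats::pchisq(tstar * sigmaX + muX, df = l, ncp = delta, lower.tail = FALSE)
}

#' Tail probability of a positively weighted sum of 1-df chi-squares
#'
#' @param q Observed statistic (scalar, >= 0).
#' @param lambda Positive mixture weights.
#' @param floor_p Lower floor applied to the returned p-value (default 1e-30).
#' @return List with `pvalue` and `method` (`"davies"` for the
#'   characteristic-function inversion, `"liu_fallback"` for the moment
#'   approximation).
#' @export
wsumchisq_pval <- function(q, lambda, floor_p = 1e-30) {
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop("no positive mixture weights")
  if (length(lambda) == 1L)
    return(list(pvalue = max(stats::pchisq(q / lambda, 1, lower.tail = FALSE),
                             floor_p),
                method = "davies"))
  p <- wsumchisq_cf_pval(q, lambda)
  method <- "davies"
  if (is.na(p) || p <= 1e-12 || p > 1) {
    p <- wsumchisq_liu_pval(q, lambda)
    method <- "liu_fallback"
  }
  list(pvalue = min(max(p, floor_p), 1), method = method)
}
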