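# Posterior (BLUP) estimation of per-cell GxC allelic effects and the
# stratification utilities built on them.

#' Estimate persistent and per-cell GxC allelic effects
#'
#' Fits the alternative model (null components plus the interaction term
#' sigma2_GxC Dg Sigma Dg) by REML, warm-started from the null variance
#' components, and returns the posterior mean of the per-cell interaction
#' effect -- the BLUP of the Gaussian random effect:
#'   beta_GxC = sigma2_GxC Sigma Dg K^{-1} (y - X beta),
#' computed through the low-rank factors (never an N x N matrix). The total
#' allelic effect in cell i is beta_G + beta_GxC_i.
#'
#' @param y Gaussianized expression.
#' @param g Cell-level genotype.
#' @param X Fixed-effect design *without* the genotype; the genotype column is
#'   appended internally (named "g").
#' @param Sigma,RSigma Covariance terms as in [fit_null()].
#' @param null_fit Optional null fit (genotype in X, REML) used to warm-start
#'   the alternative variance components.
#' @param gene_id,variant_id Identifiers.
#' @return An `effect_profile`: `beta_G`, `beta_GxC` (length N), `total`,
#'   `sigma2_GxC`, `variances`, and the alternative fit.
#' @export
estimate_effects <- function(y, g, X, Sigma, RSigma, null_fit = NULL,
                             gene_id = "gene", variant_id = "variant") {
  gv <- as_genotype_values(g)
  check_testable_genotype(gv)
  X1 <- cbind(as.matrix(X), g = gv)
  F <- gv * Sigma$factor
  extra <- NULL
  if (!is.null(null_fit)) {
    v <- null_fit$variances
    sn2 <- max(v[["sigma2_n"]], 1e-6)
    extra <- list(log(pmax(c(v[["sigma2_RC"]], v[["sigma2_C"]], 1e-4 * sn2),
                           1e-8) / sn2))
  }
  fit <- fit_lmm(y, X1, list(RSigma$factor, Sigma$factor, F),
                 method = "REML",
                 term_names = c("sigma2_RC", "sigma2_C", "sigma2_GxC"),
                 extra_starts = extra)
  s2_gxc <- fit$variances[["sigma2_GxC"]]
  Cm <- Sigma$factor
  beta_gxc <- if (s2_gxc > 0) {
    drop(s2_gxc * (Cm %*% crossprod(Cm, gv * fit$Kinv_residual)))
  } else rep(0, length(gv))
  beta_G <- unname(fit$beta["g"])
  structure(list(gene_id = gene_id, variant_id = variant_id,
                 beta_G = beta_G, beta_GxC = beta_gxc,
                 total = beta_G + beta_gxc, sigma2_GxC = s2_gxc,
                 variances = fit$variances, fit = fit),
            class = "effect_profile")
}

#' @export
print.effect_profile <- function(x, ...) {
  cat(sprintf("<effect_profile> %s/%s betaG=%.4f sigma2_GxC=%.4g sd(betaGxC)=%.4f\n",
              x$gene_id, x$variant_id, x$beta_G, x$sigma2_GxC,
              stats::sd(x$beta_GxC)))
  invisible(x)
}

#' Flag genes whose allelic effect flips sign across cells
#'
#' Computes the fraction of cells whose total allelic effect
#' (beta_G + beta_GxC_i) has the opposite sign to the persistent effect
#' beta_G; a zero total counts as non-opposite. The gene is flagged when this
#' fraction reaches `threshold` (default 0.25: at least a quarter of cells on
#' the other side). `mode = "gxc"` instead compares the sign of the GxC
#' portion itself against beta_G.
#'
#' @param profile An `effect_profile` from [estimate_effects()].
#' @param threshold Flagging fraction (default 0.25).
#' @param mode `"total"` (default) or `"gxc"`.
#' @return List with `fraction` and logical `flag`.
#' @export
flag_opposite_effects <- function(profile, threshold = 0.25,
                                  mode = c("total", "gxc")) {
  mode <- match.arg(mode)
  bG <- profile$beta_G
  comp <- if (mode == "total") profile$total else profile$beta_GxC
  if (bG == 0) {
    warning("persistent effect is exactly zero; using the majority sign of the GxC portion as reference")
    ref <- sign(sum(sign(comp)))
    if (ref == 0) ref <- 1
  } else ref <- sign(bG)
  frac <- mean(sign(comp) == -ref)   # sign(0) == 0 never equals -ref
  list(fraction = frac, flag = frac >= threshold)
}

#' Stratify cells by their estimated GxC effect
#'
#' Ranks cells by |beta_GxC| (absolute mode, default) or beta_GxC (signed) and
#' returns the disjoint bottom and top floor(q*N) index sets. Ties are broken
#' by cell order, so the split is deterministic.
#'
#' @param profile An `effect_profile`.
#' @param q Quantile fraction in (0, 0.5] (default 0.3).
#' @param mode `"absolute"` or `"signed"`.
#' @return List with integer vectors `top` and `bottom`.
#' @export
stratify_by_effect <- function(profile, q = 0.3,
                               mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (q <= 0 || q > 0.5) stop("q must lie in (0, 0.5]")
  score <- if (mode == "absolute") abs(profile$beta_GxC) else profile$beta_GxC
  n <- length(score)
  m <- floor(q * n)
  if (m < 1L) stop("q too small: empty strata")
  if (max(score) == min(score))
    warning("effect profile is constant; stratification is arbitrary (but deterministic)")
  o <- order(score, seq_len(n))
  list(top = sort(o[(n - m + 1L):n]), bottom = sort(o[seq_len(m)]))
}
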