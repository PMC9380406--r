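# Synthetic data generator emulating the semi-synthetic design of the
# benchmarking experiments: Poisson counts with a log-link mean combining a
# background expression vector, a persistent genetic effect and per-context
# interaction effects, over a donor repeat structure (many cells per donor)
# and standardized continuous contexts.

#' Simulation configuration
#'
#' Defaults are the benchmark's stated conditions: 50 donors x 100 cells,
#' 500 gene-SNP pairs, total genetic variance sigma2_G = 0.025, MAF drawn
#' uniformly from [0.05, 0.5]. Fully-synthetic stand-ins for the empirical
#' backbone (chosen once; see the methods vignette): base mean count 5,
#' additive context effects on the log-mean with total variance
#' `sigma2_context` = 0.1, and donor-specific context loadings with total
#' variance `sigma2_donor_context` = 0.1 -- the latter create the
#' relatedness-by-context structure that a no-repeat-structure model ignores.
#'
#' @param n_donors,cells_per_donor,n_pairs Cohort shape and replicate count.
#' @param k_contexts Number of simulated context variables.
#' @param k_active Number of contexts carrying GxC effects (default: all).
#' @param k_tested Number of contexts used by the tests (default: all).
#' @param sigma2_G Total genetic variance (persistent + interaction).
#' @param rho_gxc Fraction of genetic variance explained by GxC, in [0, 1].
#' @param maf_range Minor-allele-frequency range for simulated genotypes.
#' @param base_mean Mean count of the background expression (log-link scale
#'   exp(b0)).
#' @param sigma2_context,sigma2_donor_context Background variances on the
#'   log-mean (shared and donor-specific context effects).
#' @param standardize_genotype Standardize dosages across donors before
#'   applying effects, so sigma2_G is comparable across MAF (default TRUE).
#' @param split_gxc_variance Divide the per-context interaction variance by
#'   `k_active` so the *total* interaction variance is sigma2_G * rho_gxc
#'   (default TRUE); FALSE gives one full-variance draw per active context.
#' @param seed Optional integer seed; when set, output is fully determined.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_donors = 50, cells_per_donor = 100, n_pairs = 500,
                       k_contexts = 10, k_active = k_contexts,
                       k_tested = k_contexts, sigma2_G = 0.025,
                       rho_gxc = 0, maf_range = c(0.05, 0.5),
                       base_mean = 5, sigma2_context = 0.1,
                       sigma2_donor_context = 0.1,
                       standardize_genotype = TRUE,
                       split_gxc_variance = TRUE, seed = NULL) {
  stopifnot(rho_gxc >= 0, rho_gxc <= 1, sigma2_G >= 0,
            k_active <= k_contexts, k_tested <= k_contexts)
  structure(list(n_donors = n_donors, cells_per_donor = cells_per_donor,
                 n_pairs = n_pairs, k_contexts = k_contexts,
                 k_active = k_active, k_tested = k_tested,
                 sigma2_G = sigma2_G, rho_gxc = rho_gxc,
                 maf_range = maf_range, base_mean = base_mean,
                 sigma2_context = sigma2_context,
                 sigma2_donor_context = sigma2_donor_context,
                 standardize_genotype = standardize_genotype,
                 split_gxc_variance = split_gxc_variance, seed = seed),
            class = "sim_config")
}

#' Simulate donor genotype dosages
#'
#' MAF ~ Uniform(maf_range); dosage ~ Binomial(2, MAF) per donor; monomorphic
#' draws are rejected and resampled so the variant is always testable.
#'
#' @param config A [sim_config()] (uses `n_donors`, `maf_range`, and `seed`
#'   when set).
#' @return A [genotype_vector()] with donor dosages named d1..d_n.
#' @export
simulate_genotypes <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- config$n_donors
  repeat {
    maf <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    dos <- stats::rbinom(d, 2, maf)
    if (max(dos) > min(dos)) break
  }
  names(dos) <- paste0("d", seq_len(d))
  genotype_vector(dos, variant_id = "sim_variant")
}

# Standardize donor dosages (population sd) and expand to cells.
standardize_expand_genotype <- function(dos, map) {
  z <- dos - mean(dos)
  z <- z / sqrt(mean(z^2))
  as.numeric(z[map$assignment])
}

#' Simulate Poisson expression counts with GxC effects
#'
#' Draws y ~ Poisson(lambda),
#' lambda = exp(y_base + sum_i (g * c_i) betaGxC_i + g betaG), with
#' betaGxC_i ~ N(0, sigma2_G * rho / k_active) for each of the `k_active`
#' leading contexts (total interaction variance sigma2_G * rho; set
#' `split_gxc_variance = FALSE` for the per-context full-variance convention)
#' and betaG ~ N(0, sigma2_G (1 - rho)).
#'
#' @param config A [sim_config()].
#' @param y_base Background log-mean per cell (length N).
#' @param g Cell-level genotype (numeric length N), already standardized if
#'   desired.
#' @param C A standardized [context_matrix()] (or matrix) with at least
#'   `k_active` columns.
#' @return A `sim_dataset` list: `counts`, and a `truth` record (`beta_G`,
#'   per-context `beta_GxC`, `active`, `lambda`) that reproduces lambda
#'   exactly.
#' @export
simulate_counts <- function(config, y_base, g, C) {
  Cm <- as_context_values(C)
  N <- length(y_base)
  stopifnot(length(g) == N, nrow(Cm) == N)
  ka <- config$k_active
  rho <- config$rho_gxc
  s2 <- config$sigma2_G
  v_int <- if (ka > 0) s2 * rho / (if (config$split_gxc_variance) ka else 1)
           else 0
  beta_gxc <- numeric(ncol(Cm))
  active <- seq_len(ka)
  if (ka > 0 && v_int > 0)
    beta_gxc[active] <- stats::rnorm(ka, 0, sqrt(v_int))
  beta_G <- if (s2 * (1 - rho) > 0) stats::rnorm(1, 0, sqrt(s2 * (1 - rho)))
            else 0
  eta <- y_base + g * beta_G
  if (any(beta_gxc != 0))
    eta <- eta + drop((g * Cm) %*% beta_gxc)
  lambda <- exp(eta)
  if (max(lambda) > 1e8)
    stop("Poisson mean overflow (lambda > 1e8); reduce effect sizes or base expression")
  structure(list(counts = stats::rpois(N, lambda),
                 truth = list(beta_G = beta_G, beta_GxC = beta_gxc,
                              active = active, lambda = lambda,
                              y_base = y_base, g = g)),
            class = "sim_dataset")
}

#' Simulate one complete gene-SNP dataset
#'
#' Generates contexts (iid standard normal, then standardized), the donor map,
#' a genotype, the background log-mean (shared plus donor-specific context
#' effects), and Poisson counts via [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `sim_dataset` with elements `counts`, `truth`, `contexts`
#'   (standardized [context_matrix()]), `map` ([cell_donor_map()]),
#'   `g` (cell-level, standardized per config), `g_donor` (raw dosages).
#' @export
simulate_dataset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  else if (!is.null(config$seed)) set.seed(config$seed)
  d <- config$n_donors; m <- config$cells_per_donor
  N <- d * m; k <- config$k_contexts
  map <- cell_donor_map(rep(paste0("d", seq_len(d)), each = m))
  C <- standardize_contexts(matrix(stats::rnorm(N * k), N, k))
  cfg_noseed <- config; cfg_noseed$seed <- NULL
  g_donor <- simulate_genotypes(cfg_noseed)
  g <- if (config$standardize_genotype)
    standardize_expand_genotype(g_donor$donor_dosages, map)
  else as.numeric(g_donor$donor_dosages[map$assignment])
  Cm <- C$values
  gamma <- stats::rnorm(k, 0, sqrt(config$sigma2_context / k))
  Gam <- matrix(stats::rnorm(d * k, 0, sqrt(config$sigma2_donor_context / k)),
                d, k)
  y_base <- log(config$base_mean) + drop(Cm %*% gamma) +
    rowSums(Cm * Gam[map$assignment, , drop = FALSE])
  out <- simulate_counts(config, y_base, g, Cm)
  out$contexts <- C
  out$map <- map
  out$g <- g
  out$g_donor <- g_donor
  out
}

# Fit the null and run the requested tests on one simulated dataset.
# Returns a named vector of p-values. Tests outside `tests` are skipped.
analyze_sim_pair <- function(dat, config, tests, n_starts = 1) {
  y <- gaussianize(dat$counts)
  kt <- config$k_tested
  Ct <- context_matrix(dat$contexts$values[, seq_len(kt), drop = FALSE],
                       standardized = TRUE)
  Sigma <- context_covariance(Ct)
  RSigma <- relatedness_context_covariance(dat$map, Ct)
  g <- dat$g
  X <- cbind(intercept = 1, g = g)
  p <- c()
  need_null <- any(c("interaction", "single_env") %in% tests)
  if (need_null) {
    fit <- fit_lmm(y, X, list(RSigma$factor, Sigma$factor), method = "REML",
                   n_starts = n_starts,
                   term_names = c("sigma2_RC", "sigma2_C"))
    if ("interaction" %in% tests)
      p["interaction"] <- interaction_score_test(y, g, X, Sigma, RSigma,
                                                 fit = fit)$pvalue
    if ("single_env" %in% tests)
      p["single_env"] <- single_env_lrt(y, g, X, Ct, Sigma, RSigma, fit = fit)
  }
  if ("multi_env" %in% tests)   # default multi-env refits by ML on its own
    p["multi_env"] <- multi_env_lrt(y, g, X, Ct, Sigma, RSigma)
  if ("no_relatedness" %in% tests) {
    fit_nr <- fit_lmm(y, X, list(Sigma$factor), method = "REML",
                      n_starts = n_starts, term_names = "sigma2_C")
    p["no_relatedness"] <-
      interaction_test_no_relatedness(y, g, X, Sigma, fit = fit_nr)$pvalue
  }
  if ("association" %in% tests)
    p["association"] <- association_lrt(y, g, cbind(intercept = rep(1, length(g))),
                                        Sigma, RSigma, fast = TRUE)$pvalue
  p
}

#' Calibration experiment: p-value uniformity under null regimes
#'
#' Simulates `n_reps` gene-SNP pairs under a null regime -- either no genetic
#' effect at all (`"no_genetic"`: sigma2_G = 0) or a persistent effect only
#' (`"persistent_only"`: rho_gxc = 0, sigma2_G as configured, default
#' 0.025) -- runs the named tests on each, and summarizes uniformity.
#'
#' @param config A [sim_config()].
#' @param tests Character subset of `c("interaction", "association",
#'   "no_relatedness", "single_env", "multi_env")`.
#' @param regime `"no_genetic"` or `"persistent_only"`.
#' @param n_reps Number of replicates (default `config$n_pairs`).
#' @param seed Integer seed for the whole experiment.
#' @param n_starts Optimizer starts per fit (default 1 for speed in large
#'   sweeps).
#' @return List with `pvalues` (n_reps x tests matrix), and per-test `summary`
#'   (KS statistic and p-value against Uniform(0,1), empirical type-I error
#'   at alpha = 0.05 and 0.01).
#' @export
run_calibration <- function(config, tests = "interaction",
                            regime = c("no_genetic", "persistent_only"),
                            n_reps = config$n_pairs, seed = 1, n_starts = 1) {
  regime <- match.arg(regime)
  cfg <- config
  if (regime == "no_genetic") cfg$sigma2_G <- 0 else cfg$rho_gxc <- 0
  if (n_reps == 0)
    return(list(pvalues = matrix(numeric(0), 0, length(tests),
                                 dimnames = list(NULL, tests)),
                summary = NULL))
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_reps)
  P <- matrix(NA_real_, n_reps, length(tests), dimnames = list(NULL, tests))
  for (i in seq_len(n_reps)) {
    dat <- simulate_dataset(cfg, seed = seeds[i])
    P[i, ] <- analyze_sim_pair(dat, cfg, tests, n_starts = n_starts)[tests]
  }
  summary <- do.call(rbind, lapply(tests, function(t) {
    pv <- P[, t]
    ks <- stats::ks.test(pv, "punif")
    data.frame(test = t, ks_stat = unname(ks$statistic),
               ks_pvalue = ks$p.value,
               typeI_05 = mean(pv < 0.05), typeI_01 = mean(pv < 0.01),
               n = length(pv))
  }))
  list(pvalues = P, summary = summary)
}

#' Power experiment over a simulation grid
#'
#' For each grid row (columns among `rho_gxc`, `k_active`, `k_tested`,
#' overriding the config), simulates `n_reps` pairs with GxC effects and
#' computes each test's power at level `alpha` with binomial standard errors.
#'
#' @param config Base [sim_config()].
#' @param grid Data frame of grid points.
#' @param tests Tests to run (as in [run_calibration()]).
#' @param n_reps Replicates per grid point.
#' @param alpha Significance level (default 0.01).
#' @param seed Integer seed.
#' @param n_starts Optimizer starts per fit.
#' @return Data frame: grid columns, test, power, se, n.
#' @export
run_power <- function(config, grid, tests = "interaction",
                      n_reps = config$n_pairs, alpha = 0.01, seed = 1,
                      n_starts = 1) {
  out <- list()
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    for (col in names(grid)) cfg[[col]] <- grid[[col]][r]
    if (!"k_tested" %in% names(grid)) cfg$k_tested <- cfg$k_contexts
    set.seed(seed + r)
    seeds <- sample.int(2^31 - 2, n_reps)
    P <- matrix(NA_real_, n_reps, length(tests),
                dimnames = list(NULL, tests))
    for (i in seq_len(n_reps)) {
      dat <- simulate_dataset(cfg, seed = seeds[i])
      P[i, ] <- analyze_sim_pair(dat, cfg, tests, n_starts = n_starts)[tests]
    }
    pow <- colMeans(P < alpha)
    out[[r]] <- data.frame(grid[r, , drop = FALSE], test = tests,
                           power = unname(pow),
                           se = sqrt(unname(pow) * (1 - unname(pow)) / n_reps),
                           n = n_reps, row.names = NULL)
  }
  do.call(rbind, out)
}
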