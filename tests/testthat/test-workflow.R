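test_that("correct_multiple_testing matches textbook Bonferroni + BH on a fixture", {
  res <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3", "g4", "g5"),
    variant_id = paste0("v", 1:8),
    pvalue = c(0.01, 0.5, 0.001, 0.04, 0.9, 0.2, 1, 0.03))
  expect_warning(cr <- correct_multiple_testing(res, fdr = 0.2,
                                                method = "storey"),
                 "fewer than 100")
  g <- cr$genes[order(cr$genes$gene_id), ]
  expect_equal(g$p_gene, pmin(1, c(0.01 * 2, 0.001, 0.04 * 3, 1, 0.03)))
  expect_equal(g$qvalue, p.adjust(g$p_gene, "BH"))
  expect_equal(g$lead_variant[g$gene_id == "g1"], "v1")
  expect_identical(cr$method, "bh")

  expect_error(correct_multiple_testing(
    data.frame(gene_id = "g", variant_id = "v", pvalue = 0)), "0, 1")
})

test_that("all p = 1 yields zero significant genes", {
  res <- data.frame(gene_id = paste0("g", 1:10), variant_id = paste0("v", 1:10),
                    pvalue = rep(1, 10))
  cr <- correct_multiple_testing(res, method = "bh")
  expect_false(any(cr$genes$significant))
})

test_that("Storey and BH broadly agree on uniform-plus-signal p-values", {
  set.seed(70)
  m <- 1000
  p <- c(runif(900), rbeta(100, 0.05, 1))
  res <- data.frame(gene_id = paste0("g", 1:m), variant_id = "v",
                    pvalue = pmax(p, 1e-12))
  crs <- correct_multiple_testing(res, fdr = 0.05, method = "storey")
  crb <- correct_multiple_testing(res, fdr = 0.05, method = "bh")
  ns <- sum(crs$genes$significant); nb <- sum(crb$genes$significant)
  expect_gt(ns, 0)
  expect_lt(abs(ns - nb) / max(nb, 1), 0.25)
  # q-values monotone in gene-level p
  o <- order(crs$genes$p_gene)
  expect_true(all(diff(crs$genes$qvalue[o]) >= -1e-12))
  # pi0 near its true value under mostly-null p-values
  expect_gt(sum(crs$genes$significant), 0.5 * sum(crb$genes$significant))
})

make_scan_bundle <- function(seed = 71, n_genes = 12, n_signal = 4) {
  set.seed(seed)
  d <- 30; m <- 10; N <- d * m
  map <- cell_donor_map(rep(paste0("d", 1:d), each = m))
  C <- standardize_contexts(matrix(rnorm(N * 2), N, 2))
  n_var <- n_genes * 2
  dos <- matrix(rbinom(n_var * d, 2, 0.3), n_var, d,
                dimnames = list(paste0("v", 1:n_var), paste0("d", 1:d)))
  variants <- data.frame(variant_id = rownames(dos), chrom = "1",
                         pos = seq(1000, by = 50000, length.out = n_var))
  genes <- data.frame(gene_id = paste0("g", 1:n_genes), chrom = "1",
                      start = seq(1000, by = 100000, length.out = n_genes),
                      end = seq(21000, by = 100000, length.out = n_genes))
  expr <- matrix(0, n_genes, N, dimnames = list(genes$gene_id, NULL))
  for (i in 1:n_genes) {
    g <- dos[2 * i - 1, ][map$assignment]  # the variant at the gene start
    beta <- if (i <= n_signal) 0.6 else 0
    expr[i, ] <- rpois(N, exp(log(5) + beta * (g - mean(g)) + 0.1 * rnorm(N)))
  }
  list(expression = expr, genes = genes, dosages = dos, variants = variants,
       contexts = C, map = map, n_signal = n_signal)
}

test_that("two_stage_scan recovers persistent effects and forwards lead pairs", {
  b <- make_scan_bundle()
  sc <- suppressWarnings(two_stage_scan(b, cis_window = 30000,
                                        discovery_fdr = 0.2))
  # each gene window covers its own variants only: at most 2 pairs per gene
  expect_true(all(table(sc$association$gene_id) <= 2))
  hits <- sc$pairs$gene_id
  expect_gte(sum(paste0("g", seq_len(b$n_signal)) %in% hits),
             b$n_signal - 1)
  # lead variant of a signal gene is its causal variant
  g1 <- sc$pairs[sc$pairs$gene_id == "g1", ]
  if (nrow(g1)) expect_equal(g1$variant_id, "v1")
  expect_true(!is.null(sc$interaction))

  # discovery_fdr = 0 forwards nothing
  sc0 <- suppressWarnings(two_stage_scan(b, cis_window = 30000,
                                         discovery_fdr = 0))
  expect_equal(nrow(sc0$pairs), 0)
})

test_that("pseudobulk_confirmation recovers opposite slopes for flipped strata", {
  set.seed(72)
  d <- 30; m <- 20; N <- d * m
  map <- cell_donor_map(rep(paste0("d", 1:d), each = m))
  g_donor <- rbinom(d, 2, 0.4); names(g_donor) <- map$donor_ids
  g <- g_donor[map$assignment]
  # alternate cells within donors: positive vs negative allelic effect, so
  # every donor contributes to both strata
  half <- rep(c(1, -1), N / 2)
  expr <- rnorm(N, 0, 0.3) + half * 0.8 * g
  sets <- list(top = which(half == 1), bottom = which(half == -1))
  pb <- pseudobulk_confirmation(expr, sets, g_donor, map)
  expect_equal(nrow(pb), 2)
  expect_gt(pb$slope[pb$set == "top"], 0.5)
  expect_lt(pb$slope[pb$set == "bottom"], -0.5)
  expect_true(all(pb$pvalue < 0.01))

  # identical sets give identical slopes
  pb2 <- pseudobulk_confirmation(expr, list(a = sets$top, b = sets$top),
                                 g_donor, map)
  expect_equal(pb2$slope[1], pb2$slope[2])

  # a donor absent from a set is dropped with a log entry
  sets3 <- list(part = which(map$assignment > 1 & half == 1))
  expect_message(pb3 <- pseudobulk_confirmation(expr, sets3, g_donor, map),
                 "dropped")
  expect_equal(pb3$n_donors, d - 1)
})

test_that("end-to-end determinism: identical seeds give identical result tables", {
  cfg <- scaled_config(rho_gxc = 0.5)
  run_once <- function() {
    dat <- simulate_dataset(cfg, seed = 73)
    y <- gaussianize(dat$counts)
    Sigma <- context_covariance(dat$contexts)
    RSigma <- relatedness_context_covariance(dat$map, dat$contexts)
    X <- cbind(1, g = dat$g)
    r <- interaction_score_test(y, dat$g, X, Sigma, RSigma)
    f <- tempfile(fileext = ".tsv")
    write_results(list(r), f)
    readLines(f)
  }
  expect_identical(run_once(), run_once())
})
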