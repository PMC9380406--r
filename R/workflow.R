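# Orchestration: multiple-testing correction (gene-level Bonferroni followed
# by across-gene Storey FDR), the two-stage association-then-interaction
# discovery scan, and pseudo-bulk confirmation of effect strata.

#' Storey q-values
#'
#' pi0 is estimated on the lambda grid 0.05, 0.10, ..., 0.95 via
#' mean(p > lambda) / (1 - lambda), smoothed with a cubic spline and evaluated
#' at the largest lambda; q-values are the usual step-up cumulative minima
#' scaled by pi0.
#'
#' @param p P-values.
#' @return Numeric q-values in (0, 1].
#' @export
storey_qvalue <- function(p) {
  m <- length(p)
  lam <- seq(0.05, 0.95, by = 0.05)
  pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), 0)
  sp <- stats::smooth.spline(lam, pi0l, df = 3)
  pi0 <- min(max(stats::predict(sp, x = max(lam))$y, 1 / m), 1)
  o <- order(p, decreasing = TRUE)
  q <- pmin(pi0 * m * p[o] / rank(p, ties.method = "max")[o], 1)
  q <- cummin(q)
  q[order(o)]
}

#' Gene-level Bonferroni plus across-gene FDR correction
#'
#' Within each gene the minimum p-value across its tested variants is
#' Bonferroni-adjusted (min p times number of tests, capped at 1); across
#' genes, q-values are computed with Storey's method (or Benjamini-Hochberg
#' as fallback/by request). Storey's pi0 estimate needs a reasonable number
#' of genes; below 100 genes the function falls back to BH with a warning.
#'
#' @param results Data frame with columns `gene_id`, `variant_id`, `pvalue`.
#' @param fdr Significance threshold on the q-values (default 0.05).
#' @param method `"storey"` (default) or `"bh"`.
#' @return List with `pairs` (input plus gene-level columns), `genes` (one row
#'   per gene: `p_gene`, `qvalue`, `significant`, lead variant), `method`.
#' @export
correct_multiple_testing <- function(results, fdr = 0.05,
                                     method = c("storey", "bh")) {
  method <- match.arg(method)
  stopifnot(all(c("gene_id", "variant_id", "pvalue") %in% names(results)))
  if (any(results$pvalue <= 0 | results$pvalue > 1))
    stop("p-values must lie in (0, 1]")
  sp <- split(seq_len(nrow(results)), results$gene_id)
  genes <- do.call(rbind, lapply(names(sp), function(gid) {
    idx <- sp[[gid]]
    j <- idx[which.min(results$pvalue[idx])]
    data.frame(gene_id = gid, n_tests = length(idx),
               p_min = results$pvalue[j],
               p_gene = min(1, results$pvalue[j] * length(idx)),
               lead_variant = results$variant_id[j],
               stringsAsFactors = FALSE)
  }))
  if (method == "storey" && nrow(genes) < 100) {
    warning("fewer than 100 genes; falling back to Benjamini-Hochberg")
    method <- "bh"
  }
  genes$qvalue <- if (method == "storey") storey_qvalue(genes$p_gene)
                  else stats::p.adjust(genes$p_gene, "BH")
  genes$significant <- genes$qvalue < fdr
  pairs <- results
  mi <- match(pairs$gene_id, genes$gene_id)
  pairs$p_gene <- genes$p_gene[mi]
  pairs$qvalue_gene <- genes$qvalue[mi]
  list(pairs = pairs, genes = genes, method = method, fdr = fdr)
}

#' Two-stage discovery scan: association then interaction
#'
#' Stage 1 runs the association test for every gene against its cis variants
#' (within `cis_window` bp flanking the gene body, MAF > `maf_min`), corrects
#' at the lenient discovery FDR (default 20%), and forwards the lead variant
#' of each significant gene. Stage 2 runs the interaction score test on the
#' forwarded pairs.
#'
#' @param bundle List with: `expression` (gene x cell matrix of counts or
#'   log-normalized values), `genes` (data.frame gene_id, chrom, start, end;
#'   BED-style 0-based half-open), `dosages` (variant x donor matrix),
#'   `variants` (data.frame variant_id, chrom, pos), `contexts` (standardized
#'   [context_matrix()]), `map` ([cell_donor_map()]).
#' @param cis_window Window in bp flanking the gene body (default 1e5).
#' @param maf_min Minimum MAF (default 0.05).
#' @param discovery_fdr Stage-1 FDR (default 0.20).
#' @param run_interaction Run stage 2 on the forwarded pairs (default TRUE).
#' @param fdr Stage-2 significance FDR (default 0.05).
#' @return List with `pairs` (forwarded PairList data.frame), `association`
#'   (all stage-1 results), `discovery` (stage-1 correction), and when stage 2
#'   ran, `interaction` results and their `correction`.
#' @export
two_stage_scan <- function(bundle, cis_window = 1e5, maf_min = 0.05,
                           discovery_fdr = 0.20, run_interaction = TRUE,
                           fdr = 0.05) {
  Sigma <- context_covariance(bundle$contexts)
  RSigma <- relatedness_context_covariance(bundle$map, bundle$contexts)
  X0 <- cbind(intercept = rep(1, length(bundle$map$assignment)))
  dos <- as.matrix(bundle$dosages)
  maf <- pmin(rowMeans(dos, na.rm = TRUE) / 2,
              1 - rowMeans(dos, na.rm = TRUE) / 2)
  assoc <- list()
  for (gi in seq_len(nrow(bundle$genes))) {
    gene <- bundle$genes[gi, ]
    inwin <- bundle$variants$chrom == gene$chrom &
      bundle$variants$pos >= gene$start - cis_window &
      bundle$variants$pos <= gene$end + cis_window &
      maf > maf_min
    if (!any(inwin)) {
      message(sprintf("gene %s: no cis variants in window; skipped",
                      gene$gene_id))
      next
    }
    y <- gaussianize(bundle$expression[gene$gene_id, ])
    fit0 <- fit_null(y, X0, Sigma, RSigma, method = "ML")
    for (vi in which(inwin)) {
      g <- expand_genotype(genotype_vector(dos[vi, ],
                                           bundle$variants$variant_id[vi]),
                           bundle$map, missing = "drop")
      if (!all(attr(g, "keep_cells"))) next  # keep stage 1 simple: skip
      r <- tryCatch(
        association_lrt(y, g, X0, Sigma, RSigma, fast = TRUE, fit0 = fit0,
                        gene_id = gene$gene_id,
                        variant_id = bundle$variants$variant_id[vi]),
        error = function(e) NULL)
      if (!is.null(r)) assoc[[length(assoc) + 1L]] <- r
    }
  }
  assoc_df <- do.call(rbind, lapply(assoc, function(r)
    data.frame(gene_id = r$gene_id, variant_id = r$variant_id,
               beta_G = r$beta_G, pvalue = r$pvalue,
               stringsAsFactors = FALSE)))
  if (is.null(assoc_df) || nrow(assoc_df) == 0 || discovery_fdr <= 0)
    return(list(pairs = data.frame(gene_id = character(0),
                                   variant_id = character(0)),
                association = assoc_df, discovery = NULL))
  disc <- correct_multiple_testing(assoc_df, fdr = discovery_fdr)
  hits <- disc$genes[disc$genes$significant, , drop = FALSE]
  pairs <- data.frame(gene_id = hits$gene_id, variant_id = hits$lead_variant,
                      stringsAsFactors = FALSE)
  out <- list(pairs = pairs, association = assoc_df, discovery = disc)
  if (run_interaction && nrow(pairs) > 0) {
    inter <- lapply(seq_len(nrow(pairs)), function(i) {
      gene_id <- pairs$gene_id[i]; variant_id <- pairs$variant_id[i]
      y <- gaussianize(bundle$expression[gene_id, ])
      vi <- match(variant_id, bundle$variants$variant_id)
      g <- expand_genotype(genotype_vector(dos[vi, ], variant_id),
                           bundle$map, missing = "drop")
      X <- cbind(X0, g = as_genotype_values(g))
      interaction_score_test(y, g, X, Sigma, RSigma,
                             gene_id = gene_id, variant_id = variant_id)
    })
    inter_df <- do.call(rbind, lapply(inter, function(r)
      data.frame(gene_id = r$gene_id, variant_id = r$variant_id,
                 statistic = r$statistic, pvalue = r$pvalue,
                 flags = r$method_flags, stringsAsFactors = FALSE)))
    out$interaction <- inter_df
    out$correction <- correct_multiple_testing(inter_df, fdr = fdr,
                                               method = "bh")
  }
  out
}

#' Pseudo-bulk confirmation of stratified effects
#'
#' For each cell set (e.g. top/bottom strata from [stratify_by_effect()]),
#' aggregates expression to donor means over the set's cells and regresses
#' the donor means on the donor dosages -- conventional pseudo-bulk eQTL
#' mapping restricted to each stratum. Opposite-sign slopes across strata
#' confirm a sign-flipping GxC effect.
#'
#' @param expr Per-cell expression values for one gene (length N).
#' @param cell_sets Named list of integer cell-index vectors.
#' @param g_donor Named donor dosage vector.
#' @param map A [cell_donor_map()].
#' @return Data frame: set, slope, se, pvalue, n_donors.
#' @export
pseudobulk_confirmation <- function(expr, cell_sets, g_donor, map) {
  expr <- as_expression_values(expr)
  do.call(rbind, lapply(names(cell_sets), function(nm) {
    idx <- cell_sets[[nm]]
    don <- map$assignment[idx]
    mu <- tapply(expr[idx], don, mean)
    ids <- map$donor_ids[as.integer(names(mu))]
    dropped <- setdiff(map$donor_ids, ids)
    if (length(dropped))
      message(sprintf("set %s: donor(s) absent, dropped: %s", nm,
                      paste(dropped, collapse = ", ")))
    dose <- as.numeric(g_donor[ids])
    fit <- summary(stats::lm(as.numeric(mu) ~ dose))
    co <- stats::coef(fit)["dose", ]
    data.frame(set = nm, slope = co[["Estimate"]],
               se = co[["Std. Error"]], pvalue = co[["Pr(>|t|)"]],
               n_donors = length(ids), row.names = NULL)
  }))
}
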