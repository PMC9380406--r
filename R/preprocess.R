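#' Per-gene expression vector
#'
#' Lightweight container for a single gene's expression across cells, tracking
#' its normalization state. The mixed model assumes approximately Gaussian
#' phenotypes, so vectors are typically passed through [gaussianize()] before
#' model fitting.
#'
#' @param values Numeric vector, one value per cell.
#' @param state One of `"raw_counts"`, `"log_normalized"`, `"gaussianized"`.
#' @param gene_id Gene identifier.
#' @return An object of class `expression_vector`.
#' @export
expression_vector <- function(values, state = c("raw_counts", "log_normalized",
                                                "gaussianized"),
                              gene_id = "gene") {
  state <- match.arg(state)
  values <- as.numeric(values)
  if (anyNA(values)) stop("expression values contain NA")
  structure(list(values = values, state = state, gene_id = gene_id),
            class = "expression_vector")
}

#' @export
print.expression_vector <- function(x, ...) {
  cat(sprintf("<expression_vector> gene=%s n=%d state=%s\n",
              x$gene_id, length(x$values), x$state))
  invisible(x)
}

as_expression_values <- function(y) {
  if (inherits(y, "expression_vector")) y$values else as.numeric(y)
}

#' Rank-based inverse-normal transform of an expression vector
#'
#' Quantile-normalizes a per-gene expression vector to a standard normal shape:
#' value_i = qnorm((rank_i - 0.5) / N), with ties ranked by their average. The
#' offset 0.5 keeps the transform symmetric and finite. Rank order is preserved.
#'
#' @param y An [expression_vector()] (state `raw_counts` or `log_normalized`)
#'   or a plain numeric vector.
#' @return An `expression_vector` with state `"gaussianized"`.
#' @export
gaussianize <- function(y) {
  gene_id <- if (inherits(y, "expression_vector")) y$gene_id else "gene"
  if (inherits(y, "expression_vector") && y$state == "gaussianized")
    stop("expression vector is already gaussianized")
  v <- as_expression_values(y)
  n <- length(v)
  if (n < 3L) stop("need at least 3 cells to gaussianize")
  if (max(v) == min(v))
    stop("degenerate input: expression vector is constant, no ranks exist")
  r <- rank(v, ties.method = "average")
  expression_vector(stats::qnorm((r - 0.5) / n), state = "gaussianized",
                    gene_id = gene_id)
}

#' Cellular context matrix
#'
#' An N x k matrix of per-cell context variables (e.g. externally computed
#' factor-analysis factors or principal components) defining the context
#' covariance Sigma = C C'. Columns should be standardized before use.
#'
#' @param values Numeric N x k matrix.
#' @param standardized Logical; whether columns are mean 0 / sd 1.
#' @param labels Optional column labels.
#' @return An object of class `context_matrix`.
#' @export
context_matrix <- function(values, standardized = FALSE, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- paste0("context", seq_len(ncol(values)))
  }
  colnames(values) <- labels
  structure(list(values = values, standardized = standardized, labels = labels),
            class = "context_matrix")
}

#' @export
print.context_matrix <- function(x, ...) {
  cat(sprintf("<context_matrix> %d cells x %d contexts, standardized=%s\n",
              nrow(x$values), ncol(x$values), x$standardized))
  invisible(x)
}

as_context_values <- function(C) {
  if (inherits(C, "context_matrix")) C$values else as.matrix(C)
}

#' Standardize context columns to mean 0, standard deviation 1
#'
#' Uses the population convention (divide by sqrt(mean of squared deviations)),
#' so a two-point column c(1, 3) maps to c(-1, 1).
#'
#' @param C A [context_matrix()] or plain matrix.
#' @return A standardized `context_matrix`.
#' @export
standardize_contexts <- function(C) {
  labels <- if (inherits(C, "context_matrix")) C$labels else NULL
  M <- as_context_values(C)
  if (is.null(labels)) labels <- colnames(M)
  ctr <- sweep(M, 2L, colMeans(M))
  sds <- sqrt(colMeans(ctr^2))
  bad <- which(sds == 0)
  if (length(bad))
    stop(sprintf("constant context column(s): %s",
                 paste(if (is.null(labels)) bad else labels[bad],
                       collapse = ", ")))
  context_matrix(sweep(ctr, 2L, sds, "/"), standardized = TRUE, labels = labels)
}

#' One-hot encode discrete cell labels as a context matrix
#'
#' Each distinct label becomes one 0/1 column, exactly one 1 per cell; the
#' resulting Sigma = C C' (unstandardized) is the block-diagonal same-group
#' indicator covariance. By default the columns are then standardized, matching
#' the treatment of continuous contexts.
#'
#' @param labels Per-cell category vector (>= 2 distinct values).
#' @param standardize Standardize the indicator columns afterwards (default TRUE).
#' @return A `context_matrix`.
#' @export
one_hot_contexts <- function(labels, standardize = TRUE) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2L)
    stop("need at least 2 distinct labels: a single level is confounded with the intercept")
  M <- outer(labels, lev, "==") * 1.0
  colnames(M) <- lev
  C <- context_matrix(M, standardized = FALSE, labels = lev)
  if (standardize) standardize_contexts(C) else C
}

#' Cell-to-donor assignment
#'
#' @param donors Per-cell donor identifier (length N).
#' @return An object of class `cell_donor_map` with the 0/1 indicator matrix
#'   `indicator` (N x d, one 1 per row), integer `assignment`, and donor ids.
#' @export
cell_donor_map <- function(donors) {
  donors <- as.character(donors)
  ids <- unique(donors)
  idx <- match(donors, ids)
  Z <- matrix(0, length(donors), length(ids), dimnames = list(NULL, ids))
  Z[cbind(seq_along(idx), idx)] <- 1
  structure(list(assignment = idx, donor_ids = ids, n_donors = length(ids),
                 indicator = Z),
            class = "cell_donor_map")
}

#' @export
print.cell_donor_map <- function(x, ...) {
  cat(sprintf("<cell_donor_map> %d cells, %d donors\n",
              length(x$assignment), x$n_donors))
  invisible(x)
}

#' Donor genotype dosages and their per-cell expansion
#'
#' @param donor_dosages Named numeric vector of dosages in [0, 2], one per donor.
#' @param variant_id Variant identifier.
#' @return An object of class `genotype_vector` (unexpanded; see
#'   [expand_genotype()]).
#' @export
genotype_vector <- function(donor_dosages, variant_id = "variant") {
  dd <- as.numeric(donor_dosages)
  names(dd) <- names(donor_dosages)
  ok <- !is.na(dd)
  if (any(dd[ok] < 0 | dd[ok] > 2)) stop("dosages must lie in [0, 2]")
  p <- mean(dd[ok]) / 2
  structure(list(donor_dosages = dd, expanded = NULL,
                 variant_id = variant_id, maf = min(p, 1 - p)),
            class = "genotype_vector")
}

#' Expand donor dosages to the cell level
#'
#' Every cell receives its donor's dosage. Donors with missing (NA) dosage are
#' handled per `missing`: `"error"` refuses, `"drop"` returns a cell mask so
#' the caller can subset y, C and the map consistently, `"mean"` imputes the
#' mean dosage across typed donors.
#'
#' @param g A [genotype_vector()] with `donor_dosages` named by donor id, or a
#'   plain named numeric vector.
#' @param map A [cell_donor_map()].
#' @param missing One of `"error"`, `"drop"`, `"mean"`.
#' @return A `genotype_vector` with `expanded` filled in and a logical
#'   `keep_cells` attribute (all TRUE unless `missing = "drop"` dropped cells;
#'   `expanded` is already subset to the kept cells).
#' @export
expand_genotype <- function(g, map, missing = c("error", "drop", "mean")) {
  missing <- match.arg(missing)
  if (!inherits(g, "genotype_vector")) g <- genotype_vector(g)
  dd <- g$donor_dosages
  if (is.null(names(dd))) {
    if (length(dd) != map$n_donors)
      stop("unnamed dosage vector must have one entry per donor in the map")
    names(dd) <- map$donor_ids
  }
  miss_ids <- setdiff(map$donor_ids, names(dd))
  per_donor <- dd[map$donor_ids]
  names(per_donor) <- map$donor_ids
  is_miss <- is.na(per_donor)
  if (any(is_miss)) {
    bad <- map$donor_ids[is_miss]
    if (missing == "error")
      stop(sprintf("donor(s) without genotype dosage: %s (set missing='drop' or 'mean')",
                   paste(bad, collapse = ", ")))
    if (missing == "mean")
      per_donor[is_miss] <- mean(per_donor, na.rm = TRUE)
  }
  keep <- rep(TRUE, length(map$assignment))
  if (missing == "drop" && any(is_miss))
    keep <- unname(!is_miss[map$assignment])
  expanded <- as.numeric(per_donor[map$assignment])[keep]
  out <- g
  out$expanded <- expanded
  attr(out, "keep_cells") <- keep
  out
}

as_genotype_values <- function(g) {
  if (inherits(g, "genotype_vector")) {
    if (is.null(g$expanded)) stop("genotype not expanded to cells; call expand_genotype()")
    g$expanded
  } else as.numeric(g)
}

#' Aggregate raw counts into pseudocells
#'
#' Sums raw counts of transcriptionally related cells (cluster labels computed
#' externally, e.g. by graph clustering on an integrated embedding) into
#' pseudocells. Clusters must be nested within donors: a cluster spanning two
#' donors would break the donor repeat-structure expansion downstream.
#' Pseudocell profiles then go through the same normalize / log / gaussianize
#' chain as cells.
#'
#' @param counts Gene x cell matrix of raw counts.
#' @param cluster_labels Per-cell cluster label (length ncol(counts)).
#' @param donors Per-cell donor id (same length); used to validate nesting and
#'   to emit the pseudocell-to-donor map.
#' @return List with `counts` (gene x pseudocell sums), `donor_map` (a
#'   [cell_donor_map()] over pseudocells), and `sizes` (cells per pseudocell).
#' @export
aggregate_pseudocells <- function(counts, cluster_labels, donors) {
  counts <- as.matrix(counts)
  cluster_labels <- as.character(cluster_labels)
  donors <- as.character(donors)
  stopifnot(ncol(counts) == length(cluster_labels),
            length(cluster_labels) == length(donors))
  span <- tapply(donors, cluster_labels, function(d) length(unique(d)))
  if (any(span > 1L))
    stop(sprintf("cluster(s) span multiple donors: %s",
                 paste(names(span)[span > 1L], collapse = ", ")))
  cl <- factor(cluster_labels, levels = unique(cluster_labels))
  agg <- t(rowsum(t(counts), cl))
  sizes <- as.integer(table(cl)[levels(cl)])
  names(sizes) <- levels(cl)
  pc_donor <- vapply(levels(cl), function(l) donors[match(l, cluster_labels)], "")
  list(counts = agg, donor_map = cell_donor_map(pc_donor), sizes = sizes)
}
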