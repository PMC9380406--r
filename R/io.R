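# Readers for the plain-text interchange formats: dense expression TSV/CSV or
# MatrixMarket triplets, dosage tables, minimal VCF, and the per-cell tables
# (contexts, donor map, cluster labels, kinship). Cell identifiers must match
# across files exactly (case-sensitive).

#' Read a gene x cell expression matrix
#'
#' Either a dense TSV/CSV (genes in rows, first column gene ids, header =
#' cell ids) or a MatrixMarket `.mtx` triplet file with companion row (gene)
#' and column (cell) id files, one id per line.
#'
#' @param path Matrix file (.tsv/.csv/.mtx by extension).
#' @param rows,cols Id files, required for `.mtx` input.
#' @return Dense numeric matrix with dimnames.
#' @export
read_expression <- function(path, rows = NULL, cols = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(rows) || is.null(cols))
      stop("mtx input needs row (gene) and column (cell) id files")
    M <- as.matrix(Matrix::readMM(path))
    rownames(M) <- readLines(rows)
    colnames(M) <- readLines(cols)
    return(M)
  }
  sep <- if (ext == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Read a variant x donor dosage table
#'
#' TSV with variant ids in the first column, donor ids in the header, dosages
#' in [0, 2]; "NA" marks missing genotypes.
#'
#' @param path TSV file.
#' @return Numeric matrix (variants x donors).
#' @export
read_dosages <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, na.strings = c("NA", "."))
  M <- as.matrix(df)
  ok <- !is.na(M)
  if (any(M[ok] < 0 | M[ok] > 2)) stop("dosages must lie in [0, 2]")
  M
}

#' Read dosages from a minimal diploid VCF
#'
#' Uses VariantAnnotation to parse the VCF and converts the GT field to
#' alternate-allele dosage (0/1/2); missing genotypes ("./.") become NA.
#'
#' @param path Uncompressed or bgzipped VCF.
#' @return Numeric matrix (variants x donors) with variant ids
#'   `chrom:pos_ref_alt` when ID is missing.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required for VCF input")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dose <- function(x) {
    a <- strsplit(x, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a != "0")
  }
  M <- apply(gt, c(1, 2), dose)
  storage.mode(M) <- "double"
  M
}

#' Read a per-cell table keyed by cell id
#'
#' Generic TSV reader for contexts, donor assignments and cluster labels:
#' header row, first column `cell_id`. Rows are reordered to `cell_ids` when
#' given; unmatched cells are an error (ids are case-sensitive).
#'
#' @param path TSV file.
#' @param cell_ids Optional cell id vector fixing the row order.
#' @return Data frame without the id column; ids as rownames.
#' @export
read_cell_table <- function(path, cell_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1]]
  df <- df[-1]
  if (!is.null(cell_ids)) {
    mi <- match(cell_ids, rownames(df))
    if (anyNA(mi))
      stop(sprintf("cell ids missing from %s: %s", path,
                   paste(utils::head(cell_ids[is.na(mi)]), collapse = ", ")))
    df <- df[mi, , drop = FALSE]
  }
  df
}

#' Read gene annotations from BED or GTF
#'
#' BED: tab-separated, no header, columns chrom, start, end, name (0-based
#' half-open, the package's internal convention). GTF: only `gene` feature
#' lines are used; gene_id is taken from the attributes; 1-based inclusive
#' coordinates are converted to 0-based half-open.
#'
#' @param path `.bed` or `.gtf`/`.gff` file.
#' @return Data frame: gene_id, chrom, start, end.
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED needs at least 4 columns (chrom start end name)")
    return(data.frame(gene_id = df[[4]], chrom = as.character(df[[1]]),
                      start = df[[2]], end = df[[3]],
                      stringsAsFactors = FALSE))
  }
  if (ext %in% c("gtf", "gff")) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", TRUE)]
    if (!length(f)) stop("no gene feature lines in GTF")
    gid <- vapply(f, function(x) {
      m <- regmatches(x[9], regexec('gene_id[ =]+"?([^";]+)"?', x[9]))[[1]]
      if (length(m) < 2) stop("gene line without gene_id attribute")
      m[2]
    }, "")
    return(data.frame(gene_id = gid,
                      chrom = vapply(f, `[`, "", 1),
                      start = as.integer(vapply(f, `[`, "", 4)) - 1L,
                      end = as.integer(vapply(f, `[`, "", 5)),
                      stringsAsFactors = FALSE))
  }
  stop("unsupported annotation format: ", ext)
}

#' Read a donor kinship matrix
#'
#' Square TSV with donor ids as header and first column; must be symmetric to
#' 1e-8.
#'
#' @param path TSV file.
#' @return Symmetric numeric matrix.
#' @export
read_kinship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M)))
    stop("kinship must be square with matching donor ids")
  if (max(abs(M - t(M))) > 1e-8) stop("kinship must be symmetric (to 1e-8)")
  (M + t(M)) / 2
}
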