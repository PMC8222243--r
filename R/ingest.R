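# Reading count matrices, cell QC, and normalization onto the tp10K / E /
# standardized scales.

#' Read a UMI count matrix
#'
#' Supports two on-disk layouts common for droplet scRNA-seq:
#' \describe{
#'   \item{mtx}{a directory holding \code{matrix.mtx} (Matrix Market
#'     coordinate format, genes as rows), \code{genes.tsv} (one gene id per
#'     line, first column used) and \code{barcodes.tsv}.}
#'   \item{dge}{a dense Drop-seq-style digital-gene-expression table:
#'     tab-delimited, header row of cell barcodes, first column gene
#'     symbols.}
#' }
#'
#' @param path directory (mtx) or file (dge).
#' @param format \code{"mtx"} or \code{"dge"}.
#' @return sparse genes x cells count matrix with gene ids and barcodes in
#'   file order.
#' @export
read_counts <- function(path, format = c("mtx", "dge")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mfile <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    dirn <- dirname(mfile)
    for (f in c(mfile, file.path(dirn, c("genes.tsv", "barcodes.tsv"))))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mfile)
    first_field <- function(f)
      vapply(strsplit(readLines(f), "\t", fixed = TRUE),
             function(r) if (length(r)) r[1] else "", "")
    genes <- first_field(file.path(dirn, "genes.tsv"))
    barcodes <- first_field(file.path(dirn, "barcodes.tsv"))
    if (length(genes) != nrow(m))
      stop("genes.tsv has ", length(genes), " entries but matrix has ",
           nrow(m), " rows")
    if (length(barcodes) != ncol(m))
      stop("barcodes.tsv has ", length(barcodes), " entries but matrix has ",
           ncol(m), " columns")
    dimnames(m) <- list(genes, barcodes)
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      row.names = NULL)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- genes
    mode(m) <- "double"
  }
  as_count_matrix(m)
}

#' Read a barcode-to-cluster annotation table
#'
#' @param path TSV with columns \code{barcode} and \code{cluster}
#'   (additional columns such as a time point are kept).
#' @return data frame.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("barcode", "cluster") %in% names(ann)))
    stop("annotation file needs columns 'barcode' and 'cluster'")
  ann
}

default_mito_rule <- function(gene_ids) grepl("^mt-", gene_ids, ignore.case = TRUE)

resolve_mito <- function(gene_ids, mito_rule) {
  if (is.null(mito_rule)) return(default_mito_rule(gene_ids))
  if (is.function(mito_rule)) {
    flag <- mito_rule(gene_ids)
    if (!is.logical(flag) || length(flag) != length(gene_ids))
      stop("mito_rule function must return one logical per gene")
    return(flag)
  }
  if (is.character(mito_rule)) return(gene_ids %in% mito_rule)
  stop("mito_rule must be NULL, a character vector of gene ids, or a predicate")
}

#' Cell quality-control filter
#'
#' Removes low-quality cells using strict inequalities: a cell is removed
#' when it has fewer than \code{min_genes} detected genes (genes with at
#' least one UMI) or when more than \code{max_mito_frac} of its transcripts
#' come from mitochondria-encoded genes. Cells exactly at a boundary (e.g.
#' 500 detected genes, or a mitochondrial fraction of exactly 0.10) are
#' kept. Genes are never removed.
#'
#' @param counts genes x cells count matrix.
#' @param min_genes minimum detected-gene count to keep a cell (default 500).
#' @param max_mito_frac maximum tolerated mitochondrial UMI fraction
#'   (default 0.10).
#' @param mito_rule how to identify mitochondria-encoded genes: \code{NULL}
#'   for the default case-insensitive \code{"mt-"} gene-symbol prefix, a
#'   character vector of gene ids, or a predicate function on gene ids.
#' @return list with elements \code{counts} (retained cells) and
#'   \code{report} (a \code{qc_report}: per-cell metrics, pass/fail flags
#'   and reasons, plus a summary).
#' @export
qc_filter <- function(counts, min_genes = 500, max_mito_frac = 0.10,
                      mito_rule = NULL) {
  counts <- as_count_matrix(counts)
  stopifnot(max_mito_frac >= 0, max_mito_frac <= 1, min_genes >= 0)
  mito <- resolve_mito(rownames(counts), mito_rule)
  mito_warning <- NULL
  if (nrow(counts) > 0 && !any(mito))
    mito_warning <- "mitochondrial rule matched zero genes; fractions set to 0"

  n_genes <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else
    rep(0, ncol(counts))
  mito_frac <- ifelse(total > 0, mito_umi / total, 0)

  fail_genes <- n_genes < min_genes
  fail_mito <- mito_frac > max_mito_frac
  pass <- !fail_genes & !fail_mito
  reason <- rep("", ncol(counts))
  reason[fail_genes] <- "low_genes"
  reason[fail_mito] <- ifelse(fail_genes[fail_mito], "low_genes;high_mito",
                              "high_mito")

  cells <- data.frame(barcode = colnames(counts), n_genes = as.integer(n_genes),
                      total_umi = as.numeric(total), mito_frac = mito_frac,
                      pass = pass, reason = reason,
                      stringsAsFactors = FALSE, row.names = NULL)
  report <- structure(list(
    cells = cells,
    summary = list(n_input = ncol(counts), n_pass = sum(pass),
                   n_fail = sum(!pass), min_genes = min_genes,
                   max_mito_frac = max_mito_frac,
                   n_mito_genes = sum(mito), warning = mito_warning)),
    class = "qc_report")
  if (!is.null(mito_warning)) warning(mito_warning)
  list(counts = counts[, pass, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("QC: %d cells in, %d pass, %d removed (min_genes=%d, max_mito=%.3g)\n",
              s$n_input, s$n_pass, s$n_fail, s$min_genes, s$max_mito_frac))
  if (!is.null(s$warning)) cat("note:", s$warning, "\n")
  invisible(x)
}

#' Transcripts-per-10K normalization
#'
#' Divides each cell by its total UMI count and multiplies by 10,000, so
#' every column sums to 10,000.
#'
#' @param counts genes x cells count matrix; every cell must have at least
#'   one UMI (guaranteed after [qc_filter()]).
#' @return sparse expression matrix on the \code{tp10K} scale.
#' @export
normalize_tp10k <- function(counts) {
  counts <- as_count_matrix(counts)
  total <- Matrix::colSums(counts)
  if (ncol(counts) && any(total == 0))
    stop("cells with zero total UMI present; run qc_filter() first")
  x <- counts %*% Matrix::Diagonal(ncol(counts), x = 1e4 / pmax(total, 1))
  dimnames(x) <- dimnames(counts)
  expr_scale(x) <- "tp10K"
  x
}

#' Log expression: E = ln(tp10K + 1)
#'
#' @param expr expression matrix on the \code{tp10K} scale.
#' @return expression matrix on the \code{E} scale.
#' @export
log_transform <- function(expr) {
  if (!identical(expr_scale(expr), "tp10K"))
    stop("log_transform expects a tp10K-scale matrix")
  x <- expr
  if (is(x, "sparseMatrix")) x@x <- log1p(x@x) else x <- log1p(x)
  expr_scale(x) <- "E"
  x
}

#' Standardize each gene across cells
#'
#' Maps each gene's log expression E to \code{(E - mean(E)) / sd(E)} across
#' cells. Genes with zero variance become all-zero rows. The default uses
#' the sample standard deviation (n - 1 denominator); a population option
#' is available.
#'
#' @param expr expression matrix on the \code{E} scale with at least 2 cells.
#' @param sd_type \code{"sample"} (default) or \code{"population"}.
#' @return dense standardized matrix (per-gene mean 0, sd 1).
#' @export
standardize_genes <- function(expr, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!identical(expr_scale(expr), "E"))
    stop("standardize_genes expects an E-scale matrix")
  if (ncol(expr) < 2) stop("standardization needs at least 2 cells")
  x <- as.matrix(expr)
  mu <- rowMeans(x)
  n <- ncol(x)
  ss <- rowSums((x - mu)^2)
  denom <- if (sd_type == "sample") n - 1 else n
  s <- sqrt(ss / denom)
  z <- (x - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  expr_scale(z) <- "standardized"
  z
}
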