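#' @importFrom Matrix sparseMatrix Diagonal readMM writeMM colSums rowSums
#'   rowMeans
#' @importFrom methods as is new
#' @importFrom stats cor dbinom quantile rlnorm rnbinom rgamma sd var
#'   hclust as.dist p.adjust setNames
#' @importFrom utils read.delim write.table packageVersion head modifyList
NULL

# ---- CountMatrix ------------------------------------------------------------

#' Validate a UMI count matrix
#'
#' A count matrix is a genes-by-cells sparse (or dense) matrix of
#' non-negative integer UMI counts with unique gene identifiers as row
#' names and unique cell barcodes as column names.
#'
#' @param counts matrix or \code{Matrix} of counts, genes x cells.
#' @return the validated matrix as a \code{dgCMatrix}, invisibly unchanged
#'   in content.
#' @export
as_count_matrix <- function(counts) {
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0))
    stop("count matrix must have gene ids as rownames and barcodes as colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g))
    stop("duplicated gene ids: ", paste(head(dup_g, 5), collapse = ", "))
  dup_b <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_b))
    stop("duplicated barcodes: ", paste(head(dup_b, 5), collapse = ", "))
  if (is(counts, "Matrix") && !is(counts, "dMatrix"))
    counts <- counts * 1   # pattern/logical matrices (e.g. MTX with no data)
  x <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  v <- x@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("count matrix must contain non-negative integers")
  x
}

# ---- ExpressionMatrix -------------------------------------------------------

#' Scale tag of an expression matrix
#'
#' Normalized expression matrices carry a scale tag: \code{"tp10K"}
#' (transcripts per 10,000 UMIs), \code{"E"} (\code{ln(tp10K + 1)}), or
#' \code{"standardized"} (per-gene z-scores of E).
#'
#' @param x an expression matrix produced by [normalize_tp10k()],
#'   [log_transform()] or [standardize_genes()].
#' @return a character scalar, or \code{NULL} for an untagged matrix.
#' @export
expr_scale <- function(x) attr(x, "expr_scale")

`expr_scale<-` <- function(x, value) {
  stopifnot(value %in% c("tp10K", "E", "standardized"))
  attr(x, "expr_scale") <- value
  x
}

# ---- CellAnnotation ---------------------------------------------------------

#' Coerce a cell annotation to a named cluster vector
#'
#' Accepts either a named character vector (barcode -> cluster label) or a
#' data frame with columns \code{barcode} and \code{cluster}. Every
#' annotated barcode must exist in the companion matrix.
#'
#' @param ann annotation as a named vector or data frame.
#' @param barcodes barcodes of the companion matrix.
#' @return named character vector, one entry per barcode of the companion
#'   matrix (order follows \code{barcodes}).
#' @export
as_cell_annotation <- function(ann, barcodes) {
  if (is.data.frame(ann)) {
    if (!all(c("barcode", "cluster") %in% names(ann)))
      stop("annotation data frame needs columns 'barcode' and 'cluster'")
    v <- setNames(as.character(ann$cluster), as.character(ann$barcode))
  } else {
    if (is.null(names(ann))) stop("annotation vector must be named by barcode")
    v <- setNames(as.character(ann), names(ann))
  }
  if (anyDuplicated(names(v)))
    stop("annotation contains duplicated barcodes")
  missing <- setdiff(names(v), barcodes)
  if (length(missing))
    stop("annotated barcodes absent from matrix: ",
         paste(head(missing, 5), collapse = ", "))
  unann <- setdiff(barcodes, names(v))
  if (length(unann))
    stop(length(unann), " barcodes lack an annotation (e.g. ",
         paste(head(unann, 3), collapse = ", "), ")")
  v[barcodes]
}

# ---- CentroidMatrix ---------------------------------------------------------

new_centroid_matrix <- function(m, scale, n_cells) {
  attr(m, "expr_scale") <- scale
  attr(m, "n_cells") <- n_cells
  class(m) <- c("centroid_matrix", class(m))
  m
}

#' @export
print.centroid_matrix <- function(x, ...) {
  cat(sprintf("Centroid matrix: %d cell types x %d genes (scale: %s)\n",
              nrow(x), ncol(x),
              if (is.null(expr_scale(x))) "untagged" else expr_scale(x)))
  nc <- attr(x, "n_cells")
  if (!is.null(nc))
    cat("cells per type:",
        paste(sprintf("%s=%d", names(nc), nc), collapse = ", "), "\n")
  invisible(x)
}
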