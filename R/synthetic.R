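# Seeded negative-binomial count simulator with planted cell-type markers,
# mitochondrial content and ligand-receptor signals. The generator gives
# every downstream stage a dataset with known ground truth.

#' Specification of a synthetic scRNA-seq dataset
#'
#' Counts follow a negative-binomial model: the expected count of gene g in
#' cell c of type t is \code{lib(c) * baseline(g) * fold(g, t)}, where
#' \code{lib(c)} is a lognormal per-cell library scaling and
#' \code{fold(g, t)} multiplies together every marker and ligand-receptor
#' planting that applies to (g, t), defaulting to 1. The negative-binomial
#' size parameter \code{dispersion} controls overdispersion (Poisson in the
#' large-size limit).
#'
#' Defaults emulate a droplet testis-style dataset: 6 labeled somatic cell
#' types of 500 cells each, 2,000 genes with gamma-distributed baseline
#' means, 13 mitochondria-encoded genes (named with an \code{mt-} prefix)
#' tuned to a 5\% expected mitochondrial UMI fraction, 20 planted markers
#' per type at 8-fold, and a handful of planted ligand-receptor pairs.
#'
#' @param n_types number of cell types.
#' @param cells_per_type integer vector of length \code{n_types}.
#' @param n_genes number of genes.
#' @param baseline_mean per-gene positive expected counts at reference
#'   library size; if \code{NULL}, drawn once (deterministically from
#'   \code{seed}) from a gamma distribution with mean \code{mean_count}.
#' @param mean_count target mean count per gene per cell used when
#'   \code{baseline_mean} is drawn (default 2, giving roughly 4,000 UMIs
#'   per 2,000-gene cell).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param lib_size_lognormal \code{c(mu, sigma)} of the per-cell library
#'   scaling on the log scale (default \code{c(0, 0.3)}).
#' @param marker_table data frame (gene, type, fold) of planted markers, or
#'   \code{NULL} for the default plantings. Folds must be positive.
#' @param n_markers_per_type,marker_fold used when \code{marker_table} is
#'   \code{NULL}.
#' @param mito_fraction target expected mitochondrial UMI fraction
#'   (default 0.05); mito baselines are rescaled to meet it.
#' @param n_mito_genes number of mitochondria-encoded genes (default 13).
#' @param lr_plantings data frame (ligand, receptor, sender, receiver,
#'   fold), or \code{NULL} for a default set of 5 planted pairs at 10-fold.
#' @param n_decoy_lr_pairs unplanted ligand-receptor pairs added to the
#'   emitted pair list (default 40).
#' @param seed integer seed governing every random draw.
#' @return a validated \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_types = 6, cells_per_type = rep(500L, n_types),
                           n_genes = 2000, baseline_mean = NULL,
                           mean_count = 2, dispersion = 2,
                           lib_size_lognormal = c(0, 0.3),
                           marker_table = NULL, n_markers_per_type = 20,
                           marker_fold = 8, mito_fraction = 0.05,
                           n_mito_genes = 13, lr_plantings = NULL,
                           n_decoy_lr_pairs = 40, seed = 1) {
  if (n_types < 1 || n_genes < 1) stop("dimensions must be positive")
  if (length(cells_per_type) != n_types)
    stop("cells_per_type must have length n_types")
  if (any(cells_per_type < 1)) stop("cells_per_type must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (mito_fraction < 0 || mito_fraction >= 1)
    stop("mito_fraction must lie in [0, 1)")
  n_mito_genes <- min(n_mito_genes, n_genes)

  types <- sprintf("type%02d", seq_len(n_types))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  mito_idx <- if (n_mito_genes > 0) seq_len(n_mito_genes) else integer(0)
  if (length(mito_idx))
    gene_ids[mito_idx] <- sprintf("mt-gene%02d", seq_along(mito_idx))

  # every derived random choice comes from the spec seed, via a private
  # RNG stream that leaves the caller's RNG untouched
  with_spec_rng <- function(offset, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed + offset)
    expr
  }

  if (is.null(baseline_mean)) {
    baseline_mean <- with_spec_rng(1000L,
      rgamma(n_genes, shape = 0.8, rate = 0.8 / mean_count))
    baseline_mean <- pmax(baseline_mean, 1e-3)
  }
  if (length(baseline_mean) != n_genes || any(baseline_mean <= 0))
    stop("baseline_mean must be ", n_genes, " positive values")

  # rescale mito baselines so their expected share of the library equals
  # the target fraction
  if (length(mito_idx) && mito_fraction > 0) {
    other <- sum(baseline_mean[-mito_idx])
    baseline_mean[mito_idx] <- baseline_mean[mito_idx] /
      sum(baseline_mean[mito_idx]) * mito_fraction / (1 - mito_fraction) * other
  }

  non_mito <- setdiff(seq_len(n_genes), mito_idx)
  if (is.null(marker_table)) {
    nm <- min(n_markers_per_type * n_types, length(non_mito))
    picked <- with_spec_rng(2000L, sample(non_mito, nm))
    marker_table <- data.frame(
      gene = gene_ids[picked],
      type = rep(types, length.out = nm),
      fold = marker_fold, stringsAsFactors = FALSE)
  }
  if (nrow(marker_table) && any(marker_table$fold <= 0))
    stop("marker folds must be positive")
  if (any(marker_table$gene %in% gene_ids[mito_idx]))
    stop("marker genes and mitochondrial genes must be disjoint")
  if (nrow(marker_table) && !all(marker_table$gene %in% gene_ids))
    stop("marker_table names genes absent from the dataset")
  if (nrow(marker_table) && !all(marker_table$type %in% types))
    stop("marker_table names unknown types")

  if (is.null(lr_plantings)) {
    free <- setdiff(non_mito, match(marker_table$gene, gene_ids))
    n_lr <- min(5L, n_types, floor(length(free) / 2))
    lr_genes <- with_spec_rng(3000L, sample(free, 2 * n_lr))
    lr_plantings <- if (n_lr > 0) data.frame(
      ligand = gene_ids[lr_genes[seq_len(n_lr)]],
      receptor = gene_ids[lr_genes[n_lr + seq_len(n_lr)]],
      sender = types[((seq_len(n_lr) - 1) %% n_types) + 1],
      receiver = types[(seq_len(n_lr) %% n_types) + 1],
      fold = 10, stringsAsFactors = FALSE)
    else data.frame(ligand = character(), receptor = character(),
                    sender = character(), receiver = character(),
                    fold = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(lr_plantings) && any(lr_plantings$fold <= 0))
    stop("ligand-receptor planting folds must be positive")
  if (nrow(lr_plantings) &&
      (!all(c(lr_plantings$ligand, lr_plantings$receptor) %in% gene_ids) ||
       !all(c(lr_plantings$sender, lr_plantings$receiver) %in% types)))
    stop("lr_plantings reference unknown genes or types")

  structure(list(
    n_types = n_types, types = types, cells_per_type = as.integer(cells_per_type),
    n_genes = n_genes, gene_ids = gene_ids, baseline_mean = baseline_mean,
    dispersion = dispersion, lib_size_lognormal = lib_size_lognormal,
    marker_table = marker_table, mito_genes = gene_ids[mito_idx],
    mito_fraction = mito_fraction, lr_plantings = lr_plantings,
    n_decoy_lr_pairs = n_decoy_lr_pairs, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a synthetic UMI count matrix with known truth
#'
#' Draws the dataset described by a [synthetic_spec()]: negative-binomial
#' counts whose means combine per-gene baselines, lognormal per-cell
#' library sizes, and the planted marker / ligand-receptor fold changes.
#' Bitwise-identical output for identical spec and seed.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{counts} (sparse genes x cells matrix with unique
#'   barcodes) and \code{truth} (cell labels, realized marker and
#'   ligand-receptor tables, per-cell library sizes, and the emitted
#'   ligand-receptor pair list including decoys).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("spec must be built with synthetic_spec()")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(spec$seed)

  n_cells <- sum(spec$cells_per_type)
  labels <- rep(spec$types, spec$cells_per_type)
  barcodes <- sprintf("cell%06d", seq_len(n_cells))
  lib <- rlnorm(n_cells, spec$lib_size_lognormal[1], spec$lib_size_lognormal[2])

  # fold(g, t): product of all applicable plantings
  fold <- matrix(1, spec$n_genes, spec$n_types,
                 dimnames = list(spec$gene_ids, spec$types))
  mt <- spec$marker_table
  for (i in seq_len(nrow(mt)))
    fold[mt$gene[i], mt$type[i]] <- fold[mt$gene[i], mt$type[i]] * mt$fold[i]
  lr <- spec$lr_plantings
  for (i in seq_len(nrow(lr))) {
    fold[lr$ligand[i], lr$sender[i]] <- fold[lr$ligand[i], lr$sender[i]] * lr$fold[i]
    fold[lr$receptor[i], lr$receiver[i]] <-
      fold[lr$receptor[i], lr$receiver[i]] * lr$fold[i]
  }

  blocks <- vector("list", spec$n_types)
  offset <- 0L
  for (t in seq_len(spec$n_types)) {
    nt <- spec$cells_per_type[t]
    mu <- outer(spec$baseline_mean * fold[, t], lib[offset + seq_len(nt)])
    blocks[[t]] <- matrix(rnbinom(length(mu), mu = mu, size = spec$dispersion),
                          nrow = spec$n_genes)
    offset <- offset + nt
  }
  counts <- do.call(cbind, blocks)
  dimnames(counts) <- list(spec$gene_ids, barcodes)
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")

  # emitted pair list: planted pairs plus decoys on unplanted genes
  decoys <- data.frame(ligand = character(), receptor = character(),
                       stringsAsFactors = FALSE)
  if (spec$n_decoy_lr_pairs > 0) {
    used <- unique(c(lr$ligand, lr$receptor, mt$gene, spec$mito_genes))
    free <- setdiff(spec$gene_ids, used)
    nd <- min(spec$n_decoy_lr_pairs, floor(length(free) / 2))
    if (nd > 0) {
      g <- sample(free, 2 * nd)
      decoys <- data.frame(ligand = g[seq_len(nd)], receptor = g[nd + seq_len(nd)],
                           stringsAsFactors = FALSE)
    }
  }
  lr_pairs <- unique(rbind(lr[, c("ligand", "receptor")], decoys))
  rownames(lr_pairs) <- NULL

  truth <- structure(list(
    labels = setNames(labels, barcodes),
    marker_table = mt, lr_plantings = lr, lr_pairs = lr_pairs,
    lib_sizes = setNames(lib, barcodes),
    mito_genes = spec$mito_genes, mito_fraction = spec$mito_fraction,
    spec = spec), class = "synthetic_truth")
  list(counts = counts, truth = truth)
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits the count matrix in the requested format plus sidecar files:
#' \code{genes.tsv}, \code{barcodes.tsv} (mtx format), a
#' \code{labels.tsv} annotation table, the emitted ligand-receptor pair
#' list, and the truth tables. The files round-trip losslessly through
#' [read_counts()] / [read_annotation()].
#'
#' @param counts genes x cells count matrix.
#' @param truth matching \code{synthetic_truth} (or \code{NULL} to write
#'   the matrix alone).
#' @param dir output directory (created if needed).
#' @param format \code{"mtx"} or \code{"dge"}.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(counts, truth, dir, format = c("mtx", "dge")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (format == "mtx") {
    counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
    writeLines(as.character(rownames(counts)), file.path(dir, "genes.tsv"))
    writeLines(as.character(colnames(counts)), file.path(dir, "barcodes.tsv"))
    paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  } else {
    tab <- cbind(GENE = rownames(counts), as.data.frame(as.matrix(counts),
                                                        check.names = FALSE))
    f <- file.path(dir, "dge.tsv")
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- f
  }
  if (!is.null(truth)) {
    lab <- data.frame(barcode = names(truth$labels),
                      cluster = as.character(truth$labels),
                      stringsAsFactors = FALSE)
    wt <- function(x, name) {
      f <- file.path(dir, name)
      write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    }
    paths <- c(paths,
               wt(lab, "labels.tsv"),
               wt(truth$marker_table, "truth_markers.tsv"),
               wt(truth$lr_plantings, "truth_lr_plantings.tsv"),
               wt(truth$lr_pairs, "lr_pairs.tsv"),
               wt(data.frame(barcode = names(truth$lib_sizes),
                             lib_size = as.numeric(truth$lib_sizes),
                             stringsAsFactors = FALSE), "truth_libsizes.tsv"))
  }
  invisible(paths)
}
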