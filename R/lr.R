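# Ligand-receptor Interaction Scores: curated-list loading, centroid-level
# highly-variable-gene filtering, score tensors, and top-quantile strong
# interaction graphs.

#' Load a curated ligand-receptor pair list
#'
#' Reads a two-column tab-delimited table (ligand gene, receptor gene). A
#' header row is recognized when the first line contains "ligand"
#' (case-insensitive). Duplicated pairs are dropped with a warning; pair
#' order is preserved. Genes absent from a particular dataset are kept and
#' simply score as absent later.
#'
#' @param path path to the TSV.
#' @return data frame with columns \code{ligand} and \code{receptor}.
#' @export
load_lr_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("ligand-receptor file is empty: ", path)
  start <- if (grepl("ligand", lines[1], ignore.case = TRUE)) 2L else 1L
  if (start > length(lines)) stop("ligand-receptor file has no data rows: ", path)
  rows <- strsplit(lines[start:length(lines)], "\t", fixed = TRUE)
  bad <- which(vapply(rows, function(r)
    length(r) < 2 || !nzchar(trimws(r[1])) || !nzchar(trimws(r[2])), logical(1)))
  if (length(bad))
    stop("malformed ligand-receptor row at line ",
         paste(bad + start - 1L, collapse = ", "))
  pairs <- data.frame(ligand = trimws(vapply(rows, `[`, "", 1)),
                      receptor = trimws(vapply(rows, `[`, "", 2)),
                      stringsAsFactors = FALSE)
  key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicated ligand-receptor pairs dropped")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  pairs
}

#' Highly-variable-gene filter parameters
#'
#' Thresholds on the per-gene mean and variance computed across cell-type
#' centroids, given either as absolute values on the centroid scale or as
#' quantiles of the empirical distributions. The default quantile mode
#' (mean at the 50th percentile, variance at the 90th) mimics setting the
#' cutoffs from the density of the two distributions.
#'
#' @param mean_threshold,var_threshold absolute thresholds (>= 0).
#' @param mean_quantile,var_quantile quantile thresholds in [0, 1]; used
#'   when absolute thresholds are not supplied.
#' @return an \code{hvg_params} list.
#' @export
hvg_params <- function(mean_threshold = NULL, var_threshold = NULL,
                       mean_quantile = 0.5, var_quantile = 0.9) {
  if (is.null(mean_threshold) != is.null(var_threshold))
    stop("supply both absolute thresholds or neither")
  if (!is.null(mean_threshold)) {
    if (mean_threshold < 0 || var_threshold < 0)
      stop("absolute thresholds must be >= 0")
    mode <- "absolute"
  } else {
    if (any(c(mean_quantile, var_quantile) < 0) ||
        any(c(mean_quantile, var_quantile) > 1))
      stop("quantiles must lie in [0, 1]")
    mode <- "quantile"
  }
  structure(list(mode = mode, mean_threshold = mean_threshold,
                 var_threshold = var_threshold,
                 mean_quantile = mean_quantile, var_quantile = var_quantile),
            class = "hvg_params")
}

#' Highly variable genes across cell-type centroids
#'
#' Keeps genes whose across-type centroid mean and variance both clear
#' their thresholds. In quantile mode the thresholds are resolved from the
#' empirical distributions of the centroid means and variances.
#'
#' @param centroids \code{centroid_matrix} with at least 2 types.
#' @param params an [hvg_params()] object.
#' @return character vector of gene names (empty, with a warning, if the
#'   thresholds select nothing).
#' @export
centroid_hvg <- function(centroids, params = hvg_params()) {
  if (nrow(centroids) < 2) stop("need at least 2 cell types")
  m <- unclass(centroids)
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  if (params$mode == "quantile") {
    mt <- quantile(mu, params$mean_quantile, names = FALSE)
    vt <- quantile(v, params$var_quantile, names = FALSE)
  } else {
    mt <- params$mean_threshold; vt <- params$var_threshold
  }
  keep <- mu >= mt & v >= vt
  if (!any(keep)) warning("HVG thresholds selected zero genes")
  colnames(m)[keep]
}

#' Restrict ligand-receptor pairs to highly variable genes
#'
#' Keeps a pair when its ligand is highly variable among the sender
#' centroids, or its receptor is highly variable among the receiver
#' centroids (an inclusive OR).
#'
#' @param pairs ligand-receptor table from [load_lr_pairs()].
#' @param sender_centroids,receiver_centroids centroid matrices of the
#'   sender and receiver cell-type sets.
#' @param params an [hvg_params()] object applied to both sides.
#' @return filtered pair table.
#' @export
filter_lr_pairs <- function(pairs, sender_centroids, receiver_centroids,
                            params = hvg_params()) {
  hvg_l <- centroid_hvg(sender_centroids, params)
  hvg_r <- centroid_hvg(receiver_centroids, params)
  keep <- pairs$ligand %in% hvg_l | pairs$receptor %in% hvg_r
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ligand-receptor Interaction Scores
#'
#' The Interaction Score of pair p from sender type a to receiver type b is
#' the product of the ligand's mean expression in a and the receptor's mean
#' expression in b (both read off the centroid matrices). Genes absent from
#' a dataset contribute 0. Self-pairs (a = b) are included whenever a type
#' appears in both sets.
#'
#' @param sender_centroids,receiver_centroids centroid matrices; their
#'   scale tags must match.
#' @param pairs ligand-receptor table.
#' @return \code{interaction_tensor}: a 3-d array S[pair, sender, receiver]
#'   with the pair table and scale attached as attributes.
#' @export
interaction_scores <- function(sender_centroids, receiver_centroids, pairs) {
  s_scale <- attr(sender_centroids, "expr_scale")
  r_scale <- attr(receiver_centroids, "expr_scale")
  if (!identical(s_scale, r_scale))
    stop("sender and receiver centroids are on different scales (",
         s_scale, " vs ", r_scale, ")")
  sc <- unclass(sender_centroids); rc <- unclass(receiver_centroids)
  gene_col <- function(cm, gene) {
    j <- match(gene, colnames(cm))
    if (is.na(j)) rep(0, nrow(cm)) else cm[, j]
  }
  np <- nrow(pairs)
  pid <- paste(pairs$ligand, pairs$receptor, sep = "_")
  s <- array(0, dim = c(np, nrow(sc), nrow(rc)),
             dimnames = list(pid, rownames(sc), rownames(rc)))
  for (p in seq_len(np)) {
    lig <- gene_col(sc, pairs$ligand[p])
    rec <- gene_col(rc, pairs$receptor[p])
    s[p, , ] <- outer(lig, rec)
  }
  structure(s, pairs = pairs, expr_scale = s_scale,
            class = c("interaction_tensor", "array"))
}

#' Strong interactions: the top quantile of a score tensor
#'
#' The threshold is the (1 - top_fraction) empirical quantile over all
#' tensor entries (every pair x sender x receiver combination, zeros
#' included): the smallest value among the top \code{ceiling(fraction * N)}
#' scores. Every entry at or above the threshold is strong, so ties at the
#' threshold may push the strong count above that nominal size.
#'
#' @param s \code{interaction_tensor} from [interaction_scores()].
#' @param top_fraction fraction of entries to keep (default 0.05).
#' @return \code{strong_graph}: list with the boolean \code{strong} tensor,
#'   sender x receiver count matrix \code{counts}, per-type
#'   \code{sender_totals} and \code{receiver_totals}, the \code{threshold},
#'   \code{top_fraction}, \code{n_strong}, and \code{all_tied} (TRUE when
#'   every entry equals the threshold).
#' @export
strong_interactions <- function(s, top_fraction = 0.05) {
  if (!length(s)) stop("empty interaction tensor")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  v <- as.vector(s)
  m <- ceiling(top_fraction * length(v))
  thr <- sort(v, decreasing = TRUE)[m]
  strong <- unclass(s) >= thr
  counts <- apply(strong, c(2, 3), sum)
  structure(list(
    strong = strong, counts = counts,
    sender_totals = rowSums(counts), receiver_totals = colSums(counts),
    threshold = thr, top_fraction = top_fraction, n_strong = sum(strong),
    all_tied = all(v == thr)),
    class = "strong_graph")
}

#' @export
print.strong_graph <- function(x, ...) {
  cat(sprintf("Strong-interaction graph: %d strong entries (top %.1f%%, threshold %.4g)\n",
              x$n_strong, 100 * x$top_fraction, x$threshold))
  if (x$all_tied) cat("note: all scores tied at the threshold\n")
  invisible(x)
}

#' Combined interaction report over several score matrices
#'
#' Assembles the long-format interaction table (matrix, pair, ligand,
#' receptor, sender, receiver, score, strong flag) and per-type totals for
#' a set of named analyses, e.g. germ-to-soma, soma-to-soma and
#' soma-to-germ. All graphs must share the same top fraction.
#'
#' @param analyses named list; each element a list with components
#'   \code{scores} (an \code{interaction_tensor}) and \code{graph} (the
#'   matching \code{strong_graph}).
#' @return \code{interaction_report}: list with data frames
#'   \code{interactions} and \code{totals}, plus \code{top_fraction}.
#' @export
interaction_report <- function(analyses) {
  if (is.null(names(analyses)) || any(!nzchar(names(analyses))))
    stop("analyses must be a named list")
  fracs <- vapply(analyses, function(a) a$graph$top_fraction, numeric(1))
  if (length(unique(fracs)) != 1)
    stop("all graphs must use the same top fraction")
  rows <- lapply(names(analyses), function(nm) {
    a <- analyses[[nm]]
    s <- a$scores
    pairs <- attr(s, "pairs")
    dn <- dimnames(s)
    grid <- expand.grid(pair = seq_along(dn[[1]]), sender = dn[[2]],
                        receiver = dn[[3]], KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    data.frame(matrix = nm, pair = dn[[1]][grid$pair],
               ligand = pairs$ligand[grid$pair],
               receptor = pairs$receptor[grid$pair],
               sender = grid$sender, receiver = grid$receiver,
               score = as.vector(unclass(s)),
               strong = as.vector(a$graph$strong),
               stringsAsFactors = FALSE)
  })
  totals <- lapply(names(analyses), function(nm) {
    g <- analyses[[nm]]$graph
    rbind(data.frame(matrix = nm, type = names(g$sender_totals),
                     role = "sender", n_strong = as.integer(g$sender_totals),
                     stringsAsFactors = FALSE),
          data.frame(matrix = nm, type = names(g$receiver_totals),
                     role = "receiver", n_strong = as.integer(g$receiver_totals),
                     stringsAsFactors = FALSE))
  })
  structure(list(interactions = do.call(rbind, rows),
                 totals = do.call(rbind, totals),
                 top_fraction = fracs[[1]]),
            class = "interaction_report")
}

#' Write / read an interaction report
#'
#' Serializes the report as two TSVs plus a small JSON with the top
#' fraction; \code{read_interaction_report()} restores an identical object.
#'
#' @param report an \code{interaction_report}.
#' @param dir output directory (created if needed).
#' @return the directory (write) or the restored report (read).
#' @export
write_interaction_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$interactions, file.path(dir, "interactions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$totals, file.path(dir, "interaction_totals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(top_fraction = report$top_fraction),
                       file.path(dir, "interaction_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_interaction_report
#' @export
read_interaction_report <- function(dir) {
  structure(list(
    interactions = read.delim(file.path(dir, "interactions.tsv"),
                              stringsAsFactors = FALSE),
    totals = read.delim(file.path(dir, "interaction_totals.tsv"),
                        stringsAsFactors = FALSE),
    top_fraction = jsonlite::read_json(
      file.path(dir, "interaction_meta.json"))$top_fraction),
    class = "interaction_report")
}
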