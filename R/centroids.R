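# Cell-type centroids, Euclidean dissimilarity, leaf ordering of types,
# and cross-dataset centroid correlation.

#' Per-cluster expression centroids
#'
#' The centroid of a cell type is the arithmetic mean of its cells'
#' expression vectors, gene by gene, on whatever scale the input matrix
#' carries.
#'
#' @param expr genes x cells expression (or count) matrix.
#' @param ann cell annotation (see [as_cell_annotation()]); every cluster
#'   must contain at least one cell.
#' @return \code{centroid_matrix}: cell types x genes, with per-type cell
#'   counts and the inherited scale tag.
#' @export
compute_centroids <- function(expr, ann) {
  labels <- as_cell_annotation(ann, colnames(expr))
  types <- sort(unique(labels))
  ind <- Matrix::sparseMatrix(
    i = seq_along(labels), j = match(labels, types),
    x = 1, dims = c(length(labels), length(types)))
  n_cells <- as.integer(Matrix::colSums(ind))
  sums <- as.matrix(expr %*% ind)           # genes x types
  cent <- t(sweep(sums, 2, n_cells, "/"))   # types x genes
  dimnames(cent) <- list(types, rownames(expr))
  new_centroid_matrix(cent, attr(expr, "expr_scale"),
                      setNames(n_cells, types))
}

#' Euclidean dissimilarity between cell-type centroids
#'
#' @param centroids \code{centroid_matrix} with at least 2 types.
#' @return symmetric types x types matrix of Euclidean distances over all
#'   genes, zero on the diagonal.
#' @export
dissimilarity_matrix <- function(centroids) {
  if (nrow(centroids) < 2) stop("need at least 2 cell types")
  as.matrix(stats::dist(unclass(centroids), method = "euclidean"))
}

# Held-Karp dynamic program: h[S, j] = minimal cost of a Hamiltonian path
# over vertex subset S that starts at vertex j.
hamiltonian_table <- function(d) {
  k <- nrow(d)
  nsub <- bitwShiftL(1L, k)
  h <- matrix(Inf, nsub - 1L, k)
  for (j in seq_len(k)) h[bitwShiftL(1L, j - 1L), j] <- 0
  subsets <- order(vapply(seq_len(nsub - 1L), function(s)
    sum(bitwAnd(s, bitwShiftL(1L, 0:(k - 1))) > 0), numeric(1)))
  for (s in subsets) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(k - 1))) > 0)
    if (length(members) < 2) next
    for (j in members) {
      rest <- s - bitwShiftL(1L, j - 1L)
      ks <- members[members != j]
      h[s, j] <- min(d[j, ks] + h[rest, ks])
    }
  }
  h
}

# Reconstruct the lexicographically smallest optimal path from the table.
hamiltonian_path <- function(d, h) {
  k <- nrow(d)
  full <- bitwShiftL(1L, k) - 1L
  best <- min(h[full, ])
  tol <- 1e-9 * (1 + abs(best))
  cur <- which(h[full, ] <= best + tol)[1]
  path <- cur
  s <- full
  while (length(path) < k) {
    rest <- s - bitwShiftL(1L, cur - 1L)
    members <- which(bitwAnd(rest, bitwShiftL(1L, 0:(k - 1))) > 0)
    step <- d[cur, members] + h[rest, members]
    tol <- 1e-9 * (1 + abs(h[s, cur]))
    cur <- members[which(step <= h[s, cur] + tol)[1]]
    s <- rest
    path <- c(path, cur)
  }
  path
}

# Optimal leaf ordering on an average-linkage dendrogram (dynamic program
# over subtree orientations; M[l, r] = minimal cost of ordering the node's
# leaves with l leftmost and r rightmost).
olo_order <- function(d) {
  k <- nrow(d)
  hc <- hclust(as.dist(d), method = "average")
  leaves <- vector("list", nrow(hc$merge))
  tabs <- vector("list", nrow(hc$merge))
  node_info <- function(idx) {
    if (idx < 0) {
      l <- -idx
      m <- matrix(Inf, k, k); m[l, l] <- 0
      list(leaves = l, M = m)
    } else list(leaves = leaves[[idx]], M = tabs[[idx]])
  }
  for (n in seq_len(nrow(hc$merge))) {
    a <- node_info(hc$merge[n, 1]); b <- node_info(hc$merge[n, 2])
    la <- a$leaves; lb <- b$leaves
    m <- matrix(Inf, k, k)
    # join cost: best split point pair (end of left block, start of right)
    for (l in la) for (r in lb)
      m[l, r] <- min(outer(a$M[l, la], b$M[lb, r], "+") +
                       d[la, lb, drop = FALSE])
    for (l in lb) for (r in la)
      m[l, r] <- min(outer(b$M[l, lb], a$M[la, r], "+") +
                       d[lb, la, drop = FALSE])
    leaves[[n]] <- c(la, lb)
    tabs[[n]] <- m
  }
  root <- nrow(hc$merge)
  # reconstruct by re-deriving the argmin at every node
  reconstruct <- function(idx, l, r) {
    if (idx < 0) return(-idx)
    a <- node_info(hc$merge[idx, 1]); b <- node_info(hc$merge[idx, 2])
    la <- a$leaves; lb <- b$leaves
    if (l %in% la) {
      left <- a; right <- b; li <- hc$merge[idx, 1]; ri <- hc$merge[idx, 2]
    } else {
      left <- b; right <- a; li <- hc$merge[idx, 2]; ri <- hc$merge[idx, 1]
    }
    ll <- left$leaves; rl <- right$leaves
    costs <- outer(left$M[l, ll], right$M[rl, r], "+") +
      d[ll, rl, drop = FALSE]
    target <- min(costs)
    pick <- which(costs <= target + 1e-9 * (1 + abs(target)), arr.ind = TRUE)[1, ]
    c(reconstruct(li, l, ll[pick[1]]), reconstruct(ri, rl[pick[2]], r))
  }
  m <- tabs[[root]]
  best <- min(m)
  pick <- which(m <= best + 1e-9 * (1 + abs(best)), arr.ind = TRUE)
  pick <- pick[order(pick[, 1], pick[, 2]), , drop = FALSE][1, ]
  reconstruct(root, pick[1], pick[2])
}

#' Order cell types by minimizing the sum of adjacent centroid distances
#'
#' Returns a linear ordering of the cell types that minimizes the total
#' distance between adjacent types. For up to \code{exact_max} types the
#' minimum is found exactly over all Hamiltonian paths (Held-Karp dynamic
#' program); beyond that an optimal leaf ordering of an average-linkage
#' dendrogram is used. Ties are broken deterministically: the
#' lexicographically smallest ordering among the optima, oriented so the
#' first type index is the smaller end.
#'
#' @param d symmetric distance matrix (types x types).
#' @param exact_max largest type count handled by the exact search
#'   (default 10).
#' @return character vector of type labels (or indices when unlabeled) with
#'   attributes \code{cost} (sum of adjacent distances) and \code{method}.
#' @export
order_types <- function(d, exact_max = 10) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  k <- nrow(d)
  if (k < 2) stop("need at least 2 types")
  if (k <= exact_max) {
    h <- hamiltonian_table(d)
    path <- hamiltonian_path(d, h)
    method <- "exact"
  } else {
    path <- olo_order(d)
    method <- "dendrogram-olo"
  }
  if (path[1] > path[k]) path <- rev(path)
  cost <- sum(d[cbind(path[-k], path[-1])])
  out <- if (!is.null(rownames(d))) rownames(d)[path] else path
  structure(out, cost = cost, method = method, index = path)
}

#' Spearman correlation of cell types across two datasets
#'
#' Correlates every cell-type pair between two centroid matrices over a
#' shared gene set, using Spearman rank correlation with average ranks for
#' ties.
#'
#' @param a,b \code{centroid_matrix} objects (types x genes).
#' @param gene_subset \code{"shared"} (default: all genes present in both)
#'   or a character vector of genes to intersect with the shared set (for
#'   example a marker union).
#' @return types-of-a x types-of-b correlation matrix with attributes
#'   \code{n_genes} and \code{genes} recording the subset used.
#' @export
cross_dataset_correlation <- function(a, b, gene_subset = "shared") {
  genes <- intersect(colnames(a), colnames(b))
  if (!identical(gene_subset, "shared"))
    genes <- intersect(genes, gene_subset)
  if (length(genes) < 3)
    stop("need at least 3 shared genes (found ", length(genes), ")")
  rho <- cor(t(unclass(a)[, genes, drop = FALSE]),
             t(unclass(b)[, genes, drop = FALSE]),
             method = "spearman")
  structure(rho, n_genes = length(genes), genes = genes,
            class = c("correlation_matrix", "matrix", "array"))
}

#' Best cross-dataset match per cell type
#'
#' For each row (cell type of the first dataset) returns the column (cell
#' type of the second dataset) with the highest correlation; ties take the
#' first column label and are flagged.
#'
#' @param corr correlation matrix from [cross_dataset_correlation()].
#' @return data frame with columns \code{type_a}, \code{type_b},
#'   \code{rho}, \code{tie}.
#' @export
best_match <- function(corr) {
  m <- unclass(corr)
  if (!length(m)) stop("empty correlation matrix")
  idx <- apply(m, 1, which.max)
  tie <- vapply(seq_len(nrow(m)), function(i)
    sum(m[i, ] == m[i, idx[i]]) > 1, logical(1))
  data.frame(type_a = rownames(m), type_b = colnames(m)[idx],
             rho = m[cbind(seq_len(nrow(m)), idx)], tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}
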