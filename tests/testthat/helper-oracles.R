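# Independent oracles and small fixture builders used across the suite.

# all permutations of 1..n, one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force minimal Hamiltonian-path cost over a distance matrix
brute_force_path_cost <- function(d) {
  k <- nrow(d)
  p <- all_perms(k)
  costs <- rowSums(matrix(d[cbind(as.vector(p[, -k]), as.vector(p[, -1]))],
                          nrow(p)))
  min(costs)
}

# exhaustive-enumeration binomial p-value, written independently of the
# package: outcome masses from lchoose, two-sided mass of outcomes no more
# likely than the observed one
enum_binom_p <- function(k, n, p0) {
  ks <- 0:n
  logp <- lchoose(n, ks) + ks * log(p0) + (n - ks) * log1p(-p0)
  mass <- exp(logp)
  obs <- mass[k + 1]
  min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
}

# tiny labeled count matrix from a dense integer matrix
tiny_counts <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  as_count_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# labels assigning consecutive column blocks to the named groups
block_labels <- function(counts, groups) {
  n <- ncol(counts)
  per <- ceiling(n / length(groups))
  stats::setNames(rep(groups, each = per)[seq_len(n)], colnames(counts))
}
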