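# Reading count matrices, the strict-inequality QC filter, and the
# tp10K / E / standardized normalization chain.

test_that("a small MTX fixture parses to exactly its entries", {
  m <- tiny_counts(matrix(c(1L, 0L, 3L, 0L, 2L, 5L), nrow = 3),
                   genes = c("a", "b", "c"), cells = c("x", "y"))
  dir <- withr::local_tempdir()
  write_fixture(m, NULL, dir, "mtx")
  back <- read_counts(dir, "mtx")
  expect_equal(as.matrix(back), as.matrix(m))
  expect_identical(rownames(back), c("a", "b", "c"))
  expect_identical(colnames(back), c("x", "y"))
})

test_that("DGE and MTX encodings of the same data read identically", {
  m <- tiny_counts(matrix(rpois(50, 2), 10, 5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(m, NULL, d1, "mtx")
  write_fixture(m, NULL, d2, "dge")
  expect_equal(as.matrix(read_counts(d1, "mtx")),
               as.matrix(read_counts(file.path(d2, "dge.tsv"), "dge")))
})

test_that("duplicate labels and non-integer values are rejected by name", {
  m <- matrix(1L, 2, 2, dimnames = list(c("g1", "g1"), c("c1", "c2")))
  expect_error(as_count_matrix(m), "g1")
  m2 <- matrix(1L, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c1")))
  expect_error(as_count_matrix(m2), "c1")
  m3 <- matrix(c(1.5, 0, 0, 2), 2, 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(as_count_matrix(m3), "integer")
  m4 <- matrix(c(-1, 0, 0, 2), 2, 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(as_count_matrix(m4), "integer|negative")
})

# builds one cell per requested (detected genes, mito fraction) profile on
# a 1000-gene panel with 10 mt- genes
qc_boundary_fixture <- function() {
  genes <- c(sprintf("mt-%02d", 1:10), sprintf("g%04d", 1:990))
  cell <- function(n_detected, mito_umi, total_umi) {
    v <- numeric(1000)
    if (mito_umi > 0) v[1] <- mito_umi
    n_rest <- n_detected - (mito_umi > 0)
    rest <- total_umi - mito_umi
    idx <- 10 + seq_len(n_rest)
    v[idx] <- 1
    v[idx[1]] <- rest - (n_rest - 1)
    v
  }
  m <- cbind(
    genes499 = cell(499, 0, 600),
    genes500 = cell(500, 0, 600),
    mito099 = cell(600, 99, 1000),
    mito100 = cell(600, 100, 1000),
    mito101 = cell(600, 101, 1000))
  rownames(m) <- genes
  as_count_matrix(m)
}

test_that("QC boundaries follow the strict inequalities exactly", {
  counts <- qc_boundary_fixture()
  res <- qc_filter(counts, min_genes = 500, max_mito_frac = 0.10)
  kept <- colnames(res$counts)
  expect_false("genes499" %in% kept)   # <500 detected genes removed
  expect_true("genes500" %in% kept)    # exactly 500 kept
  expect_true("mito099" %in% kept)
  expect_true("mito100" %in% kept)     # exactly 10% kept; removal needs >10%
  expect_false("mito101" %in% kept)
  rep <- res$report$cells
  expect_identical(rep$reason[rep$barcode == "genes499"], "low_genes")
  expect_identical(rep$reason[rep$barcode == "mito101"], "high_mito")
  expect_equal(res$report$summary$n_pass + res$report$summary$n_fail,
               ncol(counts))
})

test_that("QC is idempotent and handles the empty matrix", {
  spec <- synthetic_spec(n_types = 2, cells_per_type = c(50, 50),
                         n_genes = 300, seed = 2)
  counts <- generate_dataset(spec)$counts
  r1 <- qc_filter(counts, min_genes = 100)
  r2 <- qc_filter(r1$counts, min_genes = 100)
  expect_equal(as.matrix(r2$counts), as.matrix(r1$counts))
  expect_equal(r2$report$summary$n_fail, 0)

  empty <- counts[, FALSE, drop = FALSE]
  re <- qc_filter(empty)
  expect_identical(ncol(re$counts), 0L)
  expect_equal(re$report$summary$n_input, 0)
})

test_that("a mito rule matching zero genes warns and applies fraction 0", {
  m <- tiny_counts(matrix(1L, 600, 2))
  expect_warning(res <- qc_filter(m, min_genes = 500,
                                  mito_rule = character(0)), "zero genes")
  expect_identical(ncol(res$counts), 2L)
  expect_true(all(res$report$cells$mito_frac == 0))
})

test_that("tp10K normalization matches the printed formula", {
  m <- tiny_counts(matrix(c(1L, 0L, 3L), 3, 1))
  tp <- normalize_tp10k(m)
  expect_equal(as.numeric(tp[, 1]), c(2500, 0, 7500))
  e <- log_transform(tp)
  expect_equal(as.numeric(e[, 1]), c(7.8245, 0, 8.9229), tolerance = 1e-4)
  expect_identical(expr_scale(tp), "tp10K")
  expect_identical(expr_scale(e), "E")
})

test_that("tp10K columns sum to 10,000 and are depth-invariant", {
  counts <- generate_dataset(synthetic_spec(n_types = 2,
    cells_per_type = c(60, 60), n_genes = 250, seed = 4))$counts
  tp <- normalize_tp10k(counts)
  expect_true(all(abs(Matrix::colSums(tp) - 1e4) < 1e-6 * 1e4))
  doubled <- counts * 2
  expect_equal(as.matrix(normalize_tp10k(as_count_matrix(doubled))),
               as.matrix(tp))
})

test_that("zero-total cells are refused with a pointer to QC", {
  m <- tiny_counts(cbind(a = c(1L, 2L), b = c(0L, 0L)))
  expect_error(normalize_tp10k(m), "qc_filter")
})

test_that("gene standardization gives mean 0 / sd 1 with both denominators", {
  m <- tiny_counts(matrix(c(3L, 1L, 20L, 5L), 2, 2))
  e <- log_transform(normalize_tp10k(m))
  # closed form on a two-cell gene: sample sd gives +-1/sqrt(2)
  z <- standardize_genes(e)
  expect_equal(abs(as.numeric(z[1, ])), rep(1 / sqrt(2), 2))
  zp <- standardize_genes(e, sd_type = "population")
  expect_equal(abs(as.numeric(zp[1, ])), rep(1, 2))

  # random fixture: recompute means and sds directly
  counts <- generate_dataset(synthetic_spec(n_types = 2,
    cells_per_type = c(30, 30), n_genes = 150, seed = 6))$counts
  z2 <- standardize_genes(log_transform(normalize_tp10k(counts)))
  keep <- apply(z2, 1, function(r) any(r != 0))
  expect_true(all(abs(rowMeans(z2[keep, ])) < 1e-10))
  expect_true(all(abs(apply(z2[keep, ], 1, sd) - 1) < 1e-10))
})

test_that("constant genes standardize to zero rows; one cell is an error", {
  m <- tiny_counts(rbind(flat = c(2L, 2L, 2L), varying = c(1L, 5L, 9L)))
  e <- log_transform(normalize_tp10k(m))
  e2 <- e; e2[1, ] <- 1   # constant on the E scale
  attr(e2, "expr_scale") <- "E"
  z <- standardize_genes(e2)
  expect_true(all(z[1, ] == 0))
  one <- e[, 1, drop = FALSE]
  attr(one, "expr_scale") <- "E"   # subsetting a sparse matrix drops the tag
  expect_error(standardize_genes(one), "2 cells")
})

test_that("gene-count and mito criteria commute", {
  counts <- qc_boundary_fixture()
  both <- qc_filter(counts, min_genes = 500, max_mito_frac = 0.10)
  genes_first <- qc_filter(
    qc_filter(counts, min_genes = 500, max_mito_frac = 1)$counts,
    min_genes = 0, max_mito_frac = 0.10)
  mito_first <- qc_filter(
    qc_filter(counts, min_genes = 0, max_mito_frac = 0.10)$counts,
    min_genes = 500, max_mito_frac = 1)
  expect_identical(colnames(genes_first$counts), colnames(both$counts))
  expect_identical(colnames(mito_first$counts), colnames(both$counts))
})
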