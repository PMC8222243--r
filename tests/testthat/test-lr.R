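# Ligand-receptor list handling, centroid HVG filtering, Interaction
# Scores, and the top-quantile strong-interaction graph.

make_centroids <- function(m, scale = "E") {
  structure(m, expr_scale = scale, class = "centroid_matrix")
}

test_that("pair lists load, deduplicate, and reject malformed input", {
  f <- withr::local_tempfile(lines = c("ligand\treceptor",
                                       "Pdgfa\tPdgfra",
                                       "Fgf2\tFgfr1",
                                       "Cx3cl1\tCx3cr1"))
  pairs <- load_lr_pairs(f)
  expect_identical(nrow(pairs), 3L)
  expect_identical(pairs$ligand[1], "Pdgfa")

  fdup <- withr::local_tempfile(lines = c("Pdgfa\tPdgfra", "Pdgfa\tPdgfra"))
  expect_warning(p2 <- load_lr_pairs(fdup), "duplicated")
  expect_identical(nrow(p2), 1L)

  fempty <- withr::local_tempfile(lines = character(0))
  expect_error(load_lr_pairs(fempty), "empty")

  fbad <- withr::local_tempfile(lines = c("Pdgfa\tPdgfra", "orphan"))
  expect_error(load_lr_pairs(fbad), "line 2")
})

test_that("HVG selection honors absolute and quantile thresholds", {
  cent <- make_centroids(rbind(t1 = c(flat = 5, lowvar = 1, hi = 0),
                               t2 = c(flat = 5, lowvar = 1.1, hi = 8),
                               t3 = c(flat = 5, lowvar = 0.9, hi = 4)))
  colnames(cent) <- c("flat", "lowvar", "hi")
  # constant gene excluded whenever any variance is required
  expect_false("flat" %in% centroid_hvg(cent, hvg_params(0, 1e-9)))
  # vacuous thresholds keep everything with any variation
  expect_setequal(centroid_hvg(cent, hvg_params(0, 1e-12)),
                  c("lowvar", "hi"))

  set.seed(17)
  big <- make_centroids(matrix(rexp(500), 5, 100,
                               dimnames = list(paste0("t", 1:5),
                                               paste0("g", 1:100))))
  got <- centroid_hvg(big, hvg_params(mean_quantile = 0.5,
                                      var_quantile = 0.9))
  mu <- colMeans(unclass(big)); v <- apply(unclass(big), 2, var)
  manual <- colnames(unclass(big))[mu >= quantile(mu, 0.5) &
                                     v >= quantile(v, 0.9)]
  expect_identical(got, manual)
  expect_warning(centroid_hvg(big, hvg_params(1e9, 1e9)), "zero genes")
})

test_that("pair filtering keeps a pair when either side is highly variable", {
  sender <- make_centroids(rbind(a = c(L1 = 0, L2 = 0, R1 = 1, R2 = 1),
                                 b = c(L1 = 9, L2 = 0, R1 = 1, R2 = 1)))
  receiver <- make_centroids(rbind(x = c(L1 = 1, L2 = 1, R1 = 0, R2 = 2),
                                   y = c(L1 = 1, L2 = 1, R1 = 9, R2 = 2)))
  pairs <- data.frame(ligand = c("L1", "L2", "L2", "L1"),
                      receptor = c("R2", "R1", "R2", "R1"))
  params <- hvg_params(0, 1e-9)
  kept <- filter_lr_pairs(pairs, sender, receiver, params)
  # L1 is HVG among senders, R1 among receivers; L2/R2 are flat
  expect_setequal(paste(kept$ligand, kept$receptor),
                  c("L1 R2", "L2 R1", "L1 R1"))
})

test_that("Interaction Scores are centroid products with absent genes = 0", {
  sender <- make_centroids(rbind(A = c(lig = 1.2, other = 3),
                                 B = c(lig = 0.4, other = 1)))
  receiver <- make_centroids(rbind(B = c(rec = 0.5, other = 2),
                                   C = c(rec = 2.0, other = 1)))
  pairs <- data.frame(ligand = c("lig", "ghost"), receptor = c("rec", "rec"))
  s <- interaction_scores(sender, receiver, pairs)
  expect_equal(s["lig_rec", "A", "B"], 0.6)
  expect_equal(s["lig_rec", "A", "C"], 2.4)
  expect_true(all(s["ghost_rec", , ] == 0))

  # naive triple loop oracle over a random tensor
  set.seed(23)
  sc <- make_centroids(matrix(runif(40), 4, 10,
                              dimnames = list(paste0("s", 1:4),
                                              paste0("g", 1:10))))
  rc <- make_centroids(matrix(runif(30), 3, 10,
                              dimnames = list(paste0("r", 1:3),
                                              paste0("g", 1:10))))
  pr <- data.frame(ligand = paste0("g", c(1, 3, 5)),
                   receptor = paste0("g", c(2, 4, 6)))
  s2 <- interaction_scores(sc, rc, pr)
  for (p in 1:3) for (a in 1:4) for (b in 1:3)
    expect_equal(s2[p, a, b],
                 unclass(sc)[a, pr$ligand[p]] * unclass(rc)[b, pr$receptor[p]])

  bad <- make_centroids(unclass(rc), scale = "tp10K")
  expect_error(interaction_scores(sc, bad, pr), "scales")
})

test_that("top-5% selection keeps exactly 5 of 100 distinct scores", {
  sc <- make_centroids(matrix(exp(1:50 / 10), 10, 5,
                              dimnames = list(paste0("s", 1:10),
                                              paste0("g", 1:5))))
  rc <- make_centroids(matrix(exp(1:50 / 1000), 10, 5,
                              dimnames = list(paste0("r", 1:10),
                                              paste0("g", 1:5))))
  pairs <- data.frame(ligand = "g1", receptor = "g2")
  s <- interaction_scores(sc, rc, pairs)
  stopifnot(length(unique(as.vector(s))) == 100)
  g <- strong_interactions(s, 0.05)
  expect_identical(g$n_strong, 5L)
  expect_equal(sum(g$counts), g$n_strong)
  # the strong entries are exactly the 5 largest
  expect_setequal(as.vector(unclass(s))[as.vector(g$strong)],
                  sort(as.vector(s), decreasing = TRUE)[1:5])
})

test_that("all-tied tensors keep every entry and flag the tie", {
  s <- structure(array(2, c(2, 2, 2),
                       dimnames = list(c("p1", "p2"), c("a", "b"),
                                       c("a", "b"))),
                 pairs = data.frame(ligand = c("x", "y"),
                                    receptor = c("u", "v")),
                 expr_scale = "E",
                 class = c("interaction_tensor", "array"))
  g <- strong_interactions(s, 0.05)
  expect_true(g$all_tied)
  expect_identical(g$n_strong, 8L)
  expect_equal(sum(g$counts), 8)
  expect_error(strong_interactions(s, 1.5), "top_fraction")
})

test_that("the strong set is invariant under global centroid rescaling", {
  set.seed(29)
  sc <- make_centroids(matrix(rexp(60), 6, 10,
                              dimnames = list(paste0("s", 1:6),
                                              paste0("g", 1:10))))
  pairs <- data.frame(ligand = paste0("g", 1:5),
                      receptor = paste0("g", 6:10))
  g1 <- strong_interactions(interaction_scores(sc, sc, pairs), 0.05)
  sc2 <- make_centroids(unclass(sc) * 3.7)
  g2 <- strong_interactions(interaction_scores(sc2, sc2, pairs), 0.05)
  expect_identical(g1$strong, g2$strong)
  expect_equal(g2$threshold, g1$threshold * 3.7^2)
})

test_that("totals are marginal sums and the report round-trips", {
  set.seed(37)
  sc <- make_centroids(matrix(rexp(40), 4, 10,
                              dimnames = list(paste0("s", 1:4),
                                              paste0("g", 1:10))))
  rc <- make_centroids(matrix(rexp(30), 3, 10,
                              dimnames = list(paste0("r", 1:3),
                                              paste0("g", 1:10))))
  pairs <- data.frame(ligand = paste0("g", c(1, 2, 3)),
                      receptor = paste0("g", c(4, 5, 6)))
  s1 <- interaction_scores(sc, rc, pairs)
  s2 <- interaction_scores(rc, sc, pairs)
  g1 <- strong_interactions(s1, 0.10)
  g2 <- strong_interactions(s2, 0.10)
  rep_ <- interaction_report(list(fwd = list(scores = s1, graph = g1),
                                  rev = list(scores = s2, graph = g2)))
  expect_setequal(unique(rep_$interactions$matrix), c("fwd", "rev"))
  expect_equal(sum(rep_$interactions$strong[rep_$interactions$matrix == "fwd"]),
               g1$n_strong)
  tot <- rep_$totals
  expect_equal(tot$n_strong[tot$matrix == "fwd" & tot$role == "sender"],
               as.integer(rowSums(g1$counts)))
  expect_equal(tot$n_strong[tot$matrix == "rev" & tot$role == "receiver"],
               as.integer(colSums(g2$counts)))

  dir <- withr::local_tempdir()
  write_interaction_report(rep_, dir)
  back <- read_interaction_report(dir)
  expect_equal(back$interactions, rep_$interactions)
  expect_equal(back$totals, rep_$totals)
  expect_equal(back$top_fraction, rep_$top_fraction)

  g_bad <- strong_interactions(s2, 0.2)
  expect_error(interaction_report(list(a = list(scores = s1, graph = g1),
                                       b = list(scores = s2, graph = g_bad))),
               "same top fraction")
})
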