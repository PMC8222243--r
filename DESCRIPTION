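Package: sctalk
Title: Centroid Atlases, Detection-Rate Marker Tests and Ligand-Receptor
    Interaction Scoring for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for droplet single-cell RNA-seq count matrices built
    around cluster centroids: cell quality control (detected-gene and
    mitochondrial-fraction filters), transcripts-per-10K and log
    normalization, per-gene standardization, cell-type centroid
    construction with Euclidean dissimilarity and optimal leaf ordering,
    an exact two-sided binomial test on detection rates with three-part
    marker criteria, ligand-receptor Interaction Scores with top-quantile
    strong-interaction graphs, Spearman correlation mapping of cell types
    across datasets, and a seeded negative-binomial count simulator with
    planted markers and ligand-receptor signals for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
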