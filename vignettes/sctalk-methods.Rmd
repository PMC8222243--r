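---
title: "Centroid-based single-cell comparison and ligand–receptor scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid-based single-cell comparison and ligand–receptor scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctalk)
```

This vignette explains the statistical procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the methods literature leaves room.

## The analysis model

The package operates on UMI count matrices (genes × cells) with
externally supplied cluster labels. Clustering itself is out of scope:
the unit of comparison throughout is the **cell-type centroid**, the
arithmetic mean expression vector of a labeled group of cells. Working at
the centroid level makes cross-dataset comparison cheap and robust to
per-cell noise, at the cost of ignoring within-type heterogeneity — a
deliberate trade-off this family of analyses accepts.

## QC and normalization

A cell is removed when it has fewer than `min_genes = 500` detected genes
(a gene is *detected* when it has at least one raw UMI) or when more than
`max_mito_frac = 0.10` of its UMIs come from mitochondria-encoded genes.
Both rules are strict inequalities, so cells exactly at a boundary (500
genes, 10% mitochondrial) are **kept**. Mitochondrial genes default to a
case-insensitive `mt-` symbol-prefix rule, overridable by an explicit
gene list or predicate, since annotation conventions differ across
references. The mitochondrial fraction is computed on the full matrix,
before any gene subsetting.

Normalization divides each cell by its total UMI count and multiplies by
10,000 (tp10K), so every column sums exactly to 10,000; the log scale is
`E = ln(tp10K + 1)`. Per-gene standardization maps E to
`(E − mean(E)) / sd(E)` across cells; the default uses the sample
standard deviation (n − 1 denominator) with a population option, and
zero-variance genes map to all-zero rows rather than NaN.

## Centroid atlas and type ordering

Centroids are computed on the E scale by default — the scale on which the
per-time-point processing in this analysis family operates — with the
scale recorded on the object and configurable to linear tp10K.
Dissimilarity between types is the Euclidean distance between centroid
rows over all genes.

Types are displayed in the linear order minimizing the sum of adjacent
distances. For K ≤ 10 types (the realistic atlas size here is 6–7) the
minimum-cost Hamiltonian path is found exactly with a Held–Karp dynamic
program over vertex subsets; ties are broken deterministically by taking
the lexicographically smallest optimal path, oriented so the smaller
first index leads. For larger K the package computes an optimal leaf
ordering of an average-linkage `hclust` dendrogram: a dynamic program
over each subtree's admissible (leftmost, rightmost) leaf pairs, which
minimizes the same adjacent-distance objective among dendrogram-
consistent orderings. Average linkage is the conventional choice for
expression centroids; the exact branch makes the linkage irrelevant for
every atlas-sized problem. The test suite verifies that the exact branch
attains the brute-force optimum on 1,000 random instances with K ≤ 7 and
that the dendrogram branch never beats (and usually matches) it.

Cross-dataset comparison computes the Spearman rank correlation
(average-rank tie handling, via `stats::cor`) between every type pair
over the genes shared by both centroid matrices, optionally intersected
with a marker set; the gene count used is recorded on the result. The
per-row argmax gives each type's best match, with ties resolved to the
first column label and flagged.

## The detection-rate binomial marker test

For a cluster versus all remaining cells, per gene:

* detection rates `dr_in = k_in/n_in`, `dr_out = k_out/n_out` (detection
  = raw UMI > 0);
* fold change `(mean_in + 1) / (mean_out + 1)` on linear tp10K means —
  the pseudocount of one tp10K unit stabilizes genes absent outside the
  cluster; a log-scale fold is available by passing E-scale input;
* an exact two-sided binomial p-value for `k_in` detections in `n_in`
  cells under the null rate `p0 = k_out/n_out`, clamped to
  `[1/(n_out+1), 1 − 1/(n_out+1)]` so a degenerate reference group (no
  detections, or all detections) still yields a finite, conservative
  null. The two-sided p-value is the enumeration sum of all outcome
  probabilities not exceeding the observed outcome's probability (with a
  `1 + 1e-7` relative guard for floating-point ties, the same convention
  `stats::binom.test` uses).

A marker passes when all three criteria hold: detection-rate difference
≥ 0.20, fold ≥ 2 (somatic preset; the time-course preset requires a
1.5-fold *increase* and a *higher* detection rate, i.e. direction `up`),
and p < 0.01 on the raw p-value. No multiple-testing correction enters
the decision — that mirrors how these criteria are used in practice,
where the three-way conjunction is itself the guard — but a
Benjamini–Hochberg FDR column is emitted for information. The somatic
preset treats the detection-rate and fold criteria two-sidedly, so
strongly depleted genes also qualify.

Under the null simulation built into the acceptance checks (three types,
200 cells each, 1,000 genes, no planted effects, 20 seeds) the observed
pass rate is ~0 of 60,000 records; planted 4-fold markers at baseline
detection 0.2 with 100 cells per cluster are recovered with ≥ 99%
sensitivity.

## Ligand–receptor Interaction Scores

Given a curated two-column ligand–receptor list, the analysis first
restricts to pairs whose ligand is **highly variable** across the sender
centroids *or* whose receptor is highly variable across the receiver
centroids. Highly variable means the gene's across-type centroid mean and
variance both clear thresholds. These cutoffs are conventionally read off
the empirical density of the two distributions rather than fixed in
advance, so the default is quantile mode — mean ≥ its 50th percentile and
variance ≥ its 90th percentile — with absolute thresholds available.

The Interaction Score is the product of the ligand's centroid value in
the sender type and the receptor's centroid value in the receiver type,
computed for every (pair, sender, receiver) combination; genes absent
from a dataset score 0, and self-signaling (sender = receiver) is
included. Scores default to E-scale centroids, matching the centroid
module; linear tp10K is available since a "mean expression level" can
reasonably be read on either scale.

**Strong interactions** are the top `top_fraction = 0.05` of all entries
in one score matrix. The threshold is the value of the
`ceiling(0.05 × N)`-th largest entry over the *full flattened tensor*
(zeros included — nothing in the procedure excludes them), and every
entry ≥ threshold is kept, so ties can push the strong count above the
nominal 5%; an all-tied tensor keeps everything and is flagged. This rule
is deterministic and permutation-invariant, and because the threshold is
an empirical quantile of the scores themselves, the strong *set* is
invariant under any global positive rescaling of the centroids. Counting
strong entries per sender–receiver type pair gives the interaction graph
(edge widths) and per-type totals (node sizes) of the standard pairwise
interaction plot.

## The synthetic-data generator

`generate_dataset()` draws counts from a negative-binomial model:

```
count(g, c) ~ NB(mean = lib(c) × baseline(g) × fold(g, type(c)), size = dispersion)
```

with `lib(c)` lognormal (default meanlog 0, sdlog 0.3), gamma-distributed
per-gene baselines (shape 0.8, mean 2 counts/gene at 2,000 genes ≈ 4,000
UMIs/cell), and `fold(g, t)` the product of all marker and
ligand–receptor plantings applying to (g, t). Defaults emulate the
structure these analyses assume: 6 cell types × 500 cells, 2,000 genes,
13 `mt-`-prefixed mitochondrial genes rescaled so their expected UMI
share hits a 5% target, 20 markers per type at 8-fold, and 5 planted
ligand–receptor pairs at 10-fold plus 40 unplanted decoy pairs.
Everything derived randomly (baselines, marker gene choice, counts,
decoys) comes from the spec's single seed through a private RNG stream,
so output is bitwise-reproducible and the caller's RNG is untouched.

Folds multiply the **mean**, not the detection probability: detection-
rate differences then emerge through the count model exactly as they do
in real droplet data, which is what makes the binomial test's planted-
marker power a meaningful check. One global dispersion keeps the truth
table simple (the negative binomial approaches Poisson as the size
parameter grows, which the tests exploit as a limit check).

The generator deliberately does **not** model doublets, ambient RNA,
batch effects, or spliced/unspliced structure. Passing tests therefore
demonstrate correctness of the computations under a clean overdispersed-
count model — not robustness to those real-data artifacts, which the QC
and statistical layers here make no claim to remove.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate (optional) → QC → markers →
ligand–receptor → atlas from one validated config (YAML/JSON or list);
each stage also runs standalone on the previous stage's on-disk outputs,
and the chained stages reproduce the full run byte for byte. All outputs
are plain TSV/JSON; the manifest records config, version, seed, row
counts and per-file MD5 checksums and contains no timestamps, so a rerun
with the same config and seed is byte-identical. Config validation
aggregates all problems into one report rather than failing on the first.

The built-in validation workloads are sized for a desk machine: the
study-scale determinism run uses 3,000 cells × 2,000 genes (seconds, not
minutes); null and power simulations use 20 seeds of 600 and 300 cells;
ordering optimality uses 1,000 random instances at K ≤ 7, where
brute-force enumeration is still exact. These sizes were chosen so the
whole suite re-runs quickly while leaving every statistical conclusion
(null rate, sensitivity, recovery fractions) comfortably away from its
acceptance boundary.

## Known limitations

* Cluster labels are trusted as given; label noise propagates directly
  into centroids, markers and scores.
* The binomial test treats cells as independent Bernoulli trials and the
  outside rate as a fixed null; it does not model per-cell depth in the
  detection probability.
* Interaction Scores are expression products — a screening heuristic,
  not evidence of physical signaling, and no per-interaction significance
  is attached: the method ranks scores rather than testing them.
* The exact ordering branch is exponential in the number of types; it is
  capped at K ≤ 10, beyond which the dendrogram-constrained optimum may
  differ from the unconstrained one.
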