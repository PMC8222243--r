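# Detection-rate statistics: the exact two-sided binomial test and the
# three-part marker criteria (detection-rate difference, fold change,
# binomial p-value).

#' Marker-calling criteria
#'
#' A gene is a marker of a cluster when all three hold: (1) its detection
#' rate differs between the cluster and the rest by at least
#' \code{min_dr_diff}; (2) its average expression changes at least
#' \code{min_fold}-fold; (3) the binomial test on detection counts gives
#' p < \code{alpha}. \code{direction = "up"} requires the cluster to be
#' higher on both (1) and (2); \code{"two_sided"} accepts either direction.
#'
#' @param min_dr_diff minimum detection-rate difference (default 0.20).
#' @param min_fold minimum fold change, > 1 (default 2).
#' @param alpha binomial-test significance level (default 0.01).
#' @param direction \code{"two_sided"} or \code{"up"}.
#' @return a \code{marker_criteria} list.
#' @export
marker_criteria <- function(min_dr_diff = 0.20, min_fold = 2, alpha = 0.01,
                            direction = c("two_sided", "up")) {
  direction <- match.arg(direction)
  if (min_dr_diff < 0 || min_dr_diff > 1)
    stop("min_dr_diff must lie in [0, 1]")
  if (min_fold <= 1) stop("min_fold must exceed 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(min_dr_diff = min_dr_diff, min_fold = min_fold,
                 alpha = alpha, direction = direction),
            class = "marker_criteria")
}

#' Preset: somatic cell-type markers (2-fold, two-sided)
#' @rdname marker_criteria
#' @export
criteria_somatic <- function() marker_criteria(0.20, 2, 0.01, "two_sided")

#' Preset: time-course markers (1.5-fold, up only)
#' @rdname marker_criteria
#' @export
criteria_timecourse <- function() marker_criteria(0.20, 1.5, 0.01, "up")

#' Per-gene detection counts for one cluster against the rest
#'
#' Detection means at least one raw UMI. Rates are computed within the
#' cluster and over all remaining cells.
#'
#' @param counts genes x cells count matrix.
#' @param ann cell annotation.
#' @param cluster cluster label; must not cover every cell.
#' @return data frame with gene, k_in, n_in, k_out, n_out, dr_in, dr_out,
#'   dr_diff (in minus out).
#' @export
detection_rates <- function(counts, ann, cluster) {
  labels <- as_cell_annotation(ann, colnames(counts))
  inside <- labels == cluster
  if (!any(inside)) stop("cluster not found: ", cluster)
  if (all(inside)) stop("cluster covers all cells; no reference group")
  det <- counts > 0
  k_in <- Matrix::rowSums(det[, inside, drop = FALSE])
  k_out <- Matrix::rowSums(det[, !inside, drop = FALSE])
  n_in <- sum(inside); n_out <- sum(!inside)
  data.frame(gene = rownames(counts),
             k_in = as.integer(k_in), n_in = n_in,
             k_out = as.integer(k_out), n_out = n_out,
             dr_in = k_in / n_in, dr_out = k_out / n_out,
             dr_diff = k_in / n_in - k_out / n_out,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact two-sided binomial test on detection counts
#'
#' Tests the observed detections \code{k_in} out of \code{n_in} cells
#' against the null detection rate observed outside the cluster,
#' \code{p0 = k_out / n_out}. To keep the test defined when the outside
#' rate is degenerate, p0 is clamped to
#' \code{[1/(n_out + 1), 1 - 1/(n_out + 1)]}. The two-sided p-value is the
#' exact enumeration sum of the probabilities of all outcomes no more
#' likely than the observed one, capped at 1.
#'
#' @param k_in,n_in detections and cells inside the cluster (vectorized
#'   over genes).
#' @param k_out,n_out detections and cells outside.
#' @return p-values in [0, 1].
#' @export
binomial_p <- function(k_in, n_in, k_out, n_out) {
  n <- max(length(k_in), length(k_out))
  k_in <- rep_len(k_in, n); n_in <- rep_len(n_in, n)
  k_out <- rep_len(k_out, n); n_out <- rep_len(n_out, n)
  if (any(n_in < 1) || any(n_out < 1))
    stop("n_in and n_out must be at least 1")
  if (any(k_in < 0) || any(k_in > n_in) || any(k_out < 0) || any(k_out > n_out))
    stop("detection counts must satisfy 0 <= k <= n")
  p0 <- pmin(pmax(k_out / n_out, 1 / (n_out + 1)), 1 - 1 / (n_out + 1))
  vapply(seq_len(n), function(i) {
    probs <- dbinom(0:n_in[i], n_in[i], p0[i])
    d_obs <- probs[k_in[i] + 1]
    # relative tolerance guards ties among floating-point outcome masses
    min(1, sum(probs[probs <= d_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Per-gene fold change of average expression, cluster vs rest
#'
#' Fold change of mean expression with a pseudocount:
#' \code{(mean_in + pseudo) / (mean_out + pseudo)}. Means are taken on the
#' matrix's own scale; linear tp10K is the conventional choice.
#'
#' @param expr genes x cells expression matrix (tp10K scale by default
#'   convention).
#' @param ann cell annotation.
#' @param cluster cluster label.
#' @param pseudo pseudocount added to both means (default 1).
#' @return data frame with gene, mean_in, mean_out, fold.
#' @export
fold_change <- function(expr, ann, cluster, pseudo = 1) {
  labels <- as_cell_annotation(ann, colnames(expr))
  inside <- labels == cluster
  if (!any(inside)) stop("cluster not found: ", cluster)
  if (all(inside)) stop("cluster covers all cells; no reference group")
  m_in <- Matrix::rowMeans(expr[, inside, drop = FALSE])
  m_out <- Matrix::rowMeans(expr[, !inside, drop = FALSE])
  data.frame(gene = rownames(expr), mean_in = as.numeric(m_in),
             mean_out = as.numeric(m_out),
             fold = (m_in + pseudo) / (m_out + pseudo),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call cluster markers one-vs-rest
#'
#' For every cluster, scores every gene against all remaining cells on the
#' three criteria in [marker_criteria()] and records every component
#' statistic. A Benjamini-Hochberg FDR column is included for information
#' only; the pass decision uses the raw p-value, as the criteria specify.
#'
#' @param counts genes x cells raw count matrix (detection and the test).
#' @param expr matching expression matrix for fold changes (tp10K scale by
#'   convention).
#' @param ann cell annotation with at least 2 clusters.
#' @param criteria a [marker_criteria()] object.
#' @param pseudo pseudocount for fold changes (default 1).
#' @return data frame, one row per (gene, cluster), sorted by cluster then
#'   ascending p-value, with per-criterion pass flags and \code{pass} =
#'   their conjunction.
#' @export
call_markers <- function(counts, expr, ann, criteria = criteria_somatic(),
                         pseudo = 1) {
  if (!inherits(criteria, "marker_criteria"))
    stop("criteria must be built with marker_criteria()")
  labels <- as_cell_annotation(ann, colnames(counts))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  res <- lapply(clusters, function(cl) {
    dr <- detection_rates(counts, labels, cl)
    fc <- fold_change(expr, labels, cl, pseudo = pseudo)
    p <- binomial_p(dr$k_in, dr$n_in, dr$k_out, dr$n_out)
    pass_dr <- if (criteria$direction == "up") dr$dr_diff >= criteria$min_dr_diff
      else abs(dr$dr_diff) >= criteria$min_dr_diff
    pass_fold <- if (criteria$direction == "up") fc$fold >= criteria$min_fold
      else fc$fold >= criteria$min_fold | fc$fold <= 1 / criteria$min_fold
    pass_p <- p < criteria$alpha
    data.frame(gene = dr$gene, cluster = cl,
               k_in = dr$k_in, n_in = dr$n_in, k_out = dr$k_out,
               n_out = dr$n_out, dr_in = dr$dr_in, dr_out = dr$dr_out,
               dr_diff = dr$dr_diff, mean_in = fc$mean_in,
               mean_out = fc$mean_out, fold = fc$fold, p_value = p,
               fdr = p.adjust(p, method = "BH"),
               pass_dr = pass_dr, pass_fold = pass_fold, pass_p = pass_p,
               pass = pass_dr & pass_fold & pass_p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out[order(out$cluster, out$p_value), , drop = FALSE]
}
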