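#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input and capped at 1 (a thin wrapper over [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values aligned with `p`.
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the probability that a randomly
#' chosen positive outranks a randomly chosen negative, with ties split --
#' the normalised Wilcoxon rank-sum statistic.  Higher scores should mean
#' "more likely positive" (e.g. `-log10` of a combined p-value).
#'
#' @param scores Numeric scores, one per instance.
#' @param truth Logical (or 0/1) ground-truth labels.
#' @return The AUC in `[0, 1]`, or `NA` with a warning when only one class
#'   is present.
#' @examples
#' auc_score(c(3, 2, 1, 0), c(TRUE, FALSE, TRUE, FALSE))  # 0.75
#' @export
auc_score <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    stop("'scores' and 'truth' must have the same length", call. = FALSE)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  rk <- rank(scores)
  (sum(rk[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True-positive rate and realised FDR at a q-value cutoff
#'
#' Declares instances with `q < cutoff` significant, and reports the
#' recalled fraction of the truth (TPR) and the realised proportion of
#' nulls among the significant calls (true FDR).  The true FDR is reported
#' only when at least `min_significant` instances are significant (five by
#' default, below which the ratio is too unstable to be meaningful);
#' otherwise it is `NA`.
#'
#' @param q Numeric vector of q-values.
#' @param truth Logical ground-truth labels (`TRUE` = real effect).
#' @param cutoff Significance threshold on `q` (default 0.05).
#' @param min_significant Minimum number of significant calls required to
#'   report the true FDR.
#' @return A list with `tpr`, `true_fdr`, and `n_significant`.
#' @examples
#' tpr_truefdr(c(0.01, 0.2, 0.03), c(TRUE, TRUE, FALSE))
#' @export
tpr_truefdr <- function(q, truth, cutoff = 0.05, min_significant = 5L) {
  truth <- as.logical(truth)
  if (length(q) != length(truth))
    stop("'q' and 'truth' must have the same length", call. = FALSE)
  sig <- !is.na(q) & q < cutoff
  ns <- sum(sig)
  tpr <- if (sum(truth) > 0) sum(sig & truth) / sum(truth) else NA_real_
  fdr <- if (ns >= min_significant) sum(sig & !truth) / ns else NA_real_
  list(tpr = tpr, true_fdr = fdr, n_significant = ns)
}

#' Hypergeometric enrichment of a gold-standard gene set
#'
#' Tests whether `O` observed overlaps between `D` significant genes and
#' `G` gold-standard genes, out of `N` genes in total, exceed chance:
#' the enrichment p-value is
#' \eqn{1 - \sum_{i=0}^{O-1} \binom{G}{i}\binom{N-G}{D-i}/\binom{N}{D}},
#' i.e. the hypergeometric probability of an overlap of at least `O`.  The
#' accompanying odds ratio is the ratio of proportions
#' \eqn{(O/D)/(G/N)} -- the enrichment of gold-standard genes among the
#' significant ones relative to their background rate (not the sample odds
#' ratio of the 2x2 table).
#'
#' @param N Total number of genes.
#' @param G Number of gold-standard genes.
#' @param D Number of significant (e.g. differentially expressed) genes.
#' @param O Observed overlap between the two sets.
#' @return A list of class `enrichment_result` with `N`, `G`, `D`, `O`,
#'   `p_enrich`, and `odds_ratio`.
#' @examples
#' hypergeom_enrichment(N = 10, G = 5, D = 4, O = 2)  # p = 155/210
#' @export
hypergeom_enrichment <- function(N, G, D, O) {
  for (v in list(N = N, G = G, D = D, O = O))
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("counts must be single non-negative integers", call. = FALSE)
  if (G > N || D > N || O > min(G, D))
    stop("inconsistent counts: need O <= min(G, D) and G, D <= N",
         call. = FALSE)
  p <- stats::phyper(O - 1, G, N - G, D, lower.tail = FALSE)
  or <- if (D > 0 && G > 0) (O / D) / (G / N) else NA_real_
  structure(list(N = N, G = G, D = D, O = O, p_enrich = p, odds_ratio = or),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, digits = 4, ...) {
  cat(sprintf("Enrichment: %d of %d significant genes in a gold standard of %d (N = %d)\n",
              x$O, x$D, x$G, x$N))
  cat(sprintf("  p = %s, odds ratio = %s\n",
              format(x$p_enrich, digits = digits),
              format(x$odds_ratio, digits = digits)))
  invisible(x)
}
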