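#' Configuration for the multi-study RNA-seq simulation
#'
#' Describes the negative-binomial simulation used to benchmark the
#' combiners on multi-study differential-expression meta-analysis:
#' `n_studies` count datasets over the same genes, of which only
#' `n_assoc_studies` carry differential expression (incomplete
#' association).  In associated studies a fixed fraction of genes is
#' differentially expressed with fold changes at or above
#' `min_fold_change`, with a random direction per gene that is consistent
#' across the associated studies; unassociated studies are pure null.
#'
#' Per-gene baseline means are drawn log-normally and per-gene dispersions
#' follow a decreasing mean-dispersion trend with multiplicative gamma
#' noise, emulating the overdispersion structure of deeply sequenced bulk
#' tumour/normal datasets.  Fold changes are drawn log-uniformly between
#' `min_fold_change` and `max_fold_change`.
#'
#' @param n_genes Number of genes (benchmark: 1000).
#' @param n_studies Number of studies (benchmark: 20).
#' @param n_assoc_studies Number of associated studies (benchmark: 2, 5, 10).
#' @param de_fraction Fraction of genes differentially expressed in the
#'   associated studies (benchmark: 0.10, 0.30, 0.60).
#' @param min_fold_change Minimum fold change for DE genes (benchmark: 1.3).
#' @param max_fold_change Upper end of the log-uniform fold-change draw.
#' @param samples_per_group Samples per condition group in every study.
#' @param mean_log_mu,mean_log_sd Location and scale of the log-normal
#'   baseline-mean draw (natural-log scale).
#' @param disp_intercept,disp_slope Mean-dispersion trend
#'   `disp = disp_intercept + disp_slope / mean`, jittered per gene by a
#'   Gamma(shape 10, mean 1) factor.
#' @param reps Number of simulation replicates.
#' @param seed Integer seed recorded with the configuration.
#' @return A list of class `rnaseq_sim_config`.
#' @examples
#' cfg <- rnaseq_sim_config(n_genes = 100, n_assoc_studies = 2, seed = 5)
#' @export
rnaseq_sim_config <- function(n_genes = 1000, n_studies = 20,
                              n_assoc_studies = 2, de_fraction = 0.30,
                              min_fold_change = 1.3, max_fold_change = 4,
                              samples_per_group = 10,
                              mean_log_mu = 4, mean_log_sd = 1.5,
                              disp_intercept = 0.15, disp_slope = 2,
                              reps = 10, seed = 1L) {
  stopifnot(n_genes >= 2, n_studies >= 1, samples_per_group >= 2, reps >= 1)
  if (n_assoc_studies > n_studies)
    stop("'n_assoc_studies' cannot exceed 'n_studies'", call. = FALSE)
  if (de_fraction <= 0 || de_fraction >= 1)
    stop("'de_fraction' must lie in (0, 1)", call. = FALSE)
  if (min_fold_change <= 1 || max_fold_change < min_fold_change)
    stop("fold changes must satisfy 1 < min <= max", call. = FALSE)
  structure(list(n_genes = n_genes, n_studies = n_studies,
                 n_assoc_studies = n_assoc_studies,
                 de_fraction = de_fraction,
                 min_fold_change = min_fold_change,
                 max_fold_change = max_fold_change,
                 samples_per_group = samples_per_group,
                 mean_log_mu = mean_log_mu, mean_log_sd = mean_log_sd,
                 disp_intercept = disp_intercept, disp_slope = disp_slope,
                 reps = reps, seed = as.integer(seed)),
            class = "rnaseq_sim_config")
}

#' Simulate one replicate of the multi-study RNA-seq design
#'
#' Generates one negative-binomial count matrix per study (genes x
#' samples, two equal groups) under the configuration.  Exactly
#' `round(de_fraction * n_genes)` genes are differentially expressed in
#' every associated study: their group-2 means are multiplied (or divided,
#' by the gene's random direction) by the gene's fold change.  Randomness
#' comes from the session RNG; seed it for reproducibility.
#'
#' @param cfg An [rnaseq_sim_config()].
#' @return A list with `counts` (list of integer matrices, one per study),
#'   `groups` (factor of length `2 * samples_per_group`), `truth` (logical
#'   per gene: differentially expressed in the associated studies),
#'   `assoc_studies` (indices of the associated studies), `direction`
#'   (per-gene sign of the imposed log-fold-change, 0 for non-DE genes),
#'   and `fold_change` (per-gene fold change, 1 for non-DE genes).
#' @examples
#' set.seed(1)
#' sim <- simulate_rnaseq_meta(rnaseq_sim_config(n_genes = 50, n_studies = 3,
#'                                               n_assoc_studies = 1))
#' @export
simulate_rnaseq_meta <- function(cfg) {
  stopifnot(inherits(cfg, "rnaseq_sim_config"))
  g <- cfg$n_genes
  mu <- exp(stats::rnorm(g, cfg$mean_log_mu, cfg$mean_log_sd))
  disp <- (cfg$disp_intercept + cfg$disp_slope / mu) *
    stats::rgamma(g, shape = 10, rate = 10)
  n_de <- round(cfg$de_fraction * g)
  de <- sample.int(g, n_de)
  truth <- logical(g); truth[de] <- TRUE
  direction <- integer(g)
  direction[de] <- sample(c(-1L, 1L), n_de, replace = TRUE)
  fc <- rep(1, g)
  fc[de] <- exp(stats::runif(n_de, log(cfg$min_fold_change),
                             log(cfg$max_fold_change)))
  assoc <- sort(sample.int(cfg$n_studies, cfg$n_assoc_studies))
  spg <- cfg$samples_per_group
  groups <- factor(rep(c("g1", "g2"), each = spg))
  counts <- vector("list", cfg$n_studies)
  for (s in seq_len(cfg$n_studies)) {
    mu2 <- if (s %in% assoc) mu * fc^direction else mu
    m1 <- matrix(stats::rnbinom(g * spg, mu = mu, size = 1 / disp), g, spg)
    m2 <- matrix(stats::rnbinom(g * spg, mu = mu2, size = 1 / disp), g, spg)
    counts[[s]] <- cbind(m1, m2)
  }
  list(counts = counts, groups = groups, truth = truth,
       assoc_studies = assoc, direction = direction, fold_change = fc)
}

#' Per-study differential-expression test
#'
#' Gene-wise Welch t-test on `log2(CPM + 0.5)` between the two groups of
#' one study, returning the two-tailed p-value, the sign of the estimated
#' difference (group 2 minus group 1), and the difference estimate with
#' its standard error for the effect-size meta-analysis baselines.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Two-level factor (or vector) over the columns; each group
#'   needs at least two samples.
#' @return A data frame with one row per gene: `p`, `sign`, `beta`
#'   (log2-CPM difference), `se`, `df`.
#' @examples
#' set.seed(1)
#' cts <- matrix(rnbinom(200, mu = 50, size = 5), 20, 10)
#' de <- per_study_de_test(cts, rep(c("a", "b"), each = 5))
#' @export
per_study_de_test <- function(counts, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("'groups' must have exactly two levels", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("each group needs at least two samples", call. = FALSE)
  if (ncol(counts) != length(groups))
    stop("'groups' must match the columns of 'counts'", call. = FALSE)
  lib <- pmax(colSums(counts), 1)
  y <- log2(sweep(counts, 2, lib, "/") * 1e6 + 0.5)
  i1 <- groups == levels(groups)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, !i1, drop = FALSE])
  v1 <- rowSums((y[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((y[, !i1, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  beta <- m2 - m1
  # Welch-Satterthwaite df; degenerate zero-variance genes get p = 1
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               1)
  tt <- ifelse(se2 > 0, beta / sqrt(se2), 0)
  p <- 2 * stats::pt(-abs(tt), df = df)
  data.frame(p = p, sign = ifelse(beta >= 0, 1L, -1L), beta = beta,
             se = sqrt(pmax(se2, 1e-12)), df = df)
}

#' Multi-study RNA-seq meta-analysis benchmark
#'
#' Runs the full pipeline `cfg$reps` times: simulate the studies, test
#' every gene in every study, combine the per-gene evidence with each
#' method (two-tailed p-values and signs through the directional wrapper,
#' per-study total sample sizes as weights; effect-size methods pool the
#' per-study estimates), and score each method against the simulated truth
#' with AUC, TPR, and realised FDR at BH `q < 0.05`.
#'
#' @param cfg An [rnaseq_sim_config()]; its `seed` is set before the first
#'   replicate.
#' @param methods Method tags: any registered combiner plus `"fem"` and
#'   `"rem"`.
#' @param rop_order Order handed to the `"rop"` method (default half the
#'   associated-study count, at least 2).
#' @return A data frame with one row per replicate x method: `rep`,
#'   `method`, `auc`, `tpr`, `true_fdr`, `n_significant`.
#' @examples
#' cfg <- rnaseq_sim_config(n_genes = 60, n_studies = 4, n_assoc_studies = 2,
#'                          samples_per_group = 4, reps = 1, seed = 2)
#' run_rnaseq_meta_experiment(cfg, methods = c("fisher", "fem"))
#' @export
run_rnaseq_meta_experiment <- function(cfg,
                                       methods = c("wfisher", "ordmeta",
                                                   "fisher", "stouffer", "wz",
                                                   "lancaster", "fem", "rem"),
                                       rop_order = NULL) {
  stopifnot(inherits(cfg, "rnaseq_sim_config"))
  set.seed(cfg$seed)
  study_n <- 2 * cfg$samples_per_group
  if (is.null(rop_order)) rop_order <- max(2L, cfg$n_assoc_studies %/% 2L)
  out <- list()
  for (rep in seq_len(cfg$reps)) {
    sim <- simulate_rnaseq_meta(cfg)
    tests <- lapply(sim$counts, per_study_de_test, groups = sim$groups)
    P <- sapply(tests, `[[`, "p")          # genes x studies
    S <- sapply(tests, `[[`, "sign")
    B <- sapply(tests, `[[`, "beta")
    E <- sapply(tests, `[[`, "se")
    sizes <- rep(study_n, cfg$n_studies)
    for (method in methods) {
      lp <- vapply(seq_len(cfg$n_genes), function(gi) {
        if (method == "fem") {
          log(fixed_effect_meta(B[gi, ], E[gi, ])$p)
        } else if (method == "rem") {
          log(random_effect_meta(B[gi, ], E[gi, ])$p)
        } else {
          suppressWarnings(
            combine_directional(P[gi, ], sign = S[gi, ], method = method,
                                n = sizes, r = rop_order))$log_p
        }
      }, numeric(1))
      p <- exp(lp)
      q <- bh_qvalues(p)
      metr <- tpr_truefdr(q, sim$truth, cutoff = 0.05)
      out[[length(out) + 1L]] <- data.frame(
        rep = rep, method = method,
        auc = auc_score(-lp, sim$truth),
        tpr = metr$tpr, true_fdr = metr$true_fdr,
        n_significant = metr$n_significant)
    }
  }
  do.call(rbind, out)
}
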