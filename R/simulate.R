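#' Configuration for the t-test simulation study
#'
#' Describes one scenario of the one-sample t-test simulation used to
#' benchmark the combiners: a set of associated p-values (p1-values) from
#' t-tests with a small positive mean, optionally diluted with unassociated
#' p-values (p0-values) drawn uniformly from a sub-interval of `[0, 1]`.
#'
#' Defaults mirror the benchmark design: per associated study the sample
#' size is drawn uniformly from 30--2000 and the true mean uniformly
#' from 0.03--0.1 (standard-normal noise), the one-tailed t-test p-value is
#' recorded together with the sample size, and up to 30 unassociated
#' p-values are appended from one of the intervals `[0, 1]`, `[0.1, 1]`,
#' `[0.3, 1]`.
#'
#' @param n_assoc Number of associated p-values (benchmarks use 2, 4, 8).
#' @param n_unassoc_max Maximum number of appended unassociated p-values.
#' @param sample_size_range Range for the per-study sample sizes
#'   (uniform draw).
#' @param mean_range Range for the per-study true means (uniform draw).
#' @param p0_interval Interval the unassociated p-values are drawn from.
#' @param reps Number of simulation replicates.
#' @param alpha_power Significance cutoff used when measuring power.
#' @param alpha_type1 Significance cutoff used when measuring type-I error.
#' @param seed Integer seed recorded with the configuration.
#' @return A list of class `ttest_sim_config`.
#' @examples
#' cfg <- ttest_sim_config(n_assoc = 4, reps = 100, seed = 7)
#' @export
ttest_sim_config <- function(n_assoc = 4, n_unassoc_max = 30,
                             sample_size_range = c(30, 2000),
                             mean_range = c(0.03, 0.1),
                             p0_interval = c(0, 1),
                             reps = 1000, alpha_power = 0.01,
                             alpha_type1 = 0.05, seed = 1L) {
  stopifnot(n_assoc >= 0, n_unassoc_max >= 0, reps >= 1,
            length(sample_size_range) == 2, length(mean_range) == 2,
            length(p0_interval) == 2)
  if (diff(sample_size_range) < 0 || sample_size_range[1] < 2)
    stop("'sample_size_range' must be increasing with lower end >= 2",
         call. = FALSE)
  if (diff(mean_range) < 0)
    stop("'mean_range' must be non-decreasing", call. = FALSE)
  if (p0_interval[1] < 0 || p0_interval[2] > 1 || diff(p0_interval) <= 0)
    stop("'p0_interval' must be a non-degenerate sub-interval of [0, 1]",
         call. = FALSE)
  structure(list(n_assoc = n_assoc, n_unassoc_max = n_unassoc_max,
                 sample_size_range = sample_size_range,
                 mean_range = mean_range, p0_interval = p0_interval,
                 reps = reps, alpha_power = alpha_power,
                 alpha_type1 = alpha_type1, seed = as.integer(seed)),
            class = "ttest_sim_config")
}

# one-tailed one-sample t-test p-values for n_assoc associated studies;
# the t statistic is simulated exactly through its sufficient statistics
# (xbar ~ N(mu, 1/s), (s-1) sd^2 ~ chi-squared(s-1)) rather than by
# generating the s raw normals
draw_p1 <- function(n_assoc, sizes, means) {
  xbar <- stats::rnorm(n_assoc, mean = means, sd = 1 / sqrt(sizes))
  sdev <- sqrt(stats::rchisq(n_assoc, df = sizes - 1) / (sizes - 1))
  tstat <- xbar / (sdev / sqrt(sizes))
  stats::pt(tstat, df = sizes - 1, lower.tail = FALSE)
}

draw_sizes <- function(k, range) {
  round(stats::runif(k, range[1], range[2]))
}

#' Draw one replicate of the t-test simulation
#'
#' Generates `cfg$n_assoc` associated one-tailed p-values from one-sample
#' t-tests (sample size and true mean drawn per study from the configured
#' ranges) and `m0` unassociated p-values drawn uniformly from
#' `cfg$p0_interval`, together with the per-study sample sizes the weighted
#' combiners use.  Randomness comes from the R session RNG; call
#' `set.seed()` (e.g. with `cfg$seed`) for reproducibility.
#'
#' @param cfg A [ttest_sim_config()].
#' @param m0 Number of unassociated p-values to append (defaults to the
#'   configured maximum).
#' @return A list with `p` (associated first, then unassociated), `sizes`,
#'   and `truth` (logical: `TRUE` for the associated positions), plus the
#'   drawn `means` for the associated studies.
#' @examples
#' set.seed(1)
#' sim <- simulate_ttest_pvalues(ttest_sim_config(n_assoc = 2), m0 = 3)
#' @export
simulate_ttest_pvalues <- function(cfg, m0 = cfg$n_unassoc_max) {
  stopifnot(inherits(cfg, "ttest_sim_config"))
  sizes1 <- draw_sizes(cfg$n_assoc, cfg$sample_size_range)
  means <- stats::runif(cfg$n_assoc, cfg$mean_range[1], cfg$mean_range[2])
  p1 <- if (cfg$n_assoc > 0) draw_p1(cfg$n_assoc, sizes1, means) else numeric(0)
  p0 <- stats::runif(m0, cfg$p0_interval[1], cfg$p0_interval[2])
  sizes0 <- draw_sizes(m0, cfg$sample_size_range)
  list(p = c(p1, p0), sizes = c(sizes1, sizes0),
       truth = rep(c(TRUE, FALSE), c(cfg$n_assoc, m0)), means = means)
}

# ---------------------------------------------------------------------------
# vectorised combination kernels over a replicate matrix --------------------

# P: reps x m matrix of one-tailed p-values, one replicate per row; sizes
# (length m) are shared across replicates.  Must agree with the per-vector
# combiners -- asserted in the test suite.
combine_matrix <- function(P, method, sizes = NULL, df = NULL, r = NULL) {
  reps <- nrow(P); m <- ncol(P)
  P[P < .p_floor] <- .p_floor
  P[P > .p_ceiling] <- .p_ceiling
  switch(method,
    fisher = exp(stats::pchisq(-2 * rowSums(log(P)), df = 2 * m,
                               lower.tail = FALSE, log.p = TRUE)),
    z = ,
    stouffer = {
      Z <- rowSums(stats::qnorm(P, lower.tail = FALSE))
      exp(stats::pnorm(Z / sqrt(m), lower.tail = FALSE, log.p = TRUE))
    },
    weighted_z = ,
    wz = {
      w <- sqrt(need_sizes(sizes, m, method))
      Z <- as.vector(stats::qnorm(P, lower.tail = FALSE) %*% w)
      exp(stats::pnorm(Z / sqrt(sum(w^2)), lower.tail = FALSE, log.p = TRUE))
    },
    lancaster = {
      d <- if (is.null(df)) need_sizes(sizes, m, method) else df
      X <- stats::qgamma(P, shape = rep(d / 2, each = reps), scale = 2,
                         lower.tail = FALSE)
      exp(stats::pgamma(rowSums(matrix(X, reps, m)), shape = sum(d) / 2,
                        scale = 2, lower.tail = FALSE, log.p = TRUE))
    },
    wfisher = {
      s <- need_sizes(sizes, m, method)
      k <- m * s / sum(s)
      X <- stats::qgamma(P, shape = rep(k, each = reps), scale = 2,
                         lower.tail = FALSE)
      exp(stats::pgamma(rowSums(matrix(X, reps, m)), shape = m, scale = 2,
                        lower.tail = FALSE, log.p = TRUE))
    },
    rop = {
      Ps <- row_sort(P)
      check_rank(r, m)
      stats::pbeta(Ps[, r], r, m - r + 1)
    },
    ordmeta = {
      Ps <- row_sort(P)
      lmarg <- stats::pbeta(Ps, rep(seq_len(m), each = reps),
                            rep(m:1, each = reps), log.p = TRUE)
      dim(lmarg) <- c(reps, m)
      X <- exp(do.call(pmin, as.data.frame(lmarg)))
      vapply(X, function(x) {
        q <- crossing_prob(order_bounds(x, m))
        min(max(q, x), 1)
      }, numeric(1))
    },
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  )
}

need_sizes <- function(sizes, m, method) {
  if (is.null(sizes))
    stop(sprintf("method '%s' needs per-study sample sizes", method),
         call. = FALSE)
  if (length(sizes) == 1L) sizes <- rep(sizes, m)
  stopifnot(length(sizes) == m, all(sizes > 0))
  sizes
}

row_sort <- function(P) {
  if (ncol(P) == 1L) return(P)
  t(apply(P, 1L, sort))
}

# ---------------------------------------------------------------------------
# experiment drivers --------------------------------------------------------

#' Type-I error of the combiners under the global null
#'
#' Draws `reps` replicates of `m` unassociated p-values (uniform on
#' `[0, 1]`, the null distribution of a one-tailed zero-effect t-test) for
#' each `m` in `m_values`, combines every replicate with each method, and
#' reports the fraction of combined p-values below `alpha`.  All methods
#' see the same replicates; the weighted methods are given equal sample
#' sizes, under which their null distributions are exact.
#'
#' @param m_values Numbers of combined p-values (benchmark: 2, 10, 30, 100).
#' @param reps Replicates per cell (benchmark: 100000).
#' @param methods Method tags to evaluate.
#' @param alpha Significance cutoff for the rate.
#' @param sample_size Common sample size handed to the weighted methods.
#' @param seed Optional seed set before the draws.
#' @param ordmeta_reps Optional smaller replicate count for the (more
#'   expensive) exact order-statistic method; its rows are the leading
#'   subset of the shared replicates.
#' @return A data frame with columns `method`, `n_pvalues`, `reps`, and
#'   `rate`.
#' @examples
#' run_type1_experiment(m_values = 2, reps = 2000, seed = 1)
#' @export
run_type1_experiment <- function(m_values = c(2, 10, 30, 100), reps = 1e5,
                                 methods = c("wfisher", "ordmeta", "stouffer",
                                             "wz", "lancaster", "fisher"),
                                 alpha = 0.05, sample_size = 50, seed = NULL,
                                 ordmeta_reps = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (m in m_values) {
    P <- matrix(stats::runif(reps * m), reps, m)
    for (method in methods) {
      use <- if (identical(method, "ordmeta") && !is.null(ordmeta_reps))
        min(ordmeta_reps, reps) else reps
      pc <- combine_matrix(P[seq_len(use), , drop = FALSE], method,
                           sizes = sample_size)
      out[[length(out) + 1L]] <- data.frame(
        method = method, n_pvalues = m, reps = use, rate = mean(pc < alpha))
    }
  }
  do.call(rbind, out)
}

#' Power of the combiners as unassociated p-values are added
#'
#' For each replicate, draws `cfg$n_assoc` associated p-values and a pool
#' of `cfg$n_unassoc_max` unassociated p-values, then measures each
#' method's power (fraction of replicates with combined p below
#' `cfg$alpha_power`) when the first `m0` pool members are appended, for
#' every `m0` in `m0_values`.  Within a replicate the pool is nested, so
#' power traces across `m0` are computed on matched draws.
#'
#' @param cfg A [ttest_sim_config()]; its `seed` is set before simulation.
#' @param methods Method tags to evaluate.
#' @param m0_values Numbers of appended unassociated p-values.
#' @return A data frame with columns `method`, `n_assoc`, `m0`,
#'   `p0_interval`, `reps`, and `power`.
#' @examples
#' cfg <- ttest_sim_config(n_assoc = 2, n_unassoc_max = 4, reps = 50)
#' run_power_experiment(cfg, methods = c("fisher", "ordmeta"),
#'                      m0_values = c(0, 4))
#' @export
run_power_experiment <- function(cfg,
                                 methods = c("wfisher", "ordmeta", "stouffer",
                                             "wz", "lancaster", "fisher"),
                                 m0_values = seq(0, cfg$n_unassoc_max, by = 5)) {
  stopifnot(inherits(cfg, "ttest_sim_config"))
  for (method in methods) lookup_combiner(method)
  set.seed(cfg$seed)
  hits <- array(0L, dim = c(length(methods), length(m0_values)),
                dimnames = list(methods, m0_values))
  for (rep in seq_len(cfg$reps)) {
    sim <- simulate_ttest_pvalues(cfg, m0 = cfg$n_unassoc_max)
    for (j in seq_along(m0_values)) {
      idx <- c(seq_len(cfg$n_assoc), cfg$n_assoc + seq_len(m0_values[j]))
      p <- sim$p[idx]; sz <- sim$sizes[idx]
      for (i in seq_along(methods)) {
        pc <- suppressWarnings(
          combine_pvalues(p, method = methods[i], n = sz))$p
        if (pc < cfg$alpha_power) hits[i, j] <- hits[i, j] + 1L
      }
    }
  }
  out <- expand.grid(method = methods, m0 = m0_values,
                     stringsAsFactors = FALSE)
  out$n_assoc <- cfg$n_assoc
  out$p0_interval <- sprintf("[%g, %g]", cfg$p0_interval[1], cfg$p0_interval[2])
  out$reps <- cfg$reps
  out$power <- as.vector(hits[cbind(match(out$method, methods),
                                    match(out$m0, m0_values))]) / cfg$reps
  out[order(out$method, out$m0), c("method", "n_assoc", "m0", "p0_interval",
                                   "reps", "power")]
}

#' Sensitivity and specificity of the predicted-associated mask
#'
#' Simulates evidence vectors in which exactly half of the `n_inputs`
#' p-values are associated (t-test draws as in [simulate_ttest_pvalues()])
#' and half are uniform nulls, applies [predict_associated()], and records
#' per-replicate sensitivity (associated inputs flagged) and specificity
#' (null inputs not flagged).
#'
#' @param n_inputs Total numbers of combined p-values to test (half
#'   associated each).
#' @param reps Replicates per setting.
#' @param cfg A [ttest_sim_config()] supplying the ranges and seed; its
#'   `n_assoc` and `n_unassoc_max` are overridden per setting.
#' @return A data frame with columns `n_inputs`, `rep`, `sensitivity`,
#'   `specificity`.
#' @examples
#' run_prediction_experiment(n_inputs = 10, reps = 20,
#'                           cfg = ttest_sim_config(seed = 3))
#' @export
run_prediction_experiment <- function(n_inputs = c(10, 30, 100), reps = 100,
                                      cfg = ttest_sim_config()) {
  stopifnot(inherits(cfg, "ttest_sim_config"), all(n_inputs %% 2 == 0))
  set.seed(cfg$seed)
  out <- list()
  for (n in n_inputs) {
    half <- n %/% 2
    cfg_n <- cfg
    cfg_n$n_assoc <- half
    cfg_n$p0_interval <- c(0, 1)
    for (rep in seq_len(reps)) {
      sim <- simulate_ttest_pvalues(cfg_n, m0 = half)
      mask <- suppressWarnings(predict_associated(sim$p))
      out[[length(out) + 1L]] <- data.frame(
        n_inputs = n, rep = rep,
        sensitivity = mean(mask[sim$truth]),
        specificity = mean(!mask[!sim$truth]))
    }
  }
  do.call(rbind, out)
}
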