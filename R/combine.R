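#' Fisher's method
#'
#' Combines one-tailed p-values with Fisher's classical statistic
#' \eqn{T = -2 \sum_i \log p_i}, referred to a chi-squared distribution
#' with \eqn{2n} degrees of freedom.  The upper-tail probability is
#' evaluated in log space, so the combined p-value stays non-zero for
#' inputs down to the clamp floor.
#'
#' @param p Numeric vector of one-tailed p-values, or a [study_evidence()]
#'   object.
#' @param ... Passed to [study_evidence()] (e.g. `feature_id`).
#' @return A `combined_p` object with elements `p`, `log_p`, `statistic`
#'   (the observed `T`), `df_total` (`2n`), and `n_studies`.
#' @examples
#' fisher_combine(c(0.1, 0.1))$p  # 0.05605
#' @seealso [wfisher_combine()] for the sample-size-weighted variant.
#' @export
fisher_combine <- function(p, ...) {
  ev <- as_evidence(p, ..., method = "fisher")
  m <- length(ev$p)
  stat <- -2 * sum(log(ev$p))
  lp <- stats::pchisq(stat, df = 2 * m, lower.tail = FALSE, log.p = TRUE)
  combined_result("fisher", exp(lp), statistic = stat, df_total = 2 * m,
                  n_studies = m, log_p = lp)
}

#' Stouffer's Z-method
#'
#' Combines one-tailed p-values through inverse-normal transforms:
#' \eqn{Z = \sum_i \Phi^{-1}(1 - p_i) / \sqrt{n}}, referred to the standard
#' normal upper tail.
#'
#' @inheritParams fisher_combine
#' @return A `combined_p` object; `statistic` is the pooled Z.
#' @examples
#' stouffer_combine(c(0.025, 0.025))
#' @export
stouffer_combine <- function(p, ...) {
  ev <- as_evidence(p, ..., method = "stouffer")
  m <- length(ev$p)
  z <- stats::qnorm(log(ev$p), lower.tail = FALSE, log.p = TRUE)
  stat <- sum(z) / sqrt(m)
  lp <- stats::pnorm(stat, lower.tail = FALSE, log.p = TRUE)
  combined_result("stouffer", exp(lp), statistic = stat, n_studies = m,
                  log_p = lp)
}

#' Weighted Z-method
#'
#' Stouffer's method with per-study weights
#' \eqn{Z = \sum_i w_i \Phi^{-1}(1 - p_i) / \sqrt{\sum_i w_i^2}}.  The
#' default weights are \eqn{w_i = \sqrt{s_i}} for sample sizes \eqn{s_i},
#' the standard sample-size weighting; arbitrary positive weights can be
#' supplied instead.
#'
#' @inheritParams fisher_combine
#' @param n Positive per-study sample sizes (required unless `weights` is
#'   given).
#' @param weights Optional explicit positive weights overriding the
#'   `sqrt(n)` default.
#' @return A `combined_p` object; `statistic` is the weighted Z.
#' @examples
#' weighted_z_combine(c(0.01, 0.5), n = c(400, 100))
#' @export
weighted_z_combine <- function(p, n = NULL, weights = NULL, ...) {
  ev <- as_evidence(p, n = n, ..., need_n = is.null(weights),
                    method = "weighted Z")
  m <- length(ev$p)
  w <- if (is.null(weights)) sqrt(ev$n) else weights
  if (length(w) != m || any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and one per retained study", call. = FALSE)
  z <- stats::qnorm(log(ev$p), lower.tail = FALSE, log.p = TRUE)
  stat <- sum(w * z) / sqrt(sum(w^2))
  lp <- stats::pnorm(stat, lower.tail = FALSE, log.p = TRUE)
  combined_result("weighted_z", exp(lp), statistic = stat, n_studies = m,
                  log_p = lp)
}

#' Lancaster's method
#'
#' Generalises Fisher's method by giving study \eqn{i} a chi-squared
#' transform with `df[i]` degrees of freedom (sample sizes by default):
#' each p-value is mapped to the chi-squared value whose upper-tail
#' probability equals it, and the sum is referred to the upper tail of a
#' chi-squared distribution with \eqn{S = \sum_i df_i} degrees of freedom.
#' Non-integer degrees of freedom are handled through the equivalent gamma
#' distribution (shape `df/2`, scale 2) rather than rounded.
#'
#' @inheritParams fisher_combine
#' @param n Per-study sample sizes, used as the default degrees of freedom.
#' @param df Optional explicit positive degrees of freedom per study.
#' @return A `combined_p` object; `df_total` is `sum(df)`.
#' @examples
#' lancaster_combine(c(0.1, 0.1), n = c(30, 60))
#' lancaster_combine(c(0.1, 0.1), df = c(2, 2))$p  # == Fisher
#' @export
lancaster_combine <- function(p, n = NULL, df = NULL, ...) {
  ev <- as_evidence(p, n = n, ..., need_n = is.null(df), method = "lancaster")
  m <- length(ev$p)
  d <- if (is.null(df)) ev$n else df
  if (length(d) != m || any(!is.finite(d)) || any(d <= 0))
    stop("degrees of freedom must be positive, one per retained study",
         call. = FALSE)
  x <- stats::qgamma(log(ev$p), shape = d / 2, scale = 2,
                     lower.tail = FALSE, log.p = TRUE)
  stat <- sum(x)
  lp <- stats::pgamma(stat, shape = sum(d) / 2, scale = 2,
                      lower.tail = FALSE, log.p = TRUE)
  combined_result("lancaster", exp(lp), statistic = stat, df_total = sum(d),
                  n_studies = m, log_p = lp)
}

#' Weighted Fisher's method (wFisher)
#'
#' Sample-size-weighted generalisation of Fisher's method.  Each p-value is
#' transformed to a gamma variable with shape \eqn{k_i = n s_i / S}
#' (\eqn{S = \sum_j s_j}) and scale 2 -- the value whose gamma upper-tail
#' probability equals \eqn{p_i} -- so the shapes sum to \eqn{n} and the
#' total degrees of freedom stay at \eqn{2n}, as in Fisher's method.  The
#' summed statistic is referred to the upper tail of a gamma distribution
#' with shape \eqn{n} and scale 2 (equivalently chi-squared with \eqn{2n}
#' df).  With equal sample sizes every \eqn{k_i = 1} and the method reduces
#' exactly to [fisher_combine()].
#'
#' @inheritParams fisher_combine
#' @param n Positive per-study sample sizes (required).  Missing-p studies
#'   are dropped first and the shapes renormalised over the survivors.
#' @param k_floor Lower bound applied to the gamma shapes; a study whose
#'   relative sample size drives its shape below the floor is clamped up
#'   with a warning (the quantile transform degenerates at shape 0).
#' @return A `combined_p` object; `statistic` is the gamma-variable sum,
#'   `df_total` is `2n`.
#' @examples
#' wfisher_combine(c(0.01, 0.5), n = c(100, 50))
#' wfisher_combine(c(0.1, 0.1), n = c(50, 50))$p  # equal sizes: Fisher
#' @export
wfisher_combine <- function(p, n = NULL, k_floor = 1e-4, ...) {
  ev <- as_evidence(p, n = n, ..., need_n = TRUE, method = "wfisher")
  m <- length(ev$p)
  k <- m * ev$n / sum(ev$n)
  if (any(k < k_floor)) {
    warning(sprintf("%d gamma shape(s) below %g clamped to the floor",
                    sum(k < k_floor), k_floor), call. = FALSE)
    k <- pmax(k, k_floor)
  }
  x <- stats::qgamma(log(ev$p), shape = k, scale = 2,
                     lower.tail = FALSE, log.p = TRUE)
  stat <- sum(x)
  lp <- stats::pgamma(stat, shape = m, scale = 2,
                      lower.tail = FALSE, log.p = TRUE)
  combined_result("wfisher", exp(lp), statistic = stat, df_total = 2 * m,
                  n_studies = m, log_p = lp,
                  extras = list(shape = k))
}

# ---------------------------------------------------------------------------
# method registry -----------------------------------------------------------

# each entry: fn(ev_p, n, df, r) -> combined_p; needs_n marks weighted methods
.combiner_registry <- list(
  fisher    = function(p, n, df, r) fisher_combine(p),
  stouffer  = function(p, n, df, r) stouffer_combine(p),
  z         = function(p, n, df, r) stouffer_combine(p),
  wz        = function(p, n, df, r) weighted_z_combine(p, n = n),
  weighted_z = function(p, n, df, r) weighted_z_combine(p, n = n),
  lancaster = function(p, n, df, r) lancaster_combine(p, n = n, df = df),
  wfisher   = function(p, n, df, r) wfisher_combine(p, n = n),
  ordmeta   = function(p, n, df, r) ordmeta_combine(p),
  rop       = function(p, n, df, r) rop_combine(p, r = r)
)

#' Registered p-value combination methods
#'
#' @return Character vector of method tags accepted by [combine_pvalues()],
#'   [combine_directional()], and [combine_table()].
#' @export
combiner_tags <- function() names(.combiner_registry)

lookup_combiner <- function(method) {
  fn <- .combiner_registry[[method]]
  if (is.null(fn))
    stop(sprintf("unknown method '%s'; registered methods: %s",
                 method, paste(combiner_tags(), collapse = ", ")),
         call. = FALSE)
  fn
}

#' Combine p-values with a named method
#'
#' Uniform front end over all registered combiners.  One-tailed p-values
#' are combined directly; two-tailed p-values with effect directions are
#' routed through [combine_directional()] when `directional = TRUE`.
#'
#' @inheritParams fisher_combine
#' @param method Method tag; see [combiner_tags()].
#' @param n Per-study sample sizes (weighted methods).
#' @param sign Per-study effect directions (directional mode).
#' @param df Per-study degrees of freedom (Lancaster).
#' @param r Order for the r-th ordered p-value method.
#' @param directional If `TRUE`, treat `p` as two-tailed and combine both
#'   effect directions (requires `sign`).
#' @return A `combined_p` object.
#' @examples
#' combine_pvalues(c(0.01, 0.2, 0.8), method = "ordmeta")
#' combine_pvalues(c(0.01, 0.2), method = "wfisher", n = c(100, 40))
#' @export
combine_pvalues <- function(p, method = "fisher", n = NULL, sign = NULL,
                            df = NULL, r = NULL, directional = FALSE) {
  if (directional)
    return(combine_directional(p, sign = sign, method = method, n = n,
                               df = df, r = r))
  fn <- lookup_combiner(method)
  fn(p, n, df, r)
}

#' Directional combination of two-tailed p-values
#'
#' Integrates two-tailed p-values whose effect directions are known.  Each
#' \eqn{p_i} is halved and synchronised to the candidate direction
#' (\eqn{p_i/2} when the study effect points with it, \eqn{1 - p_i/2}
#' otherwise); the synchronised one-tailed values are combined with the
#' requested method, the complementary values (the opposite direction) are
#' combined likewise, and the final two-tailed combined p-value is twice
#' the smaller of the two, capped at 1.
#'
#' @inheritParams combine_pvalues
#' @param sign Effect direction (+1/-1) per study; required unless
#'   `synchronized = TRUE`.
#' @param synchronized Set `TRUE` when `p` already holds one-tailed
#'   p-values synchronised to a common direction (as association summary
#'   tables sometimes report); the halving step is then skipped and `sign`
#'   is ignored.
#' @return A `combined_p` object whose `direction` element records the
#'   winning side (+1 for the direction `sign` encodes as positive) and
#'   whose method-specific extras (e.g. the ordmeta optimal order) come
#'   from the winning side.
#' @examples
#' combine_directional(c(0.01, 0.03), sign = c(1, 1), method = "fisher")
#' # synchronized one-tailed inputs:
#' combine_directional(c(0.71, 0.39, 2.8e-6, 6.5e-6), method = "ordmeta",
#'                     synchronized = TRUE)
#' @export
combine_directional <- function(p, sign = NULL, method = "fisher", n = NULL,
                                df = NULL, r = NULL, synchronized = FALSE) {
  fn <- lookup_combiner(method)
  ev <- as_evidence(p, sign = sign, n = n, need_sign = !synchronized,
                    method = method)
  u <- if (synchronized) ev$p else ifelse(ev$sign > 0, ev$p / 2, 1 - ev$p / 2)
  up <- suppressWarnings(fn(clamp_p(u, warn = FALSE), ev$n, df, r))
  dn <- suppressWarnings(fn(clamp_p(1 - u, warn = FALSE), ev$n, df, r))
  win <- if (up$p <= dn$p) up else dn
  res <- win
  res$p <- min(1, 2 * win$p)
  res$log_p <- min(0, log(2) + win$log_p)
  res$direction <- if (up$p <= dn$p) 1 else -1
  res$p_onetail <- win$p
  if (!is.null(win$p_high_precision)) {
    # doubling in log10 space for underflowed one-tailed values
    res$p_high_precision <- fmt_log10_p(log10(2) + win$log10_p)
    res$log10_p <- log10(2) + win$log10_p
  }
  res
}
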