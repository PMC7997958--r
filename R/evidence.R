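#' Per-feature study evidence
#'
#' Bundles the per-study summary statistics for one feature (a gene, SNP,
#' or other tested unit): one p-value per study, with optional effect
#' directions and per-study sample sizes.  All combiners accept either a
#' bare numeric vector of p-values or a `study_evidence` object.
#'
#' @param p Numeric vector of per-study p-values in `[0, 1]`.  Values of 0
#'   or values indistinguishable from 1 are clamped (see Details).
#' @param sign Optional integer vector of effect directions, `+1` or `-1`,
#'   one per study.  Required by [combine_directional()].
#' @param n Optional numeric vector of positive per-study sample sizes.
#'   Required by the weighted combiners ([wfisher_combine()],
#'   [weighted_z_combine()], and [lancaster_combine()] by default).
#' @param feature_id Optional label for the feature the evidence belongs to.
#'
#' @details
#' Studies with a missing (`NA`) p-value are dropped before combination and
#' any weights are renormalised over the retained studies; at least one
#' retained study is required.  Because the quantile transforms used by the
#' combiners diverge at the endpoints of `[0, 1]`, p-values below
#' `1e-320` are clamped up to `1e-320` and p-values above `1 - 1e-16` are
#' clamped down to `1 - 1e-16`, with a warning.
#'
#' @return An object of class `study_evidence`: a list with elements `p`,
#'   `sign`, `n`, `feature_id`, and `n_dropped` (number of studies removed
#'   for missing p-values).
#' @examples
#' ev <- study_evidence(p = c(0.01, 0.2, NA), n = c(100, 50, 80))
#' ev$p
#' @export
study_evidence <- function(p, sign = NULL, n = NULL, feature_id = NULL) {
  if (inherits(p, "study_evidence")) return(p)
  if (!is.numeric(p) || length(p) == 0L)
    stop("'p' must be a non-empty numeric vector of p-values", call. = FALSE)
  m <- length(p)
  if (!is.null(sign)) {
    if (length(sign) != m)
      stop("'sign' must have the same length as 'p'", call. = FALSE)
    if (!all(sign[!is.na(sign)] %in% c(-1, 1)))
      stop("'sign' entries must be +1 or -1", call. = FALSE)
  }
  if (!is.null(n)) {
    if (length(n) != m)
      stop("'n' must have the same length as 'p'", call. = FALSE)
    if (any(!is.na(n) & n <= 0))
      stop("per-study sample sizes 'n' must be positive", call. = FALSE)
  }
  keep <- !is.na(p)
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("no study with a non-missing p-value remains", call. = FALSE)
  p <- p[keep]
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  structure(list(
    p = clamp_p(p),
    sign = if (!is.null(sign)) sign[keep],
    n = if (!is.null(n)) n[keep],
    feature_id = feature_id,
    n_dropped = n_dropped
  ), class = "study_evidence")
}

# endpoint clamping shared by every combiner; quantile transforms diverge
# at 0 and 1, so the floor/ceiling keep the statistics finite
.p_floor <- 1e-320
.p_ceiling <- 1 - 1e-16

clamp_p <- function(p, warn = TRUE) {
  lo <- p < .p_floor
  hi <- p > .p_ceiling
  if (any(lo)) {
    if (warn) warning(sprintf("%d p-value(s) below %.3g clamped to the floor",
                              sum(lo), .p_floor), call. = FALSE)
    p[lo] <- .p_floor
  }
  if (any(hi)) {
    if (warn) warning(sprintf("%d p-value(s) above 1 - 1e-16 clamped", sum(hi)),
                      call. = FALSE)
    p[hi] <- .p_ceiling
  }
  p
}

#' @export
print.study_evidence <- function(x, ...) {
  cat(sprintf("Study evidence%s: %d studies\n",
              if (!is.null(x$feature_id)) paste0(" for ", x$feature_id) else "",
              length(x$p)))
  cat("  p:", format(x$p, digits = 4), "\n")
  if (!is.null(x$sign)) cat("  sign:", x$sign, "\n")
  if (!is.null(x$n)) cat("  n:", x$n, "\n")
  if (x$n_dropped > 0) cat("  (", x$n_dropped, "studies dropped: missing p )\n")
  invisible(x)
}

# internal: coerce arguments into validated study evidence, requiring
# optional fields as each combiner needs them
as_evidence <- function(p, sign = NULL, n = NULL, feature_id = NULL,
                        need_n = FALSE, need_sign = FALSE, method = "combiner") {
  ev <- study_evidence(p, sign = sign, n = n, feature_id = feature_id)
  if (need_n && is.null(ev$n))
    stop(sprintf("method '%s' weights studies by sample size: supply 'n'",
                 method), call. = FALSE)
  if (need_n && anyNA(ev$n))
    stop(sprintf("method '%s' requires a sample size for every retained study",
                 method), call. = FALSE)
  if (need_sign && (is.null(ev$sign) || anyNA(ev$sign)))
    stop(sprintf("method '%s' requires an effect direction for every study",
                 method), call. = FALSE)
  ev
}

# internal: build the container every combiner returns
combined_result <- function(method, p, statistic = NA_real_,
                            df_total = NA_real_, n_studies = NA_integer_,
                            direction = NA_real_, log_p = NULL, extras = NULL) {
  out <- list(method = method,
              p = min(max(p, 0), 1),
              log_p = if (is.null(log_p)) log(p) else log_p,
              statistic = statistic,
              df_total = df_total,
              n_studies = n_studies,
              direction = direction)
  out <- c(out, extras)
  class(out) <- c(paste0(method, "_result"), "combined_p")
  out
}

#' @export
print.combined_p <- function(x, digits = 6, ...) {
  cat(sprintf("Combined p-value (%s, %d studies)\n", x$method, x$n_studies))
  cat(sprintf("  p = %s", format(x$p, digits = digits)))
  if (x$p == 0 && !is.null(x$p_high_precision))
    cat(sprintf("  (underflow; ~%s)", x$p_high_precision))
  cat("\n")
  if (!is.na(x$statistic))
    cat(sprintf("  statistic = %s", format(x$statistic, digits = digits)),
        if (!is.na(x$df_total)) sprintf(" on %g total df", x$df_total) else "",
        "\n", sep = "")
  if (!is.na(x$direction))
    cat(sprintf("  direction = %+d\n", as.integer(x$direction)))
  if (!is.null(x$optimal_order))
    cat(sprintf("  optimal order r* = %d (min marginal %s)\n",
                x$optimal_order, format(x$min_marginal, digits = digits)))
  invisible(x)
}

#' @export
summary.combined_p <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$predicted))
    cat("  predicted associated studies:",
        paste(which(object$predicted), collapse = ", "), "\n")
  invisible(object)
}
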