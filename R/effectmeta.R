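#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools per-study effect estimates with inverse-variance weights
#' \eqn{w_i = 1/se_i^2}: the pooled estimate is
#' \eqn{\sum_i w_i \beta_i / \sum_i w_i} with standard error
#' \eqn{1/\sqrt{\sum_i w_i}}, and the two-tailed p-value comes from the
#' normal reference.  Used as a comparison baseline for the p-value
#' combiners in the simulation benchmarks.
#'
#' @param beta Numeric vector of per-study effect estimates.
#' @param se Numeric vector of positive per-study standard errors.
#' @return A list of class `effect_meta` with `method`, `estimate`, `se`,
#'   `z`, `p`, and `n_studies`.
#' @examples
#' fixed_effect_meta(beta = c(1, 2), se = c(1, 2))
#' @export
fixed_effect_meta <- function(beta, se) {
  check_effects(beta, se, min_k = 1L)
  w <- 1 / se^2
  est <- sum(w * beta) / sum(w)
  sep <- 1 / sqrt(sum(w))
  z <- est / sep
  structure(list(method = "fem", estimate = est, se = sep, z = z,
                 p = 2 * stats::pnorm(-abs(z)), tau2 = NA_real_,
                 n_studies = length(beta)),
            class = "effect_meta")
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Inverse-variance pooling with an additive between-study variance
#' \eqn{\tau^2} estimated by the DerSimonian-Laird moment estimator:
#' Cochran's \eqn{Q} is computed under fixed-effects weights and
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i))};
#' the studies are then re-pooled with weights \eqn{1/(se_i^2 + \tau^2)}.
#' Reduces to [fixed_effect_meta()] when the studies are homogeneous
#' (\eqn{\tau^2 = 0}).
#'
#' @inheritParams fixed_effect_meta
#' @return A list of class `effect_meta` as for [fixed_effect_meta()],
#'   plus `tau2` and `Q`.
#' @examples
#' random_effect_meta(beta = c(0, 2), se = c(1, 1))  # tau2 = 1
#' @export
random_effect_meta <- function(beta, se) {
  check_effects(beta, se, min_k = 2L)
  k <- length(beta)
  w <- 1 / se^2
  est_f <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - est_f)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  est <- sum(ws * beta) / sum(ws)
  sep <- 1 / sqrt(sum(ws))
  z <- est / sep
  structure(list(method = "rem", estimate = est, se = sep, z = z,
                 p = 2 * stats::pnorm(-abs(z)), tau2 = tau2, Q = Q,
                 n_studies = k),
            class = "effect_meta")
}

check_effects <- function(beta, se, min_k) {
  if (!is.numeric(beta) || !is.numeric(se) || length(beta) != length(se))
    stop("'beta' and 'se' must be numeric vectors of equal length",
         call. = FALSE)
  if (length(beta) < min_k)
    stop(sprintf("at least %d studies are required", min_k), call. = FALSE)
  if (any(!is.finite(se)) || any(se <= 0))
    stop("standard errors must be positive and finite", call. = FALSE)
  invisible(NULL)
}

#' @export
print.effect_meta <- function(x, digits = 4, ...) {
  lab <- if (x$method == "fem") "Fixed-effects" else "Random-effects (DL)"
  cat(sprintf("%s meta-analysis of %d studies\n", lab, x$n_studies))
  cat(sprintf("  estimate = %s (se %s), z = %s, p = %s\n",
              format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              format(x$z, digits = digits),
              format(x$p, digits = digits)))
  if (!is.na(x$tau2))
    cat(sprintf("  tau^2 = %s (Q = %s)\n", format(x$tau2, digits = digits),
                format(x$Q, digits = digits)))
  invisible(x)
}
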