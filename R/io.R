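#' Read a summary-statistics table
#'
#' Reads a tab-delimited summary table of per-feature, per-study evidence.
#' Two layouts are accepted:
#'
#' * **wide** -- one row per feature, with a `feature` column and per-study
#'   columns `p_<study>`, and optionally `sign_<study>`, `n_<study>`,
#'   `beta_<study>`, `se_<study>`;
#' * **long** -- columns `feature`, `study`, `p`, and optionally `sign`,
#'   `n`, `beta`, `se`, one row per feature-study pair.
#'
#' Scientific notation with a Unicode minus sign (as association tables
#' sometimes print, e.g. `2.8E−08`) is accepted alongside the ASCII
#' form.  Missing cells (empty or `NA`) are allowed; rows in which every
#' p-value is missing are dropped with a message.  Malformed numbers and
#' p-values outside `[0, 1]` are hard errors naming the offending row and
#' column.
#'
#' @param path Path to a tab-delimited text file with a header.
#' @return An object of class `summary_table`: a list with `feature_id`
#'   (character), `studies` (character), and numeric matrices `p` and
#'   (when present) `sign`, `n`, `beta`, `se`, all features x studies.
#' @examples
#' tab <- read_summary_table(system.file("extdata", "bmi_loci_synchronized.tsv",
#'                                       package = "metacomb"))
#' tab$p[1, ]
#' @export
read_summary_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = c("NA", ""))
  if (ncol(raw) < 2L)
    stop("summary table needs a header with at least two columns",
         call. = FALSE)
  cn <- names(raw)
  long <- all(c("feature", "study", "p") %in% cn)
  wide <- any(grepl("^p_", cn))
  if (!long && !wide)
    stop("unrecognised layout: need either wide 'p_<study>' columns or ",
         "long 'feature'/'study'/'p' columns", call. = FALSE)
  if (long) tab <- parse_long_table(raw) else tab <- parse_wide_table(raw)
  all_missing <- apply(tab$p, 1L, function(x) all(is.na(x)))
  if (any(all_missing)) {
    message(sprintf("dropping %d feature(s) with no non-missing p-value",
                    sum(all_missing)))
    tab <- subset_table(tab, !all_missing)
  }
  if (nrow(tab$p) == 0L)
    warning("summary table contains no usable features", call. = FALSE)
  tab
}

parse_numeric_cell <- function(x, row, col) {
  x <- gsub("−", "-", x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                 x[bad[1]], col, row[bad[1]]), call. = FALSE)
  out
}

check_p_range <- function(p, rows, col) {
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop(sprintf("p-value %g outside [0, 1] in column '%s', row %d",
                 p[bad[1]], col, rows[bad[1]]), call. = FALSE)
  p
}

parse_wide_table <- function(raw) {
  cn <- names(raw)
  fcol <- if ("feature" %in% cn) "feature" else cn[1]
  studies <- sub("^p_", "", grep("^p_", cn, value = TRUE))
  rows <- seq_len(nrow(raw))
  grab <- function(prefix, check = FALSE) {
    cols <- paste0(prefix, "_", studies)
    if (!all(cols %in% cn)) return(NULL)
    m <- matrix(NA_real_, nrow(raw), length(studies),
                dimnames = list(NULL, studies))
    for (j in seq_along(cols)) {
      v <- parse_numeric_cell(raw[[cols[j]]], rows, cols[j])
      if (check) check_p_range(v, rows, cols[j])
      m[, j] <- v
    }
    m
  }
  structure(list(feature_id = as.character(raw[[fcol]]), studies = studies,
                 p = grab("p", check = TRUE), sign = grab("sign"),
                 n = grab("n"), beta = grab("beta"), se = grab("se")),
            class = "summary_table")
}

parse_long_table <- function(raw) {
  feats <- unique(as.character(raw$feature))
  studies <- unique(as.character(raw$study))
  rows <- seq_len(nrow(raw))
  make <- function(col, check = FALSE) {
    if (!col %in% names(raw)) return(NULL)
    v <- parse_numeric_cell(raw[[col]], rows, col)
    if (check) check_p_range(v, rows, col)
    m <- matrix(NA_real_, length(feats), length(studies),
                dimnames = list(NULL, studies))
    m[cbind(match(raw$feature, feats), match(raw$study, studies))] <- v
    m
  }
  structure(list(feature_id = feats, studies = studies,
                 p = make("p", check = TRUE), sign = make("sign"),
                 n = make("n"), beta = make("beta"), se = make("se")),
            class = "summary_table")
}

subset_table <- function(tab, keep) {
  for (f in c("p", "sign", "n", "beta", "se"))
    if (!is.null(tab[[f]])) tab[[f]] <- tab[[f]][keep, , drop = FALSE]
  tab$feature_id <- tab$feature_id[keep]
  tab
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("Summary table: %d feature(s) x %d studies (%s)\n",
              nrow(x$p), length(x$studies),
              paste(x$studies, collapse = ", ")))
  opt <- c("sign", "n", "beta", "se")
  have <- opt[!vapply(x[opt], is.null, logical(1))]
  if (length(have)) cat("  extra columns:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' Write a summary table
#'
#' Writes a [read_summary_table()] object back to tab-delimited text, in
#' either layout; a write/read round trip reproduces the table.
#'
#' @param tab A `summary_table` object.
#' @param path Output path.
#' @param layout `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(tab, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(tab, "summary_table"))
  fields <- c("p", "sign", "n", "beta", "se")
  fields <- fields[!vapply(tab[fields], is.null, logical(1))]
  if (layout == "wide") {
    df <- data.frame(feature = tab$feature_id, check.names = FALSE)
    for (f in fields)
      for (s in tab$studies)
        df[[paste0(f, "_", s)]] <- tab[[f]][, s]
  } else {
    grid <- expand.grid(fi = seq_along(tab$feature_id), study = tab$studies,
                        stringsAsFactors = FALSE)
    df <- data.frame(feature = tab$feature_id[grid$fi], study = grid$study)
    for (f in fields) df[[f]] <- tab[[f]][cbind(grid$fi,
                                                match(grid$study, tab$studies))]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine every feature of a summary table
#'
#' Applies one combination method to each row of a summary table and
#' adjusts the combined p-values for multiple testing across features.
#' Studies with a missing p-value are dropped per feature (weights
#' renormalised); the weighted methods require the `n` columns and the
#' directional mode requires the `sign` columns, checked before any
#' computation.
#'
#' @param tab A `summary_table` from [read_summary_table()].
#' @param method Method tag (see [combiner_tags()]), or `"fem"`/`"rem"`
#'   for the effect-size models (requiring `beta`/`se` columns).
#' @param directional Combine two-tailed p-values with effect signs via
#'   [combine_directional()].
#' @param synchronized The table's p-values are already one-tailed and
#'   direction-synchronised; combine forward and complementary directions
#'   without halving.
#' @param r Order for the `"rop"` method.
#' @param adjust Multiple-testing adjustment across features: `"BH"`
#'   (default) or `"bonferroni"`.
#' @return A data frame with one row per feature, in the table's row
#'   order: `feature`, `method`, `p_combined`, `statistic`, `direction`,
#'   `optimal_order`, `q_value`.
#' @examples
#' tab <- read_summary_table(system.file("extdata", "bmi_loci_synchronized.tsv",
#'                                       package = "metacomb"))
#' combine_table(tab, method = "ordmeta", synchronized = TRUE)
#' @export
combine_table <- function(tab, method, directional = FALSE,
                          synchronized = FALSE, r = NULL,
                          adjust = c("BH", "bonferroni")) {
  stopifnot(inherits(tab, "summary_table"))
  adjust <- match.arg(adjust)
  effect <- method %in% c("fem", "rem")
  if (!effect) lookup_combiner(method)
  if (effect && (is.null(tab$beta) || is.null(tab$se)))
    stop(sprintf("method '%s' needs beta_* and se_* columns", method),
         call. = FALSE)
  if (!effect && method %in% c("wz", "weighted_z", "wfisher", "lancaster") &&
      is.null(tab$n))
    stop(sprintf("method '%s' weights studies by sample size: the table has no n_* columns",
                 method), call. = FALSE)
  if (directional && !synchronized && is.null(tab$sign))
    stop("directional combination needs sign_* columns", call. = FALSE)
  rows <- lapply(seq_along(tab$feature_id), function(i) {
    keep <- !is.na(tab$p[i, ])
    if (effect) {
      fit <- if (method == "fem")
        fixed_effect_meta(tab$beta[i, keep], tab$se[i, keep])
      else random_effect_meta(tab$beta[i, keep], tab$se[i, keep])
      return(data.frame(feature = tab$feature_id[i], method = method,
                        p_combined = fit$p, statistic = fit$z,
                        direction = sign(fit$estimate),
                        optimal_order = NA_integer_))
    }
    res <- suppressWarnings(
      if (directional || synchronized)
        combine_directional(tab$p[i, keep],
                            sign = if (!is.null(tab$sign)) tab$sign[i, keep],
                            method = method, n = if (!is.null(tab$n)) tab$n[i, keep],
                            r = r, synchronized = synchronized)
      else
        combine_pvalues(tab$p[i, keep], method = method,
                        n = if (!is.null(tab$n)) tab$n[i, keep], r = r))
    data.frame(feature = tab$feature_id[i], method = method,
               p_combined = res$p, statistic = res$statistic,
               direction = res$direction,
               optimal_order = if (is.null(res$optimal_order)) NA_integer_
                               else res$optimal_order)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- if (adjust == "BH") bh_qvalues(out$p_combined)
                 else pmin(1, out$p_combined * nrow(out))
  out
}
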