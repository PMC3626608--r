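#' Variance inflation and bias from adding questionable arrays
#'
#' Quantifies what it costs to keep suspect arrays in a normalization pool.
#' The reference set is quantile-normalized alone and per-feature means and
#' variances recorded; then the expanded set (reference plus added arrays) is
#' normalized from raw and the moments recomputed. Since only a minority of
#' features should be differentially expressed between comparable samples,
#' adding arrays of acceptable quality should leave per-feature moments
#' untouched — variance ratios near 1 and bias near 0 across the intensity
#' range; degraded arrays inflate variance and pull feature means.
#'
#' Features are binned by the percentile of their reference-set mean into
#' `n_bins` equal-count bins and the per-feature ratio/difference smoothed by
#' the per-bin median. Features with zero reference variance are excluded and
#' counted.
#'
#' @param Yraw An [expr_matrix()] containing both sample sets.
#' @param reference_ids,added_ids Disjoint character vectors of sample ids;
#'   at least 3 reference arrays and at least 1 added array.
#' @param n_bins Number of equal-count intensity bins (default 20).
#' @param scope After joint renormalization, compute expanded-set moments over
#'   `"all"` columns (default) or over the `"reference_only"` columns.
#' @return A `ffpe_impact` object: `summary` tibble (`bin`, `pct_lo`,
#'   `pct_hi`, `mean_intensity`, `variance_ratio`, `bias`, `n_features`),
#'   `features` tibble of per-feature values, `markers` (the 25th/50th/75th
#'   reference intensity percentiles), `n_excluded`.
#' @export
evaluate_impact <- function(Yraw, reference_ids, added_ids, n_bins = 20,
                            scope = c("all", "reference_only")) {
  scope <- match.arg(scope)
  Yraw <- validate_expr_matrix(Yraw)
  reference_ids <- as.character(reference_ids)
  added_ids <- as.character(added_ids)
  if (length(intersect(reference_ids, added_ids))) {
    stop("reference and added sample sets overlap", call. = FALSE)
  }
  if (length(added_ids) == 0L) stop("added set is empty", call. = FALSE)
  if (length(reference_ids) < 3L) stop("need at least 3 reference arrays", call. = FALSE)
  missing_ids <- setdiff(c(reference_ids, added_ids), colnames(Yraw))
  if (length(missing_ids)) {
    stop("sample ids not in matrix: ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }

  ref_norm <- quantile_normalize(Yraw[, reference_ids])$normalized
  ref_mean <- rowMeans(ref_norm)
  ref_var <- apply(ref_norm, 1, stats::var)

  exp_norm <- quantile_normalize(Yraw[, c(reference_ids, added_ids)])$normalized
  exp_cols <- if (scope == "all") colnames(exp_norm) else reference_ids
  exp_mean <- rowMeans(exp_norm[, exp_cols])
  exp_var <- apply(exp_norm[, exp_cols], 1, stats::var)

  keep <- ref_var > 0
  n_excluded <- sum(!keep)
  variance_ratio <- unname(exp_var[keep] / ref_var[keep])
  bias <- unname(exp_mean[keep] - ref_mean[keep])
  feats <- tibble::tibble(
    feature_id = rownames(Yraw)[keep],
    ref_mean = unname(ref_mean[keep]),
    variance_ratio = variance_ratio,
    bias = bias
  )
  # equal-count bins by rank of the reference mean
  edges <- seq(0, 100, length.out = n_bins + 1)
  r <- rank(feats$ref_mean, ties.method = "first")
  feats$bin <- pmin(as.integer(ceiling(r / (length(r) / n_bins))), n_bins)

  summary <- dplyr::summarise(
    dplyr::group_by(feats, .data$bin),
    pct_lo = edges[.data$bin[1]],
    pct_hi = edges[.data$bin[1] + 1],
    mean_intensity = stats::median(.data$ref_mean),
    variance_ratio = stats::median(.data$variance_ratio),
    bias = stats::median(.data$bias),
    n_features = dplyr::n(),
    .groups = "drop"
  )
  markers <- stats::quantile(feats$ref_mean, c(.25, .5, .75), type = 7)
  structure(
    list(
      summary = summary, features = feats, markers = markers,
      n_excluded = n_excluded, scope = scope,
      n_reference = length(reference_ids), n_added = length(added_ids)
    ),
    class = "ffpe_impact"
  )
}

#' @export
print.ffpe_impact <- function(x, ...) {
  cat("<ffpe_impact> ", x$n_reference, " reference + ", x$n_added,
    " added arrays (moments over ", x$scope, " columns)\n",
    sep = ""
  )
  cat(
    "  median variance ratio across bins: ",
    format(stats::median(x$summary$variance_ratio), digits = 4), "\n",
    "  median |bias| across bins: ",
    format(stats::median(abs(x$summary$bias)), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an impact evaluation
#' @param x A `ffpe_impact` object.
#' @param ... Unused.
#' @return The per-bin summary tibble.
#' @method tidy ffpe_impact
#' @export
tidy.ffpe_impact <- function(x, ...) x$summary

#' One-row summary of an impact evaluation
#' @param x A `ffpe_impact` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance ffpe_impact
#' @export
glance.ffpe_impact <- function(x, ...) {
  tibble::tibble(
    n_reference = x$n_reference,
    n_added = x$n_added,
    median_variance_ratio = stats::median(x$summary$variance_ratio),
    max_variance_ratio = max(x$summary$variance_ratio),
    median_abs_bias = stats::median(abs(x$summary$bias)),
    n_excluded = x$n_excluded
  )
}
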