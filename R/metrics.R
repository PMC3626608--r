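#' QC decision thresholds
#'
#' Bundles every cutoff used by the metrics and pipelines. Defaults follow the
#' published two-stage workflow for degraded-sample arrays: remove arrays with
#' Stress >= 1.5 (half the features moved by 50% or more during
#' normalization), investigate arrays with a 75th-percentile |dfArray| >= 2
#' (a quarter of features more than two feature-level standard deviations from
#' the consensus), distance-outlier threshold Th = 2, median NUSE 1.25, and
#' the distributional quadrant cutoffs IQR > 2 and skew > 0.2. All comparisons
#' downstream are inclusive (`>=`).
#'
#' @param stress_cut Stress removal cutoff (fold-change scale).
#' @param dfarray_cut dfArray summary cutoff (standard-deviation units).
#' @param lumi_th Distance-outlier multiplier Th.
#' @param nuse_cut Median NUSE cutoff.
#' @param dfarray_quantile Quantile used to summarize |dfArray| per array.
#' @param iqr_cut,skew_cut Quadrant-classification cutoffs on the raw-data
#'   interquartile range and skew statistic.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(stress_cut = 1.5, dfarray_cut = 2, lumi_th = 2,
                          nuse_cut = 1.25, dfarray_quantile = 0.75,
                          iqr_cut = 2, skew_cut = 0.2) {
  stopifnot(
    stress_cut > 0, dfarray_cut > 0, lumi_th > 0, nuse_cut > 0,
    dfarray_quantile > 0, dfarray_quantile < 1, iqr_cut > 0,
    skew_cut > 0, skew_cut < 1
  )
  structure(
    list(
      stress_cut = stress_cut, dfarray_cut = dfarray_cut, lumi_th = lumi_th,
      nuse_cut = nuse_cut, dfarray_quantile = dfarray_quantile,
      iqr_cut = iqr_cut, skew_cut = skew_cut
    ),
    class = "qc_thresholds"
  )
}

#' Normalization stress per array
#'
#' Stress measures how much an array had to be "stretched" during
#' normalization: for array `j`,
#' `Stress_j = 2 ^ median_i |S_ij - mean_i(S_ij)|`,
#' where `S` is the shift matrix `Y - Y'`. Centering by the array mean makes
#' the metric blind to constant per-array offsets (a uniformly brighter scan
#' is not a quality defect), and the absolute value treats up- and
#' down-adjusted features as equally stressed. The result is on the
#' fold-change scale: Stress = 2 means half of the features had to be adjusted
#' by 100% or more relative to their initial values.
#'
#' @param x A `ffpe_norm` object from [quantile_normalize()] or
#'   [feature_target_normalize()], or a numeric shift matrix (features x
#'   samples).
#' @return A tibble with columns `sample_id` and `stress` (always >= 1).
#' @examples
#' S <- matrix(c(0, 0, 1, 2, 2), ncol = 1, dimnames = list(NULL, "a"))
#' compute_stress(S) # stress = 2
#' @export
compute_stress <- function(x) {
  S <- if (inherits(x, "ffpe_norm")) x$shifts else as.matrix(x)
  if (is.null(colnames(S))) colnames(S) <- paste0("sample_", seq_len(ncol(S)))
  centered <- sweep(S, 2, colMeans(S))
  tibble::tibble(
    sample_id = colnames(S),
    stress = unname(2^apply(abs(centered), 2, stats::median))
  )
}

#' Standardized deviation of each array from the rest (dfArray)
#'
#' For each cell, dfArray standardizes the post-normalized intensity against
#' the remaining arrays' estimate of that feature:
#' `dfArray_ij = (Y'_ij - center_i(-j)) / scale_i(-j)`.
#' In `exact_loo` mode the center/scale are the leave-one-out mean and sample
#' standard deviation of the feature; in `robust` mode (the default, and far
#' cheaper at scale) they are the across-array median and the MAD scaled by
#' 1.4826 so the denominator estimates the standard deviation under
#' normality — which keeps the conventional ">= 2 standard deviations" cutoff
#' literal. The per-array summary is the `q`-quantile (default 0.75) of
#' |dfArray| over features, since deviations above and below the consensus are
#' equivalent errors.
#'
#' Zero-spread guard: when a denominator is 0, the cell is 0 if the numerator
#' is also 0 (a feature constant across arrays deviates nowhere), otherwise
#' the cell is `NA` and the feature is excluded from that array's quantile
#' summary; exclusions are counted per sample. Dead-probe floors make zero MAD
#' common in degraded data, so the guard is exercised routinely.
#'
#' @param Yprime An [expr_matrix()] of post-normalized intensities (n >= 3),
#'   or a `ffpe_norm` object (its normalized matrix is used).
#' @param mode `"robust"` (median/MAD) or `"exact_loo"` (leave-one-out
#'   mean/sd).
#' @param q Quantile for the per-array summary of |dfArray|.
#' @return A `ffpe_dfarray` list: `grid` (signed p x n matrix, NA where the
#'   guard excluded a cell), `summary` (tibble: `sample_id`, `dfarray`,
#'   `n_excluded`), `mode`, `q`.
#' @export
compute_dfarray <- function(Yprime, mode = c("robust", "exact_loo"), q = 0.75) {
  mode <- match.arg(mode)
  if (inherits(Yprime, "ffpe_norm")) Yprime <- Yprime$normalized
  m <- as_plain_matrix(validate_expr_matrix(Yprime))
  n <- ncol(m)
  if (n < 3L) stop("dfArray needs at least 3 arrays", call. = FALSE)

  if (mode == "robust") {
    center <- apply(m, 1, stats::median)
    scale <- apply(m, 1, stats::mad) # 1.4826 * median absolute deviation
    num <- m - center
    den <- matrix(scale, nrow(m), n)
  } else {
    rs <- rowSums(m)
    rss <- rowSums(m^2)
    loo_mean <- (rs - m) / (n - 1)
    # sum of squares about the leave-one-out mean, guarded against tiny
    # negative values from cancellation
    ss <- pmax(rss - m^2 - (n - 1) * loo_mean^2, 0)
    num <- m - loo_mean
    den <- sqrt(ss / (n - 2))
  }
  grid <- num / den
  zero_den <- den == 0
  grid[zero_den & num == 0] <- 0
  grid[zero_den & num != 0] <- NA_real_
  dimnames(grid) <- dimnames(m)

  summary <- tibble::tibble(
    sample_id = colnames(m),
    dfarray = unname(apply(abs(grid), 2, stats::quantile, probs = q, na.rm = TRUE, names = FALSE, type = 7)),
    n_excluded = unname(colSums(is.na(grid)))
  )
  structure(list(grid = grid, summary = summary, mode = mode, q = q),
    class = "ffpe_dfarray"
  )
}

#' @export
print.ffpe_dfarray <- function(x, ...) {
  cat("<ffpe_dfarray> mode = ", x$mode, ", summary quantile = ", x$q, "\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Relative log expression (RLE)
#'
#' Subtracts each feature's across-array median from the post-normalized
#' intensities; the per-array distribution of these residuals shows whether an
#' array sits systematically above or below the consensus. Summarized per
#' array by median and IQR.
#'
#' @inheritParams compute_dfarray
#' @return A `ffpe_rle` list: `grid` (p x n matrix) and `summary`
#'   (tibble: `sample_id`, `rle_median`, `rle_iqr`).
#' @export
compute_rle <- function(Yprime) {
  if (inherits(Yprime, "ffpe_norm")) Yprime <- Yprime$normalized
  m <- as_plain_matrix(validate_expr_matrix(Yprime))
  grid <- m - apply(m, 1, stats::median)
  summary <- tibble::tibble(
    sample_id = colnames(m),
    rle_median = unname(apply(grid, 2, stats::median)),
    rle_iqr = unname(apply(grid, 2, function(v) {
      unname(diff(stats::quantile(v, c(.25, .75), type = 7)))
    }))
  )
  structure(list(grid = grid, summary = summary), class = "ffpe_rle")
}

#' @export
print.ffpe_rle <- function(x, ...) {
  cat("<ffpe_rle>\n")
  print(x$summary, ...)
  invisible(x)
}

#' Normalized unscaled standard error (NUSE)
#'
#' Each cell's standard error is scaled by the across-array median standard
#' error of its feature: `NUSE_ij = SE_ij / median_j(SE_ij)`; the per-array
#' summary is the median over features. A median NUSE of 1.25 means the
#' array's feature-level variability runs 25% above an average array.
#' Features whose median SE is 0 (dead across the experiment) carry no
#' information and are dropped from the grid and counted.
#'
#' @param se An [se_matrix()] of per-cell standard errors.
#' @param reference Optional per-feature reference denominator (named numeric
#'   vector, one value per feature) replacing the within-experiment median —
#'   the archive-based variant for platforms where a reference collection
#'   exists.
#' @return A `ffpe_nuse` list: `grid` (rows = retained features), `summary`
#'   (tibble: `sample_id`, `nuse_median`), `n_dropped`.
#' @export
compute_nuse <- function(se, reference = NULL) {
  m <- as_plain_matrix(se)
  stopifnot(is.matrix(m), all(m >= 0))
  if (all(m == 0)) stop("SE matrix is all zeros", call. = FALSE)
  den <- if (is.null(reference)) {
    apply(m, 1, stats::median)
  } else {
    stopifnot(length(reference) == nrow(m), all(reference >= 0))
    as.numeric(reference)
  }
  keep <- den > 0
  grid <- m[keep, , drop = FALSE] / den[keep]
  summary <- tibble::tibble(
    sample_id = colnames(m),
    nuse_median = unname(apply(grid, 2, stats::median))
  )
  structure(list(grid = grid, summary = summary, n_dropped = sum(!keep)),
    class = "ffpe_nuse"
  )
}

#' @export
print.ffpe_nuse <- function(x, ...) {
  cat("<ffpe_nuse> (", x$n_dropped, " zero-SE features dropped)\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Distance-to-average-array outlier metric
#'
#' The lumi-style outlier rule: standardize each feature across arrays
#' (`Z_ij = (Y_ij - mean_k Y_ik) / sd_k(Y_ik)`, zero-spread features dropped),
#' form a robust average profile `Target_i = median_j Z_ij`, and measure each
#' array's dissimilarity from it — Euclidean distance or one minus the
#' Pearson correlation. An array is flagged when its distance exceeds
#' `th` times the median distance (and that median is positive). The
#' threshold is relative to the current batch of arrays, which is the metric's
#' main practical weakness: it has no absolute scale.
#'
#' @param Y An [expr_matrix()] (raw or normalized; n >= 3).
#' @param dissimilarity `"euclidean"` or `"one_minus_correlation"`.
#' @param th Flagging multiplier on the median distance.
#' @return A tibble with columns `sample_id`, `lumi_distance`, `lumi_flag`;
#'   attribute `n_dropped` counts zero-spread features.
#' @export
compute_lumi_outlier <- function(Y, dissimilarity = c("euclidean", "one_minus_correlation"),
                                 th = 2) {
  dissimilarity <- match.arg(dissimilarity)
  if (inherits(Y, "ffpe_norm")) Y <- Y$normalized
  m <- as_plain_matrix(validate_expr_matrix(Y))
  if (ncol(m) < 3L) stop("outlier distance needs at least 3 arrays", call. = FALSE)
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  keep <- sd_ > 0
  if (sum(keep) < 2L) {
    stop("fewer than 2 features with positive spread; cannot standardize", call. = FALSE)
  }
  Z <- (m[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  target <- apply(Z, 1, stats::median)
  d <- if (dissimilarity == "euclidean") {
    sqrt(colSums((Z - target)^2))
  } else {
    1 - as.numeric(stats::cor(Z, target))
  }
  med <- stats::median(d)
  out <- tibble::tibble(
    sample_id = colnames(m),
    lumi_distance = unname(d),
    lumi_flag = med > 0 & d > th * med
  )
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "dissimilarity") <- dissimilarity
  out
}

#' Classify arrays into distributional quadrants
#'
#' A first-pass look at raw-data quality: each array's intensity distribution
#' is summarized by its interquartile range `IQR = Q3 - Q1` and the skew
#' statistic `skew = (Q2 - Q1) / IQR`, which is 0.5 for symmetric
#' distributions and small when the lower half of the distribution is
#' compressed (the signature of probes collapsing to background). Quartiles
#' use the type-7 linear-interpolation rule throughout. Arrays fall into
#' quadrants: R1 (IQR > iqr_cut, skew > skew_cut; well-behaved),
#' R2 (large IQR, low skew), R3 (small IQR, normal skew), R4 (otherwise).
#' A zero-IQR array has undefined skew; it is reported as `NA` and the array
#' forced to R4 with a warning.
#'
#' @param Yraw An [expr_matrix()] of raw (pre-normalization) log2 intensities.
#' @param iqr_cut,skew_cut Quadrant cutoffs (defaults 2 and 0.2).
#' @return A tibble with columns `sample_id`, `iqr`, `skew`, `quadrant`.
#' @export
classify_quadrants <- function(Yraw, iqr_cut = 2, skew_cut = 0.2) {
  m <- as_plain_matrix(validate_expr_matrix(Yraw))
  qs <- apply(m, 2, stats::quantile, probs = c(.25, .5, .75), names = FALSE, type = 7)
  iqr <- qs[3, ] - qs[1, ]
  skew <- ifelse(iqr > 0, (qs[2, ] - qs[1, ]) / iqr, NA_real_)
  if (anyNA(skew)) {
    warning(sum(is.na(skew)), " array(s) with zero IQR: skew undefined, forced to R4",
      call. = FALSE
    )
  }
  quadrant <- dplyr::case_when(
    is.na(skew) ~ "R4",
    iqr > iqr_cut & skew > skew_cut ~ "R1",
    iqr > iqr_cut & skew <= skew_cut ~ "R2",
    iqr <= iqr_cut & skew > skew_cut ~ "R3",
    .default = "R4"
  )
  tibble::tibble(
    sample_id = colnames(m),
    iqr = unname(iqr), skew = unname(skew), quadrant = quadrant
  )
}

#' Assemble the per-array QC table
#'
#' Joins all metric summaries on `sample_id` into one row per array and sets
#' the decision flags at the supplied thresholds. All threshold comparisons
#' are inclusive (`>=`); the lumi flag is taken as computed by
#' [compute_lumi_outlier()] (its rule is strict `>` relative to the batch
#' median).
#'
#' @param stress Tibble from [compute_stress()].
#' @param dfarray `ffpe_dfarray` from [compute_dfarray()].
#' @param rle `ffpe_rle` from [compute_rle()].
#' @param lumi Tibble from [compute_lumi_outlier()].
#' @param quadrants Tibble from [classify_quadrants()].
#' @param nuse Optional `ffpe_nuse` from [compute_nuse()].
#' @param n_floored Optional named per-sample counts of floor-imputed cells
#'   (taken from the `expr_matrix` ingestion attribute).
#' @param thresholds A [qc_thresholds()] object.
#' @return An `array_qc` tibble, one row per sample, with every metric field
#'   and flags `flag_stress`, `flag_dfarray`, `flag_lumi`, `flag_nuse`.
#' @export
assemble_array_qc <- function(stress, dfarray, rle, lumi, quadrants,
                              nuse = NULL, n_floored = NULL,
                              thresholds = qc_thresholds()) {
  pieces <- list(
    stress,
    dplyr::rename(dfarray$summary, dfarray75 = "dfarray")[c("sample_id", "dfarray75")],
    rle$summary,
    lumi,
    quadrants
  )
  ids <- pieces[[1]]$sample_id
  for (pc in pieces[-1]) {
    if (!setequal(pc$sample_id, ids)) {
      stop("metric inputs are not aligned on the same sample ids", call. = FALSE)
    }
  }
  out <- Reduce(function(a, b) dplyr::left_join(a, b, by = "sample_id"), pieces)
  out$nuse_median <- if (is.null(nuse)) {
    NA_real_
  } else {
    nuse$summary$nuse_median[match(out$sample_id, nuse$summary$sample_id)]
  }
  out$n_floored <- if (is.null(n_floored)) {
    0L
  } else {
    as.integer(n_floored[out$sample_id])
  }
  out <- dplyr::mutate(out,
    flag_stress = .data$stress >= thresholds$stress_cut,
    flag_dfarray = .data$dfarray75 >= thresholds$dfarray_cut,
    flag_lumi = .data$lumi_flag,
    flag_nuse = !is.na(.data$nuse_median) & .data$nuse_median >= thresholds$nuse_cut
  )
  out <- out[qc_report_columns]
  class(out) <- c("array_qc", class(out))
  out
}
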