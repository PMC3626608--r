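#' Quantile-normalize an expression matrix
#'
#' Forces every array's marginal intensity distribution onto a common target
#' built as the per-rank mean of the column order statistics. Each cell is
#' replaced by the target value at its within-column rank; tied values all
#' receive the mean of the target values over the tied ranks, which makes the
#' result deterministic and invariant to sample order — an important property
#' for FFPE data, where dead-probe floors create heavy ties.
#'
#' The per-cell correction is returned as the shift matrix `S = Y - Y'`
#' (log2 units), the "deformation" each array undergoes during normalization
#' and the quantity the [compute_stress()] metric summarizes.
#'
#' @param Y An [expr_matrix()] of log2 intensities.
#' @return A `ffpe_norm` object: list with elements `normalized`
#'   (an `expr_matrix`, Y'), `shifts` (numeric matrix, `Y - Y'`), `method`
#'   and `parameters`.
#' @examples
#' Y <- expr_matrix(matrix(c(1, 2, 3, 3, 4, 5), 3, 2,
#'   dimnames = list(paste0("f", 1:3), c("a", "b"))))
#' norm <- quantile_normalize(Y)
#' norm$normalized[, 1] # target (2, 3, 4)
#' @export
quantile_normalize <- function(Y) {
  Y <- validate_expr_matrix(Y)
  m <- as_plain_matrix(Y)
  sorted <- apply(m, 2, sort)
  target <- rowMeans(sorted)
  normalized <- apply(m, 2, function(col) {
    o <- order(col)
    out <- numeric(length(col))
    runs <- rle(col[o])
    if (all(runs$lengths == 1L)) {
      out[o] <- target
    } else {
      # ties: every member of a tie run gets the mean target over its ranks
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      cs <- c(0, cumsum(target))
      run_means <- (cs[ends + 1L] - cs[starts]) / runs$lengths
      out[o] <- rep.int(run_means, runs$lengths)
    }
    out
  })
  dimnames(normalized) <- dimnames(m)
  new_ffpe_norm(Y, normalized, "quantile", list(target = target))
}

#' Feature-target normalization by running-median smoothing
#'
#' Normalizes each array against a per-feature target (the across-array median
#' of each feature) instead of a marginal distribution. For array `j` the
#' deviations `Y[i, j] - target[i]` are smoothed along features ordered by
#' target intensity with a running median of window `max(3, round(span * p))`
#' (odd-ized), and the smooth is subtracted. A running median is used rather
#' than a local-regression fit: it has one tunable and is robust to the
#' dead-probe floor typical of degraded samples. Because the correction is
#' feature-specific, the post-normalization RLE of well-behaved arrays sits
#' essentially at zero.
#'
#' @inheritParams quantile_normalize
#' @param span Fraction of features in the smoothing window, in (0, 1].
#' @return A `ffpe_norm` object (see [quantile_normalize()]).
#' @export
feature_target_normalize <- function(Y, span = 0.3) {
  Y <- validate_expr_matrix(Y)
  if (ncol(Y) < 3L) stop("feature-target normalization needs at least 3 arrays", call. = FALSE)
  stopifnot(span > 0, span <= 1)
  m <- as_plain_matrix(Y)
  p <- nrow(m)
  window <- max(3L, round(span * p))
  if (window %% 2L == 0L) window <- window + 1L
  if (window < 3L) stop("span yields a smoothing window below 3 features", call. = FALSE)
  target <- apply(m, 1, stats::median)
  ord <- order(target)
  normalized <- m
  for (j in seq_len(ncol(m))) {
    dev <- m[ord, j] - target[ord]
    fit <- stats::runmed(dev, k = min(window, length(dev) - (1 - length(dev) %% 2)), endrule = "median")
    normalized[ord, j] <- m[ord, j] - fit
  }
  new_ffpe_norm(Y, normalized, "feature_target", list(span = span, window = window, target = target))
}

new_ffpe_norm <- function(Y, normalized, method, parameters) {
  shifts <- as_plain_matrix(Y) - normalized
  structure(
    list(
      normalized = expr_matrix(normalized,
        log_scale = attr(Y, "log_scale"),
        n_floored = attr(Y, "n_floored")
      ),
      shifts = shifts,
      method = method,
      parameters = parameters
    ),
    class = "ffpe_norm"
  )
}

#' @export
print.ffpe_norm <- function(x, ...) {
  cat("<ffpe_norm> method = ", x$method, ", ",
    nrow(x$normalized), " features x ", ncol(x$normalized), " samples\n",
    sep = ""
  )
  cat(
    "  max |shift| = ", format(max(abs(x$shifts)), digits = 4),
    ", mean |shift| = ", format(mean(abs(x$shifts)), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a normalization result
#'
#' @param x A `ffpe_norm` object.
#' @param ... Unused.
#' @return One row per sample: median and IQR of the per-cell shifts.
#' @method tidy ffpe_norm
#' @export
tidy.ffpe_norm <- function(x, ...) {
  tibble::tibble(
    sample_id = colnames(x$normalized),
    shift_median = unname(apply(x$shifts, 2, stats::median)),
    shift_iqr = unname(apply(x$shifts, 2, function(v) diff(stats::quantile(v, c(.25, .75)))))
  )
}
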