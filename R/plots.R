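#' Plot an array QC table
#'
#' Stress versus the dfArray summary, the package's primary diagnostic view:
#' arrays to the right needed heavy stretching during normalization, arrays
#' toward the top deviate from the consensus profile post-normalization.
#' Threshold guides are drawn at the supplied cutoffs and points are colored
#' by distributional quadrant.
#'
#' @param object An `array_qc` tibble from [assemble_array_qc()].
#' @param thresholds A [qc_thresholds()] object for the guide lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot array_qc
#' @export
autoplot.array_qc <- function(object, thresholds = qc_thresholds(), ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$stress, y = .data$dfarray75,
    colour = .data$quadrant
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = thresholds$stress_cut, linetype = 2) +
    ggplot2::geom_hline(yintercept = thresholds$dfarray_cut, linetype = 2) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(
      x = "Stress (fold-change scale, log2 axis)",
      y = "75th percentile |dfArray| (sd units)",
      colour = "Quadrant"
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot-style RLE view
#'
#' Per-array quartile ribbon of the relative log expression residuals.
#'
#' @param rle A `ffpe_rle` object from [compute_rle()].
#' @return A ggplot object.
#' @export
plot_rle <- function(rle) {
  stopifnot(inherits(rle, "ffpe_rle"))
  long <- tibble::tibble(
    sample_id = rep(colnames(rle$grid), each = nrow(rle$grid)),
    rle = as.vector(rle$grid)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$rle)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40", linetype = 2) +
    ggplot2::labs(x = NULL, y = "RLE (log2)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot an impact evaluation
#'
#' Per-bin variance ratio and bias against reference intensity percentile,
#' with vertical markers at the 25th/50th/75th reference intensity
#' percentiles and horizontal references at 1 (ratio) and 0 (bias).
#'
#' @param object A `ffpe_impact` object from [evaluate_impact()].
#' @param ... Unused.
#' @return A ggplot object (two facets).
#' @method autoplot ffpe_impact
#' @export
autoplot.ffpe_impact <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary[c("pct_lo", "pct_hi", "variance_ratio", "bias")],
    c("variance_ratio", "bias"),
    names_to = "panel", values_to = "value"
  )
  long$mid <- (long$pct_lo + long$pct_hi) / 2
  refs <- tibble::tibble(
    panel = c("variance_ratio", "bias"),
    yref = c(1, 0)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = refs, ggplot2::aes(yintercept = .data$yref), linetype = 2) +
    ggplot2::facet_wrap(~ .data$panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "Reference intensity percentile",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
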