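#' Two-stage Stress/dfArray quality workflow
#'
#' Stage 1 removes arrays whose marginal distribution required heavy
#' deformation during quantile normalization (Stress at or above the cutoff);
#' the survivors are renormalized from the raw matrix and stage 2 computes
#' dfArray on the renormalized data, flagging arrays at or above the dfArray
#' cutoff. Stage 2 flags are advisory by default ("investigate"); set
#' `remove_stage2 = TRUE` to drop them before the final normalization. The
#' final normalization always restarts from the raw matrix of kept samples —
#' normalized data are never re-normalized. dfArray is also computed in stage
#' 1 as a diagnostic but never drives stage-1 removal.
#'
#' @param Yraw An [expr_matrix()] of raw log2 intensities (n >= 4).
#' @param thresholds A [qc_thresholds()] object.
#' @param remove_stage2 Drop stage-2-flagged arrays from the kept set?
#' @param dfarray_mode Passed to [compute_dfarray()].
#' @return A `ffpe_pipeline` object: sets `stage1_removed`, `stage2_flagged`,
#'   `kept`; `final` (a `ffpe_norm` on the kept samples); `per_stage_qc`
#'   (list of per-stage metric tibbles); `method`; `thresholds`.
#' @export
run_mahoney <- function(Yraw, thresholds = qc_thresholds(), remove_stage2 = FALSE,
                        dfarray_mode = "robust") {
  Yraw <- validate_expr_matrix(Yraw)
  if (ncol(Yraw) < 4L) stop("pipeline needs at least 4 arrays", call. = FALSE)
  all_ids <- colnames(Yraw)

  norm0 <- quantile_normalize(Yraw)
  stress0 <- compute_stress(norm0)
  df0 <- compute_dfarray(norm0, mode = dfarray_mode, q = thresholds$dfarray_quantile)
  stage1_qc <- dplyr::left_join(stress0,
    dplyr::rename(df0$summary, dfarray75 = "dfarray"),
    by = "sample_id"
  )
  stage1_removed <- stress0$sample_id[stress0$stress >= thresholds$stress_cut]
  survivors <- setdiff(all_ids, stage1_removed)
  check_survivors(survivors)

  norm1 <- quantile_normalize(Yraw[, survivors])
  df1 <- compute_dfarray(norm1, mode = dfarray_mode, q = thresholds$dfarray_quantile)
  stage2_qc <- dplyr::rename(df1$summary, dfarray75 = "dfarray")
  stage2_flagged <- stage2_qc$sample_id[stage2_qc$dfarray75 >= thresholds$dfarray_cut]

  kept <- if (remove_stage2) setdiff(survivors, stage2_flagged) else survivors
  check_survivors(kept)
  final <- quantile_normalize(Yraw[, kept])

  new_ffpe_pipeline(
    method = "mahoney", all_ids = all_ids,
    stage1_removed = stage1_removed, stage2_flagged = stage2_flagged,
    kept = kept, final = final,
    per_stage_qc = list(stage1 = stage1_qc, stage2 = stage2_qc),
    thresholds = thresholds, remove_stage2 = remove_stage2
  )
}

#' Two-stage distance-outlier quality workflow
#'
#' The lumi-style alternative: stage 1 computes the distance-to-average-array
#' metric on the raw (un-normalized) log2 data and removes arrays beyond
#' `th` times the median distance; survivors are renormalized from raw, and
#' stage 2 repeats the rule on the normalized data and removes again, followed
#' by a final normalization of the kept set.
#'
#' @inheritParams run_mahoney
#' @param th Flagging multiplier on the median distance.
#' @param dissimilarity Passed to [compute_lumi_outlier()].
#' @return A `ffpe_pipeline` object (see [run_mahoney()]); here stage-2
#'   flagged arrays are always removed, per the workflow's definition.
#' @export
run_chow <- function(Yraw, th = 2, dissimilarity = "euclidean") {
  Yraw <- validate_expr_matrix(Yraw)
  if (ncol(Yraw) < 4L) stop("pipeline needs at least 4 arrays", call. = FALSE)
  all_ids <- colnames(Yraw)

  lumi0 <- compute_lumi_outlier(Yraw, dissimilarity = dissimilarity, th = th)
  stage1_removed <- lumi0$sample_id[lumi0$lumi_flag]
  survivors <- setdiff(all_ids, stage1_removed)
  check_survivors(survivors)

  norm1 <- quantile_normalize(Yraw[, survivors])
  lumi1 <- compute_lumi_outlier(norm1, dissimilarity = dissimilarity, th = th)
  stage2_flagged <- lumi1$sample_id[lumi1$lumi_flag]

  kept <- setdiff(survivors, stage2_flagged)
  check_survivors(kept)
  final <- quantile_normalize(Yraw[, kept])

  new_ffpe_pipeline(
    method = "chow", all_ids = all_ids,
    stage1_removed = stage1_removed, stage2_flagged = stage2_flagged,
    kept = kept, final = final,
    per_stage_qc = list(stage1 = lumi0, stage2 = lumi1),
    thresholds = list(th = th, dissimilarity = dissimilarity),
    remove_stage2 = TRUE
  )
}

new_ffpe_pipeline <- function(method, all_ids, stage1_removed, stage2_flagged,
                              kept, final, per_stage_qc, thresholds,
                              remove_stage2) {
  structure(
    list(
      method = method, all_ids = all_ids,
      stage1_removed = stage1_removed, stage2_flagged = stage2_flagged,
      kept = kept, final = final, per_stage_qc = per_stage_qc,
      thresholds = thresholds, remove_stage2 = remove_stage2
    ),
    class = "ffpe_pipeline"
  )
}

check_survivors <- function(ids) {
  if (length(ids) < 3L) {
    stop("fewer than 3 arrays survive a removal stage; cannot continue ",
      "(dfArray and distance metrics need at least 3 arrays)",
      call. = FALSE
    )
  }
  invisible(ids)
}

#' All samples a pipeline considers suspect
#'
#' Union of stage-1 removals and stage-2 flags.
#'
#' @param x A `ffpe_pipeline` object.
#' @return Character vector of sample ids.
#' @export
flagged_samples <- function(x) {
  stopifnot(inherits(x, "ffpe_pipeline"))
  union(x$stage1_removed, x$stage2_flagged)
}

#' @export
print.ffpe_pipeline <- function(x, ...) {
  cat("<ffpe_pipeline> method = ", x$method, "\n", sep = "")
  cat("  samples in:      ", length(x$all_ids), "\n", sep = "")
  cat("  stage 1 removed: ", length(x$stage1_removed), "\n", sep = "")
  cat(
    "  stage 2 ", if (x$remove_stage2) "removed" else "flagged", ": ",
    length(x$stage2_flagged), "\n",
    sep = ""
  )
  cat("  kept:            ", length(x$kept), "\n", sep = "")
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x A `ffpe_pipeline` object.
#' @param ... Unused.
#' @return One row per input sample: `sample_id`, `stage1_removed`,
#'   `stage2_flagged`, `kept`.
#' @method tidy ffpe_pipeline
#' @export
tidy.ffpe_pipeline <- function(x, ...) {
  tibble::tibble(
    sample_id = x$all_ids,
    stage1_removed = x$all_ids %in% x$stage1_removed,
    stage2_flagged = x$all_ids %in% x$stage2_flagged,
    kept = x$all_ids %in% x$kept
  )
}

#' One-row summary of a pipeline result
#'
#' @param x A `ffpe_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble of counts.
#' @method glance ffpe_pipeline
#' @export
glance.ffpe_pipeline <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_samples = length(x$all_ids),
    n_stage1_removed = length(x$stage1_removed),
    n_stage2_flagged = length(x$stage2_flagged),
    n_kept = length(x$kept)
  )
}

#' Cross-tabulate the flags of two pipeline results
#'
#' Compares which samples each workflow considers suspect (stage-1 removed or
#' stage-2 flagged). Both pipelines must have been run on the same sample
#' universe.
#'
#' @param a,b `ffpe_pipeline` objects.
#' @return A `qc_concordance` list: `table` (2x2 integer matrix, rows =
#'   pipeline `a` flagged/clean, columns = pipeline `b`), and `ids` (list of
#'   the four disjoint id sets: `both`, `a_only`, `b_only`, `neither`).
#' @export
concordance <- function(a, b) {
  stopifnot(inherits(a, "ffpe_pipeline"), inherits(b, "ffpe_pipeline"))
  if (!setequal(a$all_ids, b$all_ids)) {
    stop("pipelines were run on different sample universes", call. = FALSE)
  }
  universe <- a$all_ids
  fa <- flagged_samples(a)
  fb <- flagged_samples(b)
  ids <- list(
    both = intersect(fa, fb),
    a_only = setdiff(fa, fb),
    b_only = setdiff(fb, fa),
    neither = setdiff(universe, union(fa, fb))
  )
  tab <- matrix(
    c(length(ids$both), length(ids$a_only), length(ids$b_only), length(ids$neither)),
    2, 2,
    byrow = TRUE,
    dimnames = list(
      a = c("flagged", "clean"),
      b = c("flagged", "clean")
    )
  )
  names(dimnames(tab)) <- c(a$method, b$method)
  structure(list(table = tab, ids = ids), class = "qc_concordance")
}

#' @export
print.qc_concordance <- function(x, ...) {
  cat("<qc_concordance>\n")
  print(x$table)
  invisible(x)
}
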