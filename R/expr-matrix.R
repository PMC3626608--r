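#' Construct an expression matrix
#'
#' The central data container of the package: a features-by-samples numeric
#' matrix of background-corrected intensities, normally on the log2 scale.
#' The underlying data model is the usual log-linear decomposition of an
#' observed intensity into a true relative abundance, a systematic per-cell
#' bias removed by normalization, and mean-zero noise with feature-specific
#' variance; the container stores the observed values only, the latent terms
#' are never estimated individually.
#'
#' @param values Numeric matrix, features as rows and samples as columns.
#' @param feature_ids Character vector of unique, non-empty row identifiers.
#'   Defaults to `rownames(values)`.
#' @param sample_ids Character vector of unique, non-empty column identifiers.
#'   Defaults to `colnames(values)`.
#' @param log_scale Logical provenance flag: are the values on the log2 scale?
#' @param n_floored Optional per-sample integer counts of cells floor-imputed
#'   at ingestion (see [read_expr_matrix()]).
#'
#' @return An `expr_matrix`: a numeric matrix with dimnames and attributes
#'   `log_scale` and `n_floored`.
#' @examples
#' m <- expr_matrix(matrix(rnorm(12, 8), 4, 3,
#'   dimnames = list(paste0("f", 1:4), paste0("s", 1:3))))
#' dim(m)
#' @export
expr_matrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values), log_scale = TRUE,
                        n_floored = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  if (is.null(n_floored)) {
    n_floored <- stats::setNames(integer(ncol(values)), colnames(values))
  }
  out <- structure(values,
    log_scale = isTRUE(log_scale),
    n_floored = n_floored,
    class = c("expr_matrix", "matrix", "array")
  )
  validate_expr_matrix(out)
}

#' @rdname expr_matrix
#' @param x Object to validate.
#' @export
validate_expr_matrix <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("expression matrix needs at least 2 features and 2 samples, got ",
      nrow(x), " x ", ncol(x),
      call. = FALSE
    )
  }
  check_ids(rownames(x), "feature")
  check_ids(colnames(x), "sample")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("non-finite value at feature '", rownames(x)[bad[1]],
      "', sample '", colnames(x)[bad[2]], "'",
      call. = FALSE
    )
  }
  x
}

check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop(what, " identifiers must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(
      "duplicated ", what, " identifier: '",
      ids[duplicated(ids)][1], "'",
      call. = FALSE
    )
  }
  invisible(ids)
}

#' Construct a standard-error matrix
#'
#' Companion container to [expr_matrix()] holding per-cell standard errors of
#' the normalized intensities, as consumed by [compute_nuse()]. Shape and
#' identifiers must match the companion expression matrix exactly and all
#' values must be nonnegative.
#'
#' @inheritParams expr_matrix
#' @param companion Optional `expr_matrix` to check shape/identifiers against.
#' @return An `se_matrix` (numeric matrix with dimnames).
#' @export
se_matrix <- function(values, feature_ids = rownames(values),
                      sample_ids = colnames(values), companion = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  check_ids(rownames(values), "feature")
  check_ids(colnames(values), "sample")
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("standard errors must be finite and nonnegative", call. = FALSE)
  }
  if (!is.null(companion)) {
    if (!identical(dim(values), dim(unclass(companion))) ||
      !identical(rownames(values), rownames(companion)) ||
      !identical(colnames(values), colnames(companion))) {
      stop("SE matrix must match the companion expression matrix in shape and identifiers",
        call. = FALSE
      )
    }
  }
  structure(values, class = c("se_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(
    "<expr_matrix> ", nrow(x), " features x ", ncol(x), " samples",
    if (isTRUE(attr(x, "log_scale"))) " (log2 scale)" else "", "\n",
    sep = ""
  )
  fl <- attr(x, "n_floored")
  if (!is.null(fl) && any(fl > 0)) {
    cat("  floor-imputed cells: ", sum(fl), " across ", sum(fl > 0), " samples\n", sep = "")
  }
  pr <- x[seq_len(min(4, nrow(x))), seq_len(min(4, ncol(x))), drop = FALSE]
  print(unclass(pr), ...)
  invisible(x)
}

#' @export
print.se_matrix <- function(x, ...) {
  cat("<se_matrix> ", nrow(x), " features x ", ncol(x), " samples\n", sep = "")
  pr <- x[seq_len(min(4, nrow(x))), seq_len(min(4, ncol(x))), drop = FALSE]
  print(unclass(pr), ...)
  invisible(x)
}

# subsetting keeps the class and per-sample metadata in sync
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- as_plain_matrix(x)[i, j, ..., drop = drop]
  # a slice too small to be a valid container is returned as plain data
  if (!is.matrix(out) || nrow(out) < 2L || ncol(out) < 2L) {
    return(out)
  }
  fl <- attr(x, "n_floored")
  expr_matrix(out,
    log_scale = attr(x, "log_scale"),
    n_floored = if (!is.null(fl)) fl[colnames(out)] else NULL
  )
}

#' Convert an expression matrix to a tibble
#'
#' Long-format view for dplyr/ggplot2 work: one row per cell.
#'
#' @param x An `expr_matrix` or `se_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `value`.
#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' @method as_tibble se_matrix
#' @export
as_tibble.se_matrix <- as_tibble.expr_matrix

# plain numeric matrix view: drop class and container attributes
as_plain_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "log_scale") <- NULL
  attr(m, "n_floored") <- NULL
  m
}
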