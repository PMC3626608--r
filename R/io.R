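#' Read an expression or standard-error matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers; the body must parse as numbers. Orientation is fixed as
#' features-in-rows; use `transpose = TRUE` for files written the other way.
#'
#' Ingestion policy for problem cells, applied before any log transform: a
#' cell that is empty, `NA`, or (when `log2_transform = TRUE`) nonpositive is
#' replaced by the matrix-wide minimum positive value ("floor imputation") and
#' counted per sample. Degraded FFPE arrays carry many dead probes at or below
#' background; flooring keeps the matrices aligned where dropping rows would
#' not, and the per-sample count is carried into downstream QC tables.
#'
#' @param path File path.
#' @param delimiter Field delimiter; tab (default) or `","`.
#' @param log2_transform If `TRUE`, values become `log2(x + pseudocount)`.
#' @param pseudocount Nonnegative offset added before the log2 transform.
#' @param transpose If `TRUE`, the file is samples-in-rows and is transposed
#'   at ingestion.
#' @param log_scale When `log2_transform = FALSE`, declares whether the file
#'   is already on the log2 scale (default `TRUE`); recorded as provenance.
#' @param se If `TRUE`, return an [se_matrix()] instead (no transform allowed).
#'
#' @return An [expr_matrix()] (or [se_matrix()]), with attribute `n_floored`
#'   recording imputed-cell counts per sample.
#' @export
read_expr_matrix <- function(path, delimiter = "\t", log2_transform = FALSE,
                             pseudocount = 0, transpose = FALSE,
                             log_scale = TRUE, se = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(pseudocount >= 0)
  raw <- utils::read.delim(path,
    sep = delimiter, header = TRUE, check.names = FALSE,
    colClasses = "character", row.names = NULL, stringsAsFactors = FALSE
  )
  if (ncol(raw) < 2L) stop("malformed header: need an id column plus data columns", call. = FALSE)
  feature_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  empty <- is.na(vals) & !(is.na(body) | body %in% c("", "NA", "na", "NaN"))
  if (any(empty)) {
    bad <- which(empty, arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", body[bad[1], bad[2]], "' at row '",
      feature_ids[bad[1]], "', column '", sample_ids[bad[2]], "'",
      call. = FALSE
    )
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  if (transpose) vals <- t(vals)
  check_ids(rownames(vals), "feature")
  check_ids(colnames(vals), "sample")

  if (se) {
    if (log2_transform) stop("log2_transform does not apply to SE matrices", call. = FALSE)
    if (anyNA(vals)) stop("SE matrix contains missing cells", call. = FALSE)
    return(se_matrix(vals))
  }

  needs_floor <- is.na(vals) | (log2_transform & vals <= 0)
  n_floored <- colSums(needs_floor)
  if (any(needs_floor)) {
    pos <- vals[!is.na(vals) & vals > 0]
    if (length(pos) == 0L) stop("matrix has no positive values to floor against", call. = FALSE)
    floor_val <- if (log2_transform) min(pos) else min(vals, na.rm = TRUE)
    vals[needs_floor] <- floor_val
  }
  if (log2_transform) vals <- log2(vals + pseudocount)
  expr_matrix(vals,
    log_scale = log2_transform || isTRUE(log_scale),
    n_floored = n_floored
  )
}

#' Write an expression, SE or shift matrix as delimited text
#'
#' @param x Matrix-like object with dimnames (e.g. [expr_matrix()] or a shift
#'   matrix from [quantile_normalize()]).
#' @param path Output file path.
#' @param delimiter Field delimiter.
#' @param id_column Name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(x, path, delimiter = "\t", id_column = "feature_id") {
  m <- if (inherits(x, c("expr_matrix", "se_matrix"))) as_plain_matrix(x) else as.matrix(x)
  header <- paste(c(id_column, colnames(m)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.15g", m[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

qc_report_columns <- c(
  "sample_id", "stress", "dfarray75", "rle_median", "rle_iqr", "nuse_median",
  "lumi_distance", "lumi_flag", "iqr", "skew", "quadrant", "n_floored",
  "flag_stress", "flag_dfarray", "flag_lumi", "flag_nuse"
)

#' Write and read per-sample QC reports
#'
#' The report schema is fixed: one row (TSV) or object (JSON) per sample with
#' columns `r paste(ffpeqc:::qc_report_columns, collapse = ", ")`. TSV numbers
#' are written with 6 significant digits for readability; JSON keeps full
#' precision, so JSON round-trips exactly and TSV to ~1e-6 relative.
#'
#' @param records An `array_qc` tibble from [assemble_array_qc()] (any tibble
#'   with the schema columns works).
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (nrow(records) == 0L) stop("no QC records to write", call. = FALSE)
  missing_cols <- setdiff(qc_report_columns, names(records))
  if (length(missing_cols)) {
    stop("QC records missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[qc_report_columns]
  if (format == "json") {
    jsonlite::write_json(records, path, auto_unbox = FALSE, digits = NA, na = "null")
  } else {
    out <- records
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_floored"
    out[num] <- lapply(out[num], function(v) signif(v, 6))
    utils::write.table(out, path,
      sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
    )
  }
  invisible(path)
}

#' @rdname write_qc_report
#' @export
read_qc_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  }
  df <- tibble::as_tibble(df)[qc_report_columns]
  for (col in c("lumi_flag", "flag_stress", "flag_dfarray", "flag_lumi", "flag_nuse")) {
    df[[col]] <- as.logical(df[[col]])
  }
  for (col in c(
    "stress", "dfarray75", "rle_median", "rle_iqr", "nuse_median",
    "lumi_distance", "iqr", "skew"
  )) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$sample_id <- as.character(df$sample_id)
  df$quadrant <- as.character(df$quadrant)
  df$n_floored <- as.integer(df$n_floored)
  class(df) <- c("array_qc", class(df))
  df
}
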