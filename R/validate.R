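#' Validate a feature-by-sample intensity matrix
#'
#' Checks the core invariants of the internal data model: a numeric matrix
#' with unique, non-empty feature ids as row names and sample ids as column
#' names, whose entries are finite reals or `NA` (never `Inf`/`-Inf`).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row and column names are mandatory.
#' @return `values`, invisibly, after validation.
#' @export
validate_omics <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry feature ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate feature ids in matrix.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample ids in matrix.")
  }
  if (nrow(values) == 0L) abort("no features in matrix.")
  if (ncol(values) == 0L) abort("no samples in matrix.")
  if (any(is.infinite(values))) {
    abort("matrix contains non-finite (infinite) values; entries must be finite or NA.")
  }
  invisible(values)
}

#' Validate sample metadata against an intensity matrix
#'
#' Confirms that metadata describe exactly the samples of the matrix, that a
#' batch is recorded for every sample, and that any requested covariate
#' columns are complete (covariate levels must be known for every sample).
#' Rows are reordered to match the matrix's column order.
#'
#' @param meta Data frame with one row per sample. Must contain a
#'   `sample_id` column and a `batch` column; may contain `label`,
#'   `is_reference` and arbitrary covariate columns.
#' @param values Validated feature-by-sample matrix.
#' @param covariates Character vector of covariate column names that will be
#'   used downstream (checked for completeness), or `NULL`.
#' @return A tibble with rows ordered like `colnames(values)`; `batch` and
#'   `label` coerced to character; `is_reference` filled with `FALSE` when
#'   absent.
#' @export
validate_meta <- function(meta, values, covariates = NULL) {
  meta <- tibble::as_tibble(meta)
  if (!all(c("sample_id", "batch") %in% names(meta))) {
    abort("metadata must contain `sample_id` and `batch` columns.")
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids in metadata.")
  missing_in_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_in_meta)) {
    abort(paste0("samples in matrix but not in metadata: ",
                 paste(head(missing_in_meta, 5), collapse = ", ")))
  }
  extra_in_meta <- setdiff(meta$sample_id, colnames(values))
  if (length(extra_in_meta)) {
    abort(paste0("samples in metadata but not in matrix: ",
                 paste(head(extra_in_meta, 5), collapse = ", ")))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  meta$batch <- as.character(meta$batch)
  if (anyNA(meta$batch) || any(meta$batch == "")) {
    abort("`batch` must be non-missing for every sample.")
  }
  if ("label" %in% names(meta)) meta$label <- as.character(meta$label)
  if (!"is_reference" %in% names(meta)) {
    meta$is_reference <- FALSE
  } else {
    meta$is_reference <- as.logical(meta$is_reference)
    if (anyNA(meta$is_reference)) abort("`is_reference` contains missing values.")
  }
  for (cv in covariates %||% character()) {
    if (!cv %in% names(meta)) {
      abort(paste0("covariate column not found in metadata: ", cv))
    }
    v <- meta[[cv]]
    if (anyNA(v) || any(as.character(v) == "")) {
      abort(paste0("covariates must be known for every sample; column `",
                   cv, "` has missing entries."))
    }
    meta[[cv]] <- as.character(v)
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
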