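#' Read a feature-by-sample matrix from a delimited text file
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' The delimiter is auto-detected between tab and comma unless given.
#' Cells equal to one of `missing_tokens` (or empty) become `NA`; any other
#' cell must parse as a real number.
#'
#' @param path Path to a TSV/CSV file.
#' @param missing_tokens Character vector of tokens treated as missing.
#' @param delim Field delimiter; `NULL` auto-detects among `"\t"` and `","`.
#' @param transpose If `TRUE` the file is sample-by-feature and is transposed
#'   after reading.
#' @return A numeric matrix (features x samples) with ids as dimnames.
#' @export
read_omics_matrix <- function(path, missing_tokens = c("NA", "NaN", ""),
                              delim = NULL, transpose = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE,
                           show_col_types = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) abort("no features: matrix file is empty or has no data columns.")
  feature_ids <- as.character(tab[[1]])
  sample_ids <- names(tab)[-1]
  if (anyDuplicated(feature_ids)) abort("duplicate feature ids in matrix file.")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids in matrix file.")
  cells <- as.matrix(tab[, -1, drop = FALSE])
  is_missing <- is.na(cells) | matrix(cells %in% missing_tokens, nrow = nrow(cells))
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is_missing, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(paste0("non-numeric cell at feature `", feature_ids[bad[1, 1]],
                 "`, sample `", sample_ids[bad[1, 2]], "`: \"",
                 cells[bad[1, , drop = FALSE]], "\""))
  }
  values[is_missing] <- NA_real_
  dimnames(values) <- list(feature_ids, sample_ids)
  if (transpose) values <- t(values)
  validate_omics(values)
  values
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) abort("no features: matrix file is empty.")
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read a sample metadata table
#'
#' One row per sample. Returns a tibble with standardized column names
#' (`sample_id`, `batch`, optional `label`, covariate columns kept under
#' their own names, `is_reference`).
#'
#' @param path Path to a TSV/CSV file.
#' @param sample_col,batch_col Names of the sample-id and batch columns.
#' @param label_col Optional name of a biological-label column.
#' @param covariate_cols Optional character vector of covariate columns;
#'   these must be non-missing for every sample.
#' @param reference_col Optional name of a column of 0/1 or logical flags;
#'   absent means no sample is a reference.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A tibble of sample metadata.
#' @export
read_sample_meta <- function(path, sample_col = "sample", batch_col = "batch",
                             label_col = NULL, covariate_cols = NULL,
                             reference_col = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% detect_delim(path)
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("NA", ""), progress = FALSE, show_col_types = FALSE)
  need <- c(sample_col, batch_col, label_col, covariate_cols, reference_col)
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort(paste0("metadata columns not found: ", paste(miss, collapse = ", ")))
  out <- tibble::tibble(sample_id = as.character(tab[[sample_col]]),
                        batch = as.character(tab[[batch_col]]))
  if (anyNA(out$batch)) abort("`batch` must be non-missing for every sample.")
  if (!is.null(label_col)) out$label <- as.character(tab[[label_col]])
  for (cv in covariate_cols %||% character()) {
    v <- as.character(tab[[cv]])
    if (anyNA(v)) {
      abort(paste0("covariates must be known for every sample; column `",
                   cv, "` has missing entries."))
    }
    out[[cv]] <- v
  }
  out$is_reference <- if (is.null(reference_col)) {
    FALSE
  } else {
    as.logical(as.numeric(tab[[reference_col]]) != 0)
  }
  if (anyNA(out$is_reference)) abort("reference flags must be 0/1 for every sample.")
  out
}

#' Write a corrected matrix and its QC report
#'
#' The matrix is written with feature and sample order exactly as stored
#' (which the tree engine keeps identical to the user's input order);
#' missing entries are written as `"NA"`. The QC report is serialized as
#' JSON.
#'
#' @param values Corrected feature-by-sample matrix.
#' @param report QC report, e.g. `glance()` of a fit or the `$report` field.
#' @param out_dir Output directory, created if needed.
#' @param prefix File-name prefix (default `"corrected"`).
#' @param delim Delimiter for the matrix file.
#' @return Invisibly, the paths written (matrix, report).
#' @export
write_outputs <- function(values, report, out_dir, prefix = "corrected",
                          delim = "\t") {
  validate_omics(values)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  mat_path <- file.path(out_dir, paste0(prefix, "_matrix.tsv"))
  qc_path <- file.path(out_dir, paste0(prefix, "_qc.json"))
  tab <- tibble::as_tibble(values, rownames = "feature_id")
  readr::write_delim(tab, mat_path, delim = delim, na = "NA")
  jsonlite::write_json(as.list(report), qc_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(matrix = mat_path, report = qc_path))
}
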