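#' Remove singleton values from each (feature, batch) block
#'
#' The pairwise adjusters require at least two numeric values per feature in
#' each batch they touch; features may otherwise be entirely missing in a
#' batch. This pre-processing pass enforces that relaxed completeness
#' condition by blanking any (feature, batch) cell holding exactly one
#' numeric value. It is the only stage of the pipeline that discards data.
#'
#' @param values Feature-by-sample matrix.
#' @param meta Sample metadata (validated against `values`).
#' @return A list with `values` (matrix after removal) and `removed_count`
#'   (number of numeric values blanked).
#' @export
remove_singletons <- function(values, meta) {
  meta <- validate_meta(meta, validate_omics(values))
  batches <- unique(meta$batch)
  removed <- 0L
  for (b in batches) {
    cols <- which(meta$batch == b)
    obs <- !is.na(values[, cols, drop = FALSE])
    counts <- rowSums(obs)
    single <- counts == 1L
    if (any(single)) {
      sub <- values[single, cols, drop = FALSE]
      sub[!is.na(sub)] <- NA_real_
      values[single, cols] <- sub
      removed <- removed + sum(single)
    }
  }
  list(values = values, removed_count = removed)
}

#' Classify features for a pairwise correction step
#'
#' For each feature, decides between correcting it (enough numeric data in
#' both batches), propagating it unchanged (numeric data in only one batch),
#' or marking it absent (no numeric data in either batch). With
#' `references = TRUE`, eligibility additionally requires at least two
#' numeric reference values per batch.
#'
#' @param values Feature-by-sample matrix (after [remove_singletons()]).
#' @param meta Sample metadata.
#' @param batch_a,batch_b The two batch ids of the step.
#' @param references Require reference-sample support for eligibility?
#' @return A tibble with `feature_id` and `status` in
#'   `c("CORRECT", "PROPAGATE_A", "PROPAGATE_B", "ABSENT")`.
#' @export
classify_features <- function(values, meta, batch_a, batch_b,
                              references = FALSE) {
  if (identical(batch_a, batch_b)) abort("batch_a and batch_b must differ.")
  meta <- validate_meta(meta, validate_omics(values))
  cols_a <- which(meta$batch == batch_a)
  cols_b <- which(meta$batch == batch_b)
  if (!length(cols_a)) abort(paste0("unknown batch: ", batch_a))
  if (!length(cols_b)) abort(paste0("unknown batch: ", batch_b))
  n_a <- rowSums(!is.na(values[, cols_a, drop = FALSE]))
  n_b <- rowSums(!is.na(values[, cols_b, drop = FALSE]))
  status <- ifelse(n_a >= 2 & n_b >= 2, "CORRECT",
            ifelse(n_a >= 2, "PROPAGATE_A",
            ifelse(n_b >= 2, "PROPAGATE_B", "ABSENT")))
  if (references) {
    ref_a <- cols_a[meta$is_reference[cols_a]]
    ref_b <- cols_b[meta$is_reference[cols_b]]
    r_a <- rowSums(!is.na(values[, ref_a, drop = FALSE]))
    r_b <- rowSums(!is.na(values[, ref_b, drop = FALSE]))
    demote <- status == "CORRECT" & !(r_a >= 2 & r_b >= 2)
    status[demote] <- ifelse(n_a[demote] >= 2 & n_b[demote] >= 2,
                             ifelse(n_a[demote] >= n_b[demote],
                                    "PROPAGATE_A", "PROPAGATE_B"),
                             status[demote])
  }
  tibble::tibble(feature_id = rownames(values), status = unname(status))
}
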