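#' Pairwise batch-effect correction
#'
#' Correct a two-batch dataset with one of the three back-ends:
#' `correct_pair_combat()` applies the parametric empirical-Bayes
#' location/scale adjustment, `correct_pair_linear()` an ordinary
#' least-squares fit whose batch term is subtracted, and
#' `correct_pair_references()` estimates the shift on flagged reference
#' samples only and applies it to all samples. Features with fewer than two
#' numeric values in either batch (or, for the reference mode, fewer than
#' two numeric reference values) are propagated unchanged; missingness is
#' never altered.
#'
#' @param values Feature-by-sample matrix holding exactly two batches.
#' @param meta Sample metadata (see [validate_meta()]).
#' @param covariates Optional character vector of categorical covariate
#'   columns in `meta`, preserved by the correction.
#' @return Corrected matrix of identical shape and missingness.
#' @export
correct_pair_combat <- function(values, meta, covariates = NULL) {
  correct_pair(values, meta, covariates, method = "combat")
}

#' @rdname correct_pair_combat
#' @export
correct_pair_linear <- function(values, meta, covariates = NULL) {
  correct_pair(values, meta, covariates, method = "limma")
}

#' @rdname correct_pair_combat
#' @export
correct_pair_references <- function(values, meta, covariates = NULL) {
  correct_pair(values, meta, covariates, method = "references")
}

correct_pair <- function(values, meta, covariates = NULL,
                         method = c("combat", "limma", "references")) {
  method <- match.arg(method)
  validate_omics(values)
  meta <- validate_meta(meta, values, covariates)
  batches <- unique(meta$batch)
  if (length(batches) != 2L) {
    abort("pairwise correction requires exactly 2 batches.")
  }
  covdata <- if (length(covariates)) {
    as.data.frame(meta[, covariates, drop = FALSE])
  }
  res <- adjust_pair_step(values, meta$batch, covdata, meta$is_reference, method)
  res$values
}

# Shared pairwise step used by the surface functions and the tree engine.
# Classifies features, adjusts the eligible ones, propagates the rest.
adjust_pair_step <- function(Y, batch, covdata, is_ref, method) {
  obs <- !is.na(Y)
  b <- unique(batch)
  cols1 <- which(batch == b[1L])
  cols2 <- which(batch == b[2L])
  n1 <- rowSums(obs[, cols1, drop = FALSE])
  n2 <- rowSums(obs[, cols2, drop = FALSE])
  eligible <- n1 >= 2 & n2 >= 2
  if (method == "references") {
    r1 <- cols1[is_ref[cols1]]
    r2 <- cols2[is_ref[cols2]]
    if (!length(r1) || !length(r2)) {
      abort("each batch of a pair must contain at least one reference sample.")
    }
    eligible <- eligible &
      rowSums(obs[, r1, drop = FALSE]) >= 2 &
      rowSums(obs[, r2, drop = FALSE]) >= 2
  }
  n_absent <- sum(n1 < 2 & n2 < 2)
  out <- Y
  n_skipped <- 0L
  if (any(eligible)) {
    Ye <- Y[eligible, , drop = FALSE]
    adj <- switch(method,
      combat = {
        r <- combat_adjust(Ye, batch, covdata)
        n_skipped <- length(r$skipped)
        r$values
      },
      limma = linear_adjust(Ye, batch, covdata),
      references = reference_adjust(Ye, batch, is_ref, covdata)
    )
    out[eligible, ] <- adj
  }
  list(values = out,
       n_corrected = sum(eligible) - n_skipped,
       n_propagated = sum(!eligible) - n_absent + n_skipped,
       n_absent = n_absent)
}
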