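# Design-matrix helpers shared by the pairwise adjusters.
#
# Batch indicators use sum-to-zero coding so that a pairwise correction
# distributes the estimated shift symmetrically over both batches; any
# constant offset is irrelevant for downstream analyses that rely on
# relative differences.

# Sum-to-zero batch columns for a factor with k levels: k-1 columns.
batch_contrast_cols <- function(batch, levels = unique(batch)) {
  f <- factor(batch, levels = levels)
  k <- nlevels(f)
  if (k < 2) abort("need at least 2 batches in a correction step.")
  X <- stats::contr.sum(k)[as.integer(f), , drop = FALSE]
  colnames(X) <- paste0("batch", seq_len(k - 1L))
  X
}

# Dummy columns (drop first level) for categorical covariates.
covariate_cols_matrix <- function(covdata) {
  if (is.null(covdata) || ncol(covdata) == 0L) {
    return(NULL)
  }
  covdata <- as.data.frame(lapply(covdata, function(v) factor(as.character(v))),
                           stringsAsFactors = FALSE)
  X <- model.matrix(~ ., data = covdata)
  X[, -1, drop = FALSE]
}

# Error with the offending column name if a design is rank-deficient on the
# rows `rows` (a logical or integer subset). Used so that a covariate level
# perfectly confounded with batch fails loudly instead of being dropped.
check_full_rank <- function(X, context = "design") {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort(paste0(context, " is rank-deficient (confounded with batch): ",
                 paste(dropped, collapse = ", ")))
  }
  invisible(qr_x)
}

# Per-missingness-pattern least squares for many features sharing one design.
#
# Y: features x n matrix (NA allowed); X: n x p design. Features are grouped
# by their observation pattern; each group is solved in one call. Returns the
# p x nfeat coefficient matrix. Patterns for which the design (restricted to
# observed samples) is rank-deficient trigger `on_deficient`, which may
# either abort or return NULL to mark the features as unestimable (their
# coefficients are NA).
fit_ols_patterns <- function(Y, X, context = "design") {
  n <- ncol(Y)
  stopifnot(nrow(X) == n)
  obs <- !is.na(Y)
  grp <- vctrs::vec_group_id(as.data.frame(obs))
  coef <- matrix(NA_real_, nrow = ncol(X), ncol = nrow(Y),
                 dimnames = list(colnames(X), rownames(Y)))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    s <- obs[rows[1L], ]
    Xs <- X[s, , drop = FALSE]
    qr_x <- check_full_rank(Xs, context)
    Ys <- t(Y[rows, s, drop = FALSE])
    coef[, rows] <- qr.coef(qr_x, Ys)
  }
  coef
}
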