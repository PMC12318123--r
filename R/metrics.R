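#' Missingness-tolerant pairwise sample distances
#'
#' Euclidean distance computed over the features observed in both samples of
#' a pair, rescaled by `sqrt(F_total / F_shared)` so that distances remain
#' comparable between pairs with different numbers of shared features. On
#' complete data this reduces to the ordinary Euclidean distance.
#'
#' @param values Feature-by-sample matrix (`NA` allowed).
#' @return A symmetric numeric matrix of sample-by-sample distances with a
#'   zero diagonal.
#' @export
omics_dist <- function(values) {
  validate_omics(values)
  n <- ncol(values)
  if (n < 2L) abort("need at least 2 samples for pairwise distances.")
  W <- !is.na(values)
  storage.mode(W) <- "double"
  M0 <- values
  M0[is.na(M0)] <- 0
  shared <- crossprod(W)                       # shared feature counts
  if (any(shared == 0)) {
    bad <- which(shared == 0, arr.ind = TRUE)[1L, ]
    abort(paste0("samples share no observed features: ",
                 colnames(values)[bad[1]], ", ", colnames(values)[bad[2]]))
  }
  sq <- crossprod(M0^2, W)                     # sum over shared of x_k^2
  d2 <- sq + t(sq) - 2 * crossprod(M0)
  d2 <- d2 * (nrow(values) / shared)
  d2[d2 < 0] <- 0                              # numerical noise
  d <- sqrt(d2)
  diag(d) <- 0
  dimnames(d) <- list(colnames(values), colnames(values))
  d
}

#' Average silhouette width of a sample grouping
#'
#' The mean over samples of `(b_i - a_i) / max(a_i, b_i)` where `a_i` is the
#' mean distance of sample `i` to its own group (excluding itself) and `b_i`
#' the smallest mean distance to any other group. Members of singleton
#' groups contribute silhouette 0. Computed with respect to the batch of
#' origin (lower after integration = better) or a biological label (higher =
#' better-preserved signal). Samples with a missing grouping value are
#' excluded and counted.
#'
#' @param values Feature-by-sample matrix.
#' @param grouping Vector of group assignments, one per sample (`NA`
#'   excluded).
#' @param dist_matrix Optional precomputed matrix from [omics_dist()]
#'   (reusing it across groupings avoids recomputation).
#' @return A list of class `asw_result`: `asw` (in `[-1, 1]`),
#'   `n_samples_used`, `n_excluded`, and `widths`, a tibble of per-sample
#'   silhouette widths.
#' @export
asw <- function(values, grouping, dist_matrix = NULL) {
  if (length(grouping) != ncol(values)) {
    abort("`grouping` must have one entry per sample.")
  }
  d <- dist_matrix %||% omics_dist(values)
  keep <- !is.na(grouping)
  n_excluded <- sum(!keep)
  d <- d[keep, keep, drop = FALSE]
  g <- as.character(grouping[keep])
  groups <- unique(g)
  if (length(groups) < 2L) abort("silhouette needs at least 2 groups.")
  n <- length(g)
  sizes <- table(g)
  # mean distance from each sample to every group, via one matrix product
  G <- stats::model.matrix(~ g - 1)
  colnames(G) <- sub("^g", "", colnames(G))
  sums <- d %*% G                              # n x k: total distance to group
  mean_other <- sweep(sums, 2, as.numeric(sizes[colnames(G)]), "/")
  own_size <- as.numeric(sizes[g])
  a <- (sums[cbind(seq_len(n), match(g, colnames(G)))]) / pmax(own_size - 1, 1)
  b_mat <- mean_other
  b_mat[cbind(seq_len(n), match(g, colnames(G)))] <- Inf
  b <- apply(b_mat, 1, min)
  s <- unname((b - a) / pmax(a, b))
  s[own_size == 1] <- 0
  s[!is.finite(s)] <- 0                        # a == b == 0 degenerate ties
  structure(list(asw = mean(s),
                 n_samples_used = n,
                 n_excluded = n_excluded,
                 widths = tibble::tibble(sample_id = colnames(d) %||% as.character(seq_len(n)),
                                         group = g, a = unname(a),
                                         b = unname(b), width = s)),
            class = "asw_result")
}

#' @export
print.asw_result <- function(x, ...) {
  cat(sprintf("average silhouette width: %.4f (%d samples, %d excluded)\n",
              x$asw, x$n_samples_used, x$n_excluded))
  invisible(x)
}
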