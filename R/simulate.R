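#' Simulate multi-batch omics data under a location/scale batch-effect model
#'
#' Generates log-scale intensities
#' `y = alpha_f + X beta_f + gamma_bf + delta_bf * eps` with per-feature
#' baseline `alpha_f ~ N(0,1)`, condition effects `beta_f ~ N(0,1)` (dummy
#' coding, first condition baseline), additive batch effects
#' `gamma_bf ~ N(0, gamma_sd^2)`, multiplicative batch effects
#' `delta_bf ~ InverseGamma(shape, scale)` (mean `scale/(shape-1)`, 0.5 at
#' the defaults) and standard-normal noise. Optionally a fraction of
#' features is set fully missing per batch (feature-wise MCAR) and samples
#' are flagged as references.
#'
#' @param n_features,n_batches,samples_per_batch Dimensions of the dataset.
#' @param n_conditions Number of biological conditions (default 2).
#' @param class_ratio Numeric vector of per-batch condition proportions
#'   (sums to 1). The assignment of proportions to conditions is randomized
#'   per batch (the minority class differs between batches); `NULL` means
#'   balanced.
#' @param missing_fraction Fraction of features fully missing per batch
#'   (`0 <= f < 1`), applied independently per batch.
#' @param gamma_sd Standard deviation of the additive batch effects; 0
#'   switches them off.
#' @param delta_shape,delta_scale Inverse-gamma parameters of the
#'   multiplicative batch effects.
#' @param delta_constant If non-`NULL`, a fixed value replacing the
#'   inverse-gamma draws (1 switches scale effects off).
#' @param n_references Number of reference samples flagged per batch, spread
#'   over the conditions round-robin.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   output.
#' @return A list with `values` (matrix), `meta` (tibble with `sample_id`,
#'   `batch`, `label`, `is_reference`) and `truth` (drawn parameters:
#'   `alpha`, `beta`, `gamma`, `delta`).
#' @export
simulate_batches <- function(n_features = 6000, n_batches = 20,
                             samples_per_batch = 10, n_conditions = 2,
                             class_ratio = NULL, missing_fraction = 0,
                             gamma_sd = 1, delta_shape = 5, delta_scale = 2,
                             delta_constant = NULL, n_references = 0,
                             seed = NULL) {
  if (n_batches < 2L) abort("need at least 2 batches.")
  if (samples_per_batch < 2L) abort("need at least 2 samples per batch.")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must be in [0, 1).")
  }
  if (!is.null(class_ratio)) {
    if (length(class_ratio) != n_conditions ||
        abs(sum(class_ratio) - 1) > 1e-8) {
      abort("class_ratio must have one proportion per condition and sum to 1.")
    }
  } else {
    class_ratio <- rep(1 / n_conditions, n_conditions)
  }
  if (!is.null(seed)) set.seed(seed)

  n_samples <- n_batches * samples_per_batch
  feature_ids <- paste0("f", seq_len(n_features))
  sample_ids <- paste0("s", seq_len(n_samples))
  batch_ids <- paste0("b", seq_len(n_batches))
  conditions <- paste0("cond", seq_len(n_conditions))

  batch <- rep(batch_ids, each = samples_per_batch)
  # per-batch condition assignment with randomized ratio-to-condition mapping
  label <- character(n_samples)
  for (i in seq_len(n_batches)) {
    counts <- ratio_counts(class_ratio, samples_per_batch)
    counts <- counts[sample.int(n_conditions)]
    label[batch == batch_ids[i]] <- rep(conditions, counts)
  }

  alpha <- rnorm(n_features)
  beta <- matrix(rnorm(n_features * (n_conditions - 1L)), nrow = n_features,
                 dimnames = list(feature_ids, conditions[-1]))
  gamma <- matrix(rnorm(n_features * n_batches, sd = gamma_sd),
                  nrow = n_features, dimnames = list(feature_ids, batch_ids))
  delta <- if (is.null(delta_constant)) {
    matrix(rinvgamma(n_features * n_batches, delta_shape, delta_scale),
           nrow = n_features, dimnames = list(feature_ids, batch_ids))
  } else {
    matrix(delta_constant, n_features, n_batches,
           dimnames = list(feature_ids, batch_ids))
  }
  if (gamma_sd == 0) gamma[] <- 0

  eps <- matrix(rnorm(n_features * n_samples), nrow = n_features)
  cond_idx <- match(label, conditions)
  bx <- match(batch, batch_ids)
  beta_part <- cbind(0, beta)[, cond_idx, drop = FALSE]
  values <- alpha + beta_part + gamma[, bx, drop = FALSE] +
    delta[, bx, drop = FALSE] * eps
  dimnames(values) <- list(feature_ids, sample_ids)

  is_reference <- rep(FALSE, n_samples)
  if (n_references > 0) {
    for (i in seq_len(n_batches)) {
      idx <- which(batch == batch_ids[i])
      by_cond <- split(idx, label[idx])
      picks <- integer()
      ci <- rep(seq_along(by_cond), length.out = n_references)
      for (k in seq_len(n_references)) {
        pool <- setdiff(by_cond[[ci[k]]], picks)
        if (!length(pool)) abort("not enough samples of a condition to draw references.")
        picks <- c(picks, pool[sample.int(length(pool), 1L)])
      }
      is_reference[picks] <- TRUE
    }
  }

  meta <- tibble::tibble(sample_id = sample_ids, batch = batch,
                         label = label, is_reference = is_reference)
  if (missing_fraction > 0) {
    values <- apply_feature_mcar(values, meta, missing_fraction)
  }
  list(values = values, meta = meta,
       truth = list(alpha = setNames(alpha, feature_ids), beta = beta,
                    gamma = gamma, delta = delta))
}

# Integer condition counts for one batch, preserving the total.
ratio_counts <- function(ratio, n) {
  counts <- floor(ratio * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- ratio * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  as.integer(counts)
}

# Inverse-gamma draws in shape/scale parameterization:
# density proportional to x^(-shape-1) exp(-scale/x); mean scale/(shape-1).
rinvgamma <- function(n, shape, scale) {
  1 / rgamma(n, shape = shape, rate = scale)
}

#' Apply feature-wise per-batch MCAR missingness
#'
#' Independently in each batch, a uniformly random fraction of features is
#' set fully missing within that batch; no partial missingness is
#' introduced, so every (feature, batch) block stays all-or-nothing and
#' singleton removal is a no-op on the result.
#'
#' @param values Feature-by-sample matrix.
#' @param meta Sample metadata.
#' @param missing_fraction Fraction of features blanked per batch.
#' @param seed Optional seed.
#' @return Matrix with added missingness.
#' @export
apply_feature_mcar <- function(values, meta, missing_fraction, seed = NULL) {
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must be in [0, 1).")
  }
  if (!is.null(seed)) set.seed(seed)
  if (missing_fraction == 0) return(values)
  meta <- validate_meta(meta, validate_omics(values))
  n_miss <- floor(missing_fraction * nrow(values))
  for (b in unique(meta$batch)) {
    rows <- sample.int(nrow(values), n_miss)
    values[rows, meta$batch == b] <- NA_real_
  }
  batch_counts <- rowsum((!is.na(t(values))) * 1, meta$batch)  # batches x features
  orphaned <- sum(colSums(batch_counts >= 2) < 2)
  if (orphaned > 0) {
    warn(paste0(orphaned, " feature(s) left observed in fewer than 2 batches",
                " and can only be propagated, never corrected."))
  }
  values
}

#' Simulate a two-batch dataset with configurable class imbalance
#'
#' Starts from two balanced batches of two conditions, then removes
#' `depletion` samples of the first condition from batch 1 and of the second
#' condition from batch 2 (symmetric imbalance). Optionally flags
#' `n_references` samples per batch (spread over conditions) before
#' depletion; references are never removed.
#'
#' @param n_features Number of features (default 600).
#' @param samples_per_batch Samples per batch before depletion (even).
#' @param depletion Number of samples of the depleted condition removed per
#'   batch (`0 <=` depletion `< samples_per_batch / 2`).
#' @param n_references References flagged per batch (round-robin over
#'   conditions).
#' @param missing_fraction Feature-wise MCAR fraction per batch.
#' @param gamma_sd,delta_shape,delta_scale Batch-effect parameters, as in
#'   [simulate_batches()].
#' @param seed Optional seed.
#' @return A list with `values`, `meta`, `truth` as in [simulate_batches()].
#' @export
simulate_imbalanced_pair <- function(n_features = 600, samples_per_batch = 20,
                                     depletion = 0, n_references = 0,
                                     missing_fraction = 0.1, gamma_sd = 1,
                                     delta_shape = 5, delta_scale = 2,
                                     seed = NULL) {
  half <- samples_per_batch %/% 2L
  if (depletion >= half) {
    abort("depletion would remove an entire condition from a batch.")
  }
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_batches(n_features = n_features, n_batches = 2,
                          samples_per_batch = samples_per_batch,
                          n_conditions = 2, class_ratio = c(0.5, 0.5),
                          missing_fraction = 0, gamma_sd = gamma_sd,
                          delta_shape = delta_shape, delta_scale = delta_scale,
                          n_references = n_references)
  meta <- sim$meta
  # fix the per-batch assignment so cond1 is depleted in b1, cond2 in b2
  drop_idx <- integer()
  for (b in c("b1", "b2")) {
    cond <- if (b == "b1") "cond1" else "cond2"
    pool <- which(meta$batch == b & meta$label == cond & !meta$is_reference)
    if (length(pool) < depletion) {
      abort("not enough non-reference samples of the depleted condition.")
    }
    if (depletion > 0) drop_idx <- c(drop_idx, sample(pool, depletion))
  }
  if (length(drop_idx)) {
    keep <- setdiff(seq_len(nrow(meta)), drop_idx)
    sim$values <- sim$values[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (missing_fraction > 0) {
    sim$values <- apply_feature_mcar(sim$values, meta, missing_fraction)
  }
  list(values = sim$values, meta = meta, truth = sim$truth)
}
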