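# Scripted, seed-controlled desk-scale experiments. Each driver returns a
# tibble of per-repetition records (class `batchtree_experiment`) carrying
# the experiment id and the seeds used as attributes, so that summaries can
# always be recomputed from the records.

experiment_result <- function(records, id, seeds) {
  structure(dplyr::as_tibble(records),
            experiment = id, seeds = seeds,
            class = c("batchtree_experiment", class(records)))
}

exp_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max %/% 2L, n)
}

#' Tree-based versus one-step linear correction on complete data
#'
#' For each repetition, generates a complete multi-batch dataset, corrects
#' it once with the binary-tree procedure (linear adjuster) and once with a
#' single whole-matrix linear correction, and records the ASW scores of both
#' outputs with respect to batch and label. Because the two corrections
#' differ only by per-feature constant offsets, the ASW scores should agree
#' almost exactly.
#'
#' @param reps Number of repetitions.
#' @param n_features,n_batches,samples_per_batch Dataset dimensions per
#'   repetition.
#' @param seed Seed for the experiment's seed stream.
#' @return A `batchtree_experiment` tibble with per-repetition ASW scores
#'   for both procedures and their absolute differences.
#' @export
compare_tree_vs_onestep <- function(reps = 10, n_features = 6000,
                                    n_batches = 20, samples_per_batch = 10,
                                    seed = NULL) {
  seeds <- exp_seeds(seed, reps)
  records <- purrr::map_dfr(seq_len(reps), function(r) {
    sim <- simulate_batches(n_features = n_features, n_batches = n_batches,
                            samples_per_batch = samples_per_batch,
                            missing_fraction = 0, seed = seeds[r])
    fit <- batchtree(sim$values, sim$meta, method = "limma")
    one <- correct_onestep_linear(sim$values, sim$meta)
    d_one <- omics_dist(one)
    asw_b_one <- asw(one, sim$meta$batch, dist_matrix = d_one)$asw
    asw_l_one <- asw(one, sim$meta$label, dist_matrix = d_one)$asw
    tibble::tibble(
      rep = r, seed = seeds[r],
      asw_batch_tree = fit$report$asw_batch_corrected,
      asw_batch_onestep = asw_b_one,
      asw_label_tree = fit$report$asw_label_corrected,
      asw_label_onestep = asw_l_one,
      diff_batch = abs(fit$report$asw_batch_corrected - asw_b_one),
      diff_label = abs(fit$report$asw_label_corrected - asw_l_one)
    )
  })
  experiment_result(records, "tree_vs_onestep", seeds)
}

#' Missing-value sweep
#'
#' Varies the feature-wise MCAR fraction and records, per repetition and
#' adjuster, the fraction of numeric values retained (expected 1 after
#' pre-processing on this missingness scheme) and the ASW scores before and
#' after correction. Integration quality should stay approximately constant
#' across missingness levels.
#'
#' @param reps Repetitions per fraction.
#' @param fractions Missing-value fractions to sweep (in `[0, 0.5]`).
#' @param methods Adjusters to run.
#' @param n_features,n_batches,samples_per_batch Dataset dimensions.
#' @param fast Use the scaled-down configuration (3 repetitions, 2000
#'   features).
#' @param seed Seed for the seed stream.
#' @return A `batchtree_experiment` tibble.
#' @export
sweep_missingness <- function(reps = 10, fractions = seq(0, 0.5, by = 0.1),
                              methods = c("limma", "combat"),
                              n_features = 6000, n_batches = 20,
                              samples_per_batch = 10, fast = FALSE,
                              seed = NULL) {
  if (fast) {
    reps <- min(reps, 3L)
    n_features <- min(n_features, 2000L)
  }
  seeds <- exp_seeds(seed, reps * length(fractions))
  grid <- tidyr::expand_grid(rep = seq_len(reps), fraction = fractions)
  grid$seed <- seeds
  records <- purrr::pmap_dfr(grid, function(rep, fraction, seed) {
    sim <- simulate_batches(n_features = n_features, n_batches = n_batches,
                            samples_per_batch = samples_per_batch,
                            missing_fraction = fraction, seed = seed)
    purrr::map_dfr(methods, function(m) {
      fit <- batchtree(sim$values, sim$meta, method = m)
      r <- fit$report
      tibble::tibble(rep = rep, fraction = fraction, seed = seed, method = m,
                     retained = r$n_numeric_out / r$n_numeric_in,
                     removed_preprocessing = r$n_numeric_removed_preprocessing,
                     asw_batch_raw = r$asw_batch_raw,
                     asw_batch_corrected = r$asw_batch_corrected,
                     asw_label_raw = r$asw_label_raw,
                     asw_label_corrected = r$asw_label_corrected,
                     elapsed_seconds = r$elapsed_seconds)
    })
  })
  experiment_result(records, "missingness_sweep", seeds)
}

#' Batch-count scaling
#'
#' Generates datasets with an increasing number of batches (20% missing
#' values per batch) and records the pairwise-step count (always `N - 1`,
#' hence linear complexity by construction), value conservation and elapsed
#' time (informational only; wall-clock numbers are hardware-dependent and
#' never asserted).
#'
#' @param reps Repetitions per batch count.
#' @param batch_counts Numbers of batches to test.
#' @param n_features,samples_per_batch,missing_fraction Dataset parameters.
#' @param method Adjuster to run.
#' @param fast Use the scaled-down configuration (1 repetition, 1000
#'   features, up to 16 batches).
#' @param seed Seed for the seed stream.
#' @return A `batchtree_experiment` tibble.
#' @export
scale_batches <- function(reps = 10, batch_counts = c(4, 8, 16, 32, 64),
                          n_features = 6000, samples_per_batch = 10,
                          missing_fraction = 0.2, method = "limma",
                          fast = FALSE, seed = NULL) {
  if (fast) {
    reps <- 1L
    n_features <- min(n_features, 1000L)
    batch_counts <- batch_counts[batch_counts <= 16]
  }
  seeds <- exp_seeds(seed, reps * length(batch_counts))
  grid <- tidyr::expand_grid(rep = seq_len(reps), n_batches = batch_counts)
  grid$seed <- seeds
  records <- purrr::pmap_dfr(grid, function(rep, n_batches, seed) {
    sim <- simulate_batches(n_features = n_features, n_batches = n_batches,
                            samples_per_batch = samples_per_batch,
                            missing_fraction = missing_fraction, seed = seed)
    fit <- batchtree(sim$values, sim$meta, method = method,
                     compute_asw = FALSE)
    r <- fit$report
    tibble::tibble(rep = rep, n_batches = n_batches, seed = seed,
                   n_steps = r$n_pairwise_steps,
                   removed_preprocessing = r$n_numeric_removed_preprocessing,
                   conserved = r$n_numeric_out ==
                     r$n_numeric_in - r$n_numeric_removed_preprocessing,
                   elapsed_seconds = r$elapsed_seconds,
                   seconds_per_batch = r$elapsed_seconds / n_batches)
  })
  experiment_result(records, "batch_scaling", seeds)
}

#' Class-imbalance sweep: naive versus covariate-aware correction
#'
#' For each class-ratio scenario (e.g. 1:9, 3:7, 5:5, minority condition
#' randomized per batch), corrects with the empirical-Bayes adjuster naively
#' and with the condition passed as a categorical covariate, and records the
#' label ASW of both. Under strong imbalance the covariate-aware run should
#' recover class separation the naive run loses.
#'
#' @param reps Repetitions per scenario.
#' @param ratios List of two-condition proportion vectors.
#' @param n_features,n_batches,samples_per_batch Dataset dimensions.
#' @param fast Use the scaled-down configuration (3 repetitions, 1000
#'   features, 4 batches of 40).
#' @param seed Seed for the seed stream.
#' @return A `batchtree_experiment` tibble.
#' @export
sweep_imbalance_covariates <- function(reps = 10,
                                       ratios = list(c(0.1, 0.9), c(0.3, 0.7),
                                                     c(0.5, 0.5)),
                                       n_features = 6000, n_batches = 8,
                                       samples_per_batch = 80, fast = FALSE,
                                       seed = NULL) {
  if (fast) {
    reps <- min(reps, 3L)
    n_features <- min(n_features, 1000L)
    n_batches <- min(n_batches, 4L)
    samples_per_batch <- min(samples_per_batch, 40L)
  }
  seeds <- exp_seeds(seed, reps * length(ratios))
  grid <- tidyr::expand_grid(rep = seq_len(reps),
                             scenario = seq_along(ratios))
  grid$seed <- seeds
  records <- purrr::pmap_dfr(grid, function(rep, scenario, seed) {
    ratio <- ratios[[scenario]]
    sim <- simulate_batches(n_features = n_features, n_batches = n_batches,
                            samples_per_batch = samples_per_batch,
                            class_ratio = ratio, seed = seed)
    fit_naive <- batchtree(sim$values, sim$meta, method = "combat")
    fit_cov <- batchtree(sim$values, sim$meta, method = "combat",
                         covariates = "label")
    tibble::tibble(rep = rep, seed = seed,
                   ratio = paste(round(ratio * 10), collapse = ":"),
                   asw_label_raw = fit_naive$report$asw_label_raw,
                   asw_label_naive = fit_naive$report$asw_label_corrected,
                   asw_label_covariate = fit_cov$report$asw_label_corrected)
  })
  experiment_result(records, "imbalance_covariates", seeds)
}

#' Batch-order invariance check
#'
#' Runs the tree correction on the same dataset with the original and a
#' randomly permuted batch order and records (a) the largest per-feature
#' standard deviation of the difference between the two outputs (near zero
#' when the outputs differ only by per-feature constant offsets) and (b) the
#' absolute difference of label ASW scores (offsets cancel in pairwise
#' distances). The linear adjuster satisfies both to float precision; the
#' empirical-Bayes adjuster rescales variances per pair, so its differences
#' are recorded informationally.
#'
#' @param reps Repetitions.
#' @param methods Adjusters to check.
#' @param n_features,n_batches,samples_per_batch,missing_fraction Dataset
#'   parameters.
#' @param seed Seed for the seed stream.
#' @return A `batchtree_experiment` tibble with columns `max_feature_sd`
#'   and `asw_label_diff` per repetition and method.
#' @export
check_order_invariance <- function(reps = 3, methods = c("limma", "combat"),
                                   n_features = 1000, n_batches = 6,
                                   samples_per_batch = 10,
                                   missing_fraction = 0, seed = NULL) {
  seeds <- exp_seeds(seed, reps)
  records <- purrr::map_dfr(seq_len(reps), function(r) {
    sim <- simulate_batches(n_features = n_features, n_batches = n_batches,
                            samples_per_batch = samples_per_batch,
                            missing_fraction = missing_fraction,
                            seed = seeds[r])
    set.seed(seeds[r] + 1L)
    perm <- sample(unique(sim$meta$batch))
    ord <- order(match(sim$meta$batch, perm))
    purrr::map_dfr(methods, function(m) {
      fit1 <- suppressWarnings(batchtree(sim$values, sim$meta, method = m,
                                         compute_asw = FALSE))
      fit2 <- suppressWarnings(batchtree(sim$values[, ord, drop = FALSE],
                                         sim$meta[ord, , drop = FALSE],
                                         method = m, compute_asw = FALSE))
      back <- fit2$corrected[, colnames(fit1$corrected), drop = FALSE]
      diff <- back - fit1$corrected
      sds <- apply(diff, 1, sd, na.rm = TRUE)
      asw1 <- asw(fit1$corrected, sim$meta$label)$asw
      asw2 <- asw(back, sim$meta$label)$asw
      tibble::tibble(rep = r, seed = seeds[r], method = m,
                     permutation = paste(perm, collapse = ","),
                     max_feature_sd = max(sds, na.rm = TRUE),
                     asw_label_diff = abs(asw1 - asw2))
    })
  })
  experiment_result(records, "order_invariance", seeds)
}

#' Reference-mode robustness to class imbalance
#'
#' Sweeps the per-batch depletion of one condition in a two-batch design and
#' corrects each dataset naively (linear adjuster) and with two reference
#' samples per batch (one per condition). Records the label ASW of both
#' modes: the naive score degrades as imbalance grows while the
#' reference-based score stays approximately constant.
#'
#' @param reps Repetitions per depletion level.
#' @param depletions Numbers of samples of the depleted condition removed
#'   per batch.
#' @param n_features,samples_per_batch,missing_fraction,n_references Dataset
#'   parameters (defaults: 600 features, 10% missingness, 2 references per
#'   batch).
#' @param seed Seed for the seed stream.
#' @return A `batchtree_experiment` tibble.
#' @export
sweep_reference_imbalance <- function(reps = 10, depletions = c(0, 2, 4, 6, 8),
                                      n_features = 600, samples_per_batch = 20,
                                      missing_fraction = 0.1, n_references = 2,
                                      seed = NULL) {
  seeds <- exp_seeds(seed, reps * length(depletions))
  grid <- tidyr::expand_grid(rep = seq_len(reps), depletion = depletions)
  grid$seed <- seeds
  records <- purrr::pmap_dfr(grid, function(rep, depletion, seed) {
    sim <- simulate_imbalanced_pair(n_features = n_features,
                                    samples_per_batch = samples_per_batch,
                                    depletion = depletion,
                                    n_references = n_references,
                                    missing_fraction = missing_fraction,
                                    seed = seed)
    fit_naive <- batchtree(sim$values, sim$meta, method = "limma")
    fit_ref <- batchtree(sim$values, sim$meta, method = "limma",
                         references = TRUE)
    tibble::tibble(rep = rep, depletion = depletion, seed = seed,
                   asw_label_naive = fit_naive$report$asw_label_corrected,
                   asw_label_reference = fit_ref$report$asw_label_corrected)
  })
  experiment_result(records, "reference_imbalance", seeds)
}

#' @export
print.batchtree_experiment <- function(x, ...) {
  cat("experiment:", attr(x, "experiment"), "-", nrow(x), "records\n")
  NextMethod()
}

#' Plot an experiment result
#'
#' Dispatches on the experiment id to a sensible default visualization
#' (ASW against the swept variable, grouped by method/mode).
#'
#' @param object A `batchtree_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.batchtree_experiment <- function(object, ...) {
  id <- attr(object, "experiment")
  df <- tibble::as_tibble(object)
  long_asw <- function(df, x) {
    df |>
      tidyr::pivot_longer(dplyr::starts_with("asw_label"),
                          names_to = "mode", values_to = "asw_label",
                          names_prefix = "asw_label_") |>
      ggplot2::ggplot(ggplot2::aes(x = .data[[x]], y = .data$asw_label,
                                   colour = .data$mode)) +
      ggplot2::stat_summary(fun = mean, geom = "line") +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::theme_minimal() +
      ggplot2::labs(y = "ASW (label)")
  }
  switch(id,
    reference_imbalance = long_asw(df, "depletion"),
    imbalance_covariates = long_asw(df, "ratio"),
    missingness_sweep = df |>
      ggplot2::ggplot(ggplot2::aes(x = .data$fraction,
                                   y = .data$asw_batch_corrected,
                                   colour = .data$method)) +
      ggplot2::stat_summary(fun = mean, geom = "line") +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "missing-value fraction", y = "ASW (batch), corrected"),
    batch_scaling = df |>
      ggplot2::ggplot(ggplot2::aes(x = .data$n_batches, y = .data$n_steps)) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(slope = 1, intercept = -1, linetype = 2) +
      ggplot2::theme_minimal() +
      ggplot2::labs(x = "batches", y = "pairwise steps"),
    abort(paste0("no default plot for experiment `", id, "`."))
  )
}
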