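#' Hierarchical batch-effect correction of a multi-batch dataset
#'
#' Integrates an incomplete feature-by-sample matrix over its batches by a
#' binary tree of pairwise correction steps. Each step applies the chosen
#' back-end (empirical-Bayes location/scale, linear model, or
#' reference-based linear model) to features with at least two numeric
#' values in both batches of the pair and propagates all other features
#' unchanged; merged pairs enter the next level as single batches. After an
#' initial singleton-removal pass, no numeric value is ever lost or created.
#'
#' Quality control reports average silhouette widths (ASW) with respect to
#' batch (lower after correction = better integration) and, when a `label`
#' column is present, with respect to the biological label (higher =
#' better-preserved signal), before and after correction.
#'
#' @param values Feature-by-sample numeric matrix (missing entries `NA`).
#' @param meta Sample metadata: `sample_id`, `batch`, optional `label`,
#'   covariate columns and `is_reference`.
#' @param method `"combat"` (empirical-Bayes location/scale) or `"limma"`
#'   (linear model).
#' @param covariates Optional character vector of categorical covariate
#'   columns whose effects must survive correction. Mutually exclusive with
#'   `references`.
#' @param references If `TRUE`, estimate batch shifts on the samples flagged
#'   `is_reference` in `meta` (linear model on references only) and apply
#'   them to all samples. Mutually exclusive with `covariates`.
#' @param workers,reduction,seq_threshold Scheduling parameters P, R, S; see
#'   [schedule_parallel()]. They control parallelism only and never change
#'   numeric output.
#' @param compute_asw Compute silhouette QC metrics (can be switched off for
#'   timing-sensitive runs).
#' @return An object of class `batchtree_fit` with elements `corrected`
#'   (matrix in the original row/column order), `report` (QC list), `steps`
#'   (per-step tibble), `plan`, `meta`, `method`. Use [glance()] for a
#'   one-row QC summary and [tidy()] for the per-step table.
#' @examples
#' sim <- simulate_batches(n_features = 60, n_batches = 4,
#'                         samples_per_batch = 6, seed = 1)
#' fit <- batchtree(sim$values, sim$meta, method = "limma")
#' glance(fit)
#' @export
batchtree <- function(values, meta, method = c("combat", "limma"),
                      covariates = NULL, references = FALSE,
                      workers = 1L, reduction = 2L, seq_threshold = 2L,
                      compute_asw = TRUE) {
  method <- match.arg(method)
  if (length(covariates) && references) {
    abort("covariate mode and reference mode are mutually exclusive.")
  }
  validate_omics(values)
  meta <- validate_meta(meta, values, covariates)
  step_method <- if (references) "references" else method
  if (references && !any(meta$is_reference)) {
    abort("reference mode requested but no sample is flagged as reference.")
  }
  batches <- unique(meta$batch)
  if (length(batches) < 2L) abort("nothing to integrate: need at least 2 batches.")
  if (references) {
    no_ref <- batches[!batches %in% unique(meta$batch[meta$is_reference])]
    if (length(no_ref)) {
      abort(paste0("batch(es) without reference samples: ",
                   paste(no_ref, collapse = ", ")))
    }
  }

  n_in <- sum(!is.na(values))
  has_label <- "label" %in% names(meta) && !all(is.na(meta$label))
  asw_raw_batch <- asw_raw_label <- NA_real_
  if (compute_asw) {
    d_raw <- omics_dist(values)
    asw_raw_batch <- asw(values, meta$batch, dist_matrix = d_raw)$asw
    if (has_label) asw_raw_label <- asw(values, meta$label, dist_matrix = d_raw)$asw
  }

  pre <- remove_singletons(values, meta)
  work <- pre$values
  n_after_pre <- sum(!is.na(work))

  plan <- build_tree(batches)
  sched <- schedule_parallel(plan, workers, reduction, seq_threshold)
  covdata <- if (length(covariates)) as.data.frame(meta[, covariates, drop = FALSE])

  t0 <- proc.time()[["elapsed"]]
  cur_batch <- meta$batch
  step_rows <- list()
  for (lvl in seq_along(plan)) {
    lv <- plan[[lvl]]
    w <- sched$workers[match(lvl, sched$level)]
    run_step <- function(k) {
      cols <- which(cur_batch %in% c(lv$left[k], lv$right[k]))
      adjust_pair_step(work[, cols, drop = FALSE], cur_batch[cols],
                       if (is.null(covdata)) NULL else covdata[cols, , drop = FALSE],
                       meta$is_reference[cols], step_method)
    }
    results <- if (w > 1L) {
      parallel::mclapply(seq_len(nrow(lv)), run_step, mc.cores = w)
    } else {
      lapply(seq_len(nrow(lv)), run_step)
    }
    for (k in seq_len(nrow(lv))) {
      r <- results[[k]]
      if (inherits(r, "try-error") || is.null(r$values)) {
        abort(paste0("pairwise step failed at level ", lvl, ", step ", k,
                     if (is.character(r)) paste0(": ", r) else ""))
      }
      cols <- which(cur_batch %in% c(lv$left[k], lv$right[k]))
      work[, cols] <- r$values
      cur_batch[cols] <- lv$merged[k]
      step_rows[[length(step_rows) + 1L]] <-
        tibble::tibble(level = lvl, step = k, left = lv$left[k],
                       right = lv$right[k], workers = w,
                       n_corrected = r$n_corrected,
                       n_propagated = r$n_propagated,
                       n_absent = r$n_absent)
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  asw_cor_batch <- asw_cor_label <- NA_real_
  if (compute_asw) {
    d_cor <- omics_dist(work)
    asw_cor_batch <- asw(work, meta$batch, dist_matrix = d_cor)$asw
    if (has_label) asw_cor_label <- asw(work, meta$label, dist_matrix = d_cor)$asw
  }

  report <- list(
    n_numeric_in = n_in,
    n_numeric_removed_preprocessing = n_in - n_after_pre,
    n_numeric_out = sum(!is.na(work)),
    asw_batch_raw = asw_raw_batch,
    asw_batch_corrected = asw_cor_batch,
    asw_label_raw = if (has_label) asw_raw_label else NA_real_,
    asw_label_corrected = if (has_label) asw_cor_label else NA_real_,
    elapsed_seconds = elapsed,
    n_pairwise_steps = attr(plan, "n_steps")
  )
  structure(list(corrected = work, report = report,
                 steps = dplyr::bind_rows(step_rows), plan = plan,
                 meta = meta, method = step_method),
            class = "batchtree_fit")
}

#' @export
print.batchtree_fit <- function(x, ...) {
  r <- x$report
  cat("batch-effect correction tree fit (", x$method, ")\n", sep = "")
  cat(sprintf("  %d features x %d samples, %d batches, %d pairwise steps\n",
              nrow(x$corrected), ncol(x$corrected),
              length(attr(x$plan, "batch_ids")), r$n_pairwise_steps))
  cat(sprintf("  numeric values: %d in, %d removed in pre-processing, %d out\n",
              r$n_numeric_in, r$n_numeric_removed_preprocessing, r$n_numeric_out))
  if (!is.na(r$asw_batch_raw)) {
    cat(sprintf("  ASW batch: %.4f -> %.4f\n", r$asw_batch_raw, r$asw_batch_corrected))
  }
  if (!is.na(r$asw_label_raw)) {
    cat(sprintf("  ASW label: %.4f -> %.4f\n", r$asw_label_raw, r$asw_label_corrected))
  }
  cat(sprintf("  elapsed: %.2f s (correction phases only)\n", r$elapsed_seconds))
  invisible(x)
}

#' Tidy the per-step table of a tree fit
#'
#' @param x A `batchtree_fit`.
#' @param ... Unused.
#' @return A tibble with one row per pairwise step: tree level, the two
#'   input batches, worker-pool size and per-feature outcome counts
#'   (corrected / propagated / absent).
#' @export
tidy.batchtree_fit <- function(x, ...) x$steps

#' One-row quality-control summary of a tree fit
#'
#' @param x A `batchtree_fit`.
#' @param ... Unused.
#' @return A one-row tibble with retained-value counts, ASW metrics before
#'   and after correction, elapsed seconds and the pairwise-step count.
#' @export
glance.batchtree_fit <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' Plot ASW quality metrics of a tree fit
#'
#' Bar chart of average silhouette width with respect to batch (and label,
#' when available) before and after correction.
#'
#' @param object A `batchtree_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.batchtree_fit <- function(object, ...) {
  r <- object$report
  df <- tibble::tibble(
    grouping = rep(c("batch", "label"), each = 2),
    stage = factor(rep(c("raw", "corrected"), 2), levels = c("raw", "corrected")),
    asw = c(r$asw_batch_raw, r$asw_batch_corrected,
            r$asw_label_raw, r$asw_label_corrected)
  )
  df <- df[!is.na(df$asw), , drop = FALSE]
  if (!nrow(df)) abort("fit was run with compute_asw = FALSE; nothing to plot.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grouping, y = .data$asw,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "average silhouette width",
                  fill = NULL,
                  title = "Integration quality (ASW)") +
    ggplot2::theme_minimal()
}

#' One-step whole-matrix linear correction
#'
#' Corrects all batches in a single ordinary-least-squares step (sum-to-zero
#' batch coding, covariates retained). Used as the flat comparator for the
#' tree-based procedure: on complete data the two differ only by per-feature
#' constant offsets.
#'
#' @inheritParams batchtree
#' @return Corrected matrix.
#' @export
correct_onestep_linear <- function(values, meta, covariates = NULL) {
  validate_omics(values)
  meta <- validate_meta(meta, values, covariates)
  covdata <- if (length(covariates)) as.data.frame(meta[, covariates, drop = FALSE])
  linear_adjust(values, meta$batch, covdata)
}
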