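#' Build the binary integration tree over batches
#'
#' Batches are paired in their given order at every level; an odd batch is
#' carried unpaired to the next level. For `N` input batches the whole tree
#' contains exactly `N - 1` pairwise correction steps.
#'
#' @param batch_ids Ordered character vector of distinct batch ids
#'   (`N >= 2`).
#' @return An object of class `batchtree_plan`: a list of levels, each a
#'   tibble with columns `left`, `right`, `merged`, plus attributes
#'   `n_steps` and `carried` per level.
#' @export
build_tree <- function(batch_ids) {
  batch_ids <- as.character(batch_ids)
  if (anyDuplicated(batch_ids)) abort("batch ids must be distinct.")
  if (length(batch_ids) < 2L) abort("nothing to integrate: need at least 2 batches.")
  levels <- list()
  active <- batch_ids
  while (length(active) > 1L) {
    n_pairs <- length(active) %/% 2L
    idx <- seq_len(n_pairs) * 2L
    left <- active[idx - 1L]
    right <- active[idx]
    merged <- paste(left, right, sep = "+")
    carried <- if (length(active) %% 2L == 1L) active[length(active)] else character()
    levels[[length(levels) + 1L]] <- tibble::tibble(left = left, right = right,
                                                    merged = merged)
    attr(levels[[length(levels)]], "carried") <- carried
    active <- c(merged, carried)
  }
  structure(levels,
            class = "batchtree_plan",
            batch_ids = batch_ids,
            n_steps = sum(vapply(levels, nrow, 0L)))
}

#' @export
print.batchtree_plan <- function(x, ...) {
  cat("batch-effect correction tree:", length(attr(x, "batch_ids")),
      "batches,", attr(x, "n_steps"), "pairwise steps,",
      length(x), "levels\n")
  for (i in seq_along(x)) {
    lv <- x[[i]]
    carried <- attr(lv, "carried")
    cat(sprintf("  level %d: %d step(s)%s\n", i, nrow(lv),
                if (length(carried)) paste0(", carried: ", carried) else ""))
  }
  invisible(x)
}

#' Derive the parallel execution schedule of a tree plan
#'
#' Sub-trees at each level are distributed over a worker pool of initial
#' size `workers`; after every level the pool size is divided by
#' `reduction` (floored, minimum 1). Once the number of active intermediate
#' batches at the start of a level is at most `seq_threshold`, the remaining
#' steps run sequentially. The schedule is a pure function of its inputs and
#' never affects numeric results, only the degree of parallelism.
#'
#' @param plan A `batchtree_plan` from [build_tree()].
#' @param workers Initial number of worker processes (`P >= 1`).
#' @param reduction Integer reduction factor between levels (`R >= 2`).
#' @param seq_threshold Number of active batches at which execution becomes
#'   sequential (`S >= 2`).
#' @return A tibble with one row per pairwise step: `level`, `step`, `left`,
#'   `right`, `merged`, `workers` (pool size during that level).
#' @export
schedule_parallel <- function(plan, workers = 1L, reduction = 2L,
                              seq_threshold = 2L) {
  stopifnot(inherits(plan, "batchtree_plan"))
  if (workers < 1L) abort("workers (P) must be >= 1.")
  if (reduction < 2L) abort("reduction (R) must be an integer >= 2.")
  if (seq_threshold < 2L) abort("seq_threshold (S) must be >= 2.")
  active <- length(attr(plan, "batch_ids"))
  pool <- as.integer(workers)
  rows <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    lv <- plan[[i]]
    w <- if (active <= seq_threshold) 1L else max(1L, min(pool, nrow(lv)))
    rows[[i]] <- tibble::tibble(level = i, step = seq_len(nrow(lv)),
                                left = lv$left, right = lv$right,
                                merged = lv$merged, workers = w)
    active <- nrow(lv) + length(attr(lv, "carried"))
    pool <- max(1L, pool %/% as.integer(reduction))
  }
  dplyr::bind_rows(rows)
}
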