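test_that("tree plans pair adjacent batches and carry the odd one", {
  plan4 <- build_tree(paste0("b", 1:4))
  expect_equal(length(plan4), 2L)
  expect_equal(plan4[[1]]$left, c("b1", "b3"))
  expect_equal(plan4[[1]]$right, c("b2", "b4"))
  expect_equal(attr(plan4, "n_steps"), 3L)

  plan5 <- build_tree(paste0("b", 1:5))
  expect_equal(attr(plan5, "n_steps"), 4L)
  expect_equal(attr(plan5[[1]], "carried"), "b5")

  plan20 <- build_tree(paste0("b", 1:20))
  expect_equal(attr(plan20, "n_steps"), 19L)
  expect_equal(length(plan20), 5L)

  expect_error(build_tree("b1"), "nothing to integrate")
})

test_that("every input batch appears exactly once as a leaf and steps total N - 1", {
  for (n in c(2, 3, 7, 16, 33, 64)) {
    ids <- paste0("b", seq_len(n))
    plan <- build_tree(ids)
    expect_equal(attr(plan, "n_steps"), n - 1L)
    leaves <- c(plan[[1]]$left, plan[[1]]$right, attr(plan[[1]], "carried"))
    expect_setequal(leaves, ids)
    # each level halves the active batch count, rounding up
    active <- n
    for (lv in plan) {
      expect_equal(nrow(lv) + length(attr(lv, "carried")), ceiling(active / 2))
      active <- ceiling(active / 2)
    }
  }
})

test_that("worker pools shrink by the reduction factor until the sequential phase", {
  plan <- build_tree(paste0("b", 1:16))
  sched <- schedule_parallel(plan, workers = 4, reduction = 2, seq_threshold = 2)
  per_level <- vapply(split(sched$workers, sched$level), unique, 0L)
  expect_equal(unname(per_level), c(4L, 2L, 1L, 1L))

  sched1 <- schedule_parallel(plan, workers = 1)
  expect_true(all(sched1$workers == 1L))
  expect_equal(nrow(sched1), 15L)

  expect_error(schedule_parallel(plan, workers = 0), "P")
  expect_error(schedule_parallel(plan, reduction = 1), "R")
})

test_that("scheduling parameters never change numeric output", {
  sim <- simulate_batches(n_features = 200, n_batches = 8,
                          samples_per_batch = 6, missing_fraction = 0.2,
                          seed = 41)
  base <- batchtree(sim$values, sim$meta, method = "limma",
                    compute_asw = FALSE)
  for (prs in list(c(4, 2, 2), c(4, 4, 8), c(2, 3, 4))) {
    alt <- batchtree(sim$values, sim$meta, method = "limma",
                     workers = prs[1], reduction = prs[2],
                     seq_threshold = prs[3], compute_asw = FALSE)
    expect_identical(alt$corrected, base$corrected)
  }
})

test_that("the engine integrates to a single batch and fills the QC report", {
  sim <- simulate_batches(n_features = 150, n_batches = 5,
                          samples_per_batch = 6, missing_fraction = 0.2,
                          seed = 43)
  fit <- batchtree(sim$values, sim$meta, method = "combat")
  r <- fit$report
  expect_equal(r$n_pairwise_steps, 4L)
  expect_equal(r$n_numeric_out,
               r$n_numeric_in - r$n_numeric_removed_preprocessing)
  expect_true(all(c(r$asw_batch_raw, r$asw_batch_corrected,
                    r$asw_label_raw, r$asw_label_corrected) >= -1))
  expect_true(all(c(r$asw_batch_raw, r$asw_batch_corrected,
                    r$asw_label_raw, r$asw_label_corrected) <= 1))
  expect_identical(colnames(fit$corrected), colnames(sim$values))
  expect_identical(is.na(fit$corrected), is.na(sim$values))
  # batch structure is reduced, label structure preserved or improved
  expect_lt(r$asw_batch_corrected, r$asw_batch_raw)
  expect_gt(r$asw_label_corrected, r$asw_label_raw)
})

test_that("mode combinations are validated", {
  sim <- simulate_batches(n_features = 30, n_batches = 2,
                          samples_per_batch = 4, seed = 47)
  expect_error(batchtree(sim$values, sim$meta, covariates = "label",
                         references = TRUE), "mutually exclusive")
  expect_error(batchtree(sim$values, sim$meta, references = TRUE),
               "no sample is flagged")
  one_batch <- sim$meta
  one_batch$batch <- "A"
  expect_error(batchtree(sim$values, one_batch), "nothing to integrate")
})
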