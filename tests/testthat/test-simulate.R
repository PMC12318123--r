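test_that("identical seeds give bit-identical datasets", {
  a <- simulate_batches(n_features = 100, n_batches = 4, samples_per_batch = 6,
                        missing_fraction = 0.2, n_references = 2, seed = 63)
  b <- simulate_batches(n_features = 100, n_batches = 4, samples_per_batch = 6,
                        missing_fraction = 0.2, n_references = 2, seed = 63)
  expect_identical(a$values, b$values)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
})

test_that("multiplicative batch effects follow the inverse-gamma mean", {
  set.seed(65)
  draws <- batchtree:::rinvgamma(1e5, 5, 2)
  expect_lt(abs(mean(draws) - 2 / (5 - 1)) / 0.5, 0.01)
  expect_true(all(draws > 0))
})

test_that("per-batch mean shifts track the drawn additive effects", {
  sim <- simulate_batches(n_features = 2000, n_batches = 4,
                          samples_per_batch = 50, seed = 67)
  # per feature and batch: empirical mean - (alpha + mean beta contribution)
  for (b in c("b1", "b3")) {
    cols <- sim$meta$batch == b
    beta_part <- colMeans(
      rbind(0, t(sim$truth$beta))[match(sim$meta$label[cols],
                                        c("cond1", "cond2")), , drop = FALSE])
    shift <- rowMeans(sim$values[, cols]) - sim$truth$alpha - beta_part
    err <- shift - sim$truth$gamma[, b]
    expect_lt(abs(mean(err)), 0.05)
    expect_gt(cor(shift, sim$truth$gamma[, b]), 0.95)
  }
})

test_that("the null-effect switch removes batch structure", {
  sim <- simulate_batches(n_features = 400, n_batches = 2,
                          samples_per_batch = 100, gamma_sd = 0,
                          delta_constant = 1, seed = 69)
  gap <- rowMeans(sim$values[, sim$meta$batch == "b1"]) -
    rowMeans(sim$values[, sim$meta$batch == "b2"])
  # standard error of a difference of two 100-sample means of unit-sd noise
  expect_lt(abs(mean(gap)), 3 * sqrt(2 / 100) / sqrt(400))
  expect_lt(abs(mean(gap)), 0.05)
})

test_that("feature-wise MCAR blanks whole blocks and respects the fraction", {
  sim <- simulate_batches(n_features = 200, n_batches = 20,
                          samples_per_batch = 10, seed = 71)
  masked <- apply_feature_mcar(sim$values, sim$meta, 0.5)
  for (b in unique(sim$meta$batch)) {
    block <- masked[, sim$meta$batch == b, drop = FALSE]
    n_obs <- rowSums(!is.na(block))
    expect_true(all(n_obs %in% c(0L, ncol(block))))   # all-or-nothing
    expect_equal(sum(n_obs == 0L), 100L)              # floor(0.5 * 200)
  }
  expect_identical(apply_feature_mcar(sim$values, sim$meta, 0), sim$values)
})

test_that("imbalanced pairs deplete opposite conditions symmetrically", {
  sim <- simulate_imbalanced_pair(n_features = 100, samples_per_batch = 20,
                                  depletion = 8, n_references = 2,
                                  missing_fraction = 0, seed = 73)
  tab <- table(sim$meta$batch, sim$meta$label)
  expect_equal(unname(tab["b1", ]), c(2, 10))   # cond1 depleted in b1
  expect_equal(unname(tab["b2", ]), c(10, 2))   # cond2 depleted in b2
  refs <- sim$meta[sim$meta$is_reference, ]
  expect_equal(as.integer(table(refs$batch)), c(2L, 2L))
  expect_equal(as.integer(table(refs$batch, refs$label)["b1", ]), c(1L, 1L))
  expect_error(simulate_imbalanced_pair(samples_per_batch = 10, depletion = 5),
               "entire condition")
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simulate_batches(n_batches = 1), "at least 2 batches")
  expect_error(simulate_batches(missing_fraction = 1), "missing_fraction")
  expect_error(simulate_batches(class_ratio = c(0.5, 0.6)), "sum to 1")
})
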