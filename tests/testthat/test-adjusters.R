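test_that("linear correction matches closed-form OLS on a 4-point system", {
  m <- toy_matrix(rbind(c(0, 0, 4, 4), c(1, 1, 5, 5)))
  meta <- toy_meta(c("A", "A", "B", "B"))
  out <- correct_pair_linear(m, meta)
  # sum-to-zero coding: both batches land on the midpoint of the batch means
  expect_equal(unname(out["f1", ]), rep(2, 4))
  expect_equal(unname(out["f2", ]), rep(3, 4))
})

test_that("two identical batches are a fixed point of the linear adjuster", {
  set.seed(7)
  block <- matrix(rnorm(40), 10, 4)
  m <- toy_matrix(cbind(block, block))
  meta <- toy_meta(rep(c("A", "B"), each = 4))
  expect_equal(correct_pair_linear(m, meta), m)
})

test_that("linear correction is invariant to swapping batch labels", {
  sim <- simulate_batches(n_features = 50, n_batches = 2,
                          samples_per_batch = 6, seed = 3)
  meta_swapped <- sim$meta
  meta_swapped$batch <- ifelse(sim$meta$batch == "b1", "b2", "b1")
  expect_equal(correct_pair_linear(sim$values, sim$meta),
               correct_pair_linear(sim$values, meta_swapped))
})

test_that("a covariate perfectly aligned with batch raises a rank error", {
  m <- toy_matrix(matrix(rnorm(24), 4, 6))
  meta <- toy_meta(rep(c("A", "B"), each = 3),
                   sex = rep(c("m", "f"), each = 3))
  expect_error(correct_pair_linear(m, meta, covariates = "sex"),
               "rank-deficient")
  expect_error(correct_pair_combat(m, meta, covariates = "sex"),
               "rank-deficient")
})

test_that("adjusters never convert numeric values to missing or vice versa", {
  sim <- simulate_batches(n_features = 120, n_batches = 2,
                          samples_per_batch = 8, missing_fraction = 0.3,
                          seed = 9)
  mask <- is.na(sim$values)
  for (fun in list(correct_pair_linear, correct_pair_combat)) {
    out <- suppressWarnings(fun(sim$values, sim$meta))
    expect_identical(is.na(out), mask)
  }
})

test_that("features fully missing in one batch are propagated bit-identically", {
  sim <- simulate_batches(n_features = 100, n_batches = 2,
                          samples_per_batch = 6, seed = 13)
  v <- sim$values
  v[1:10, sim$meta$batch == "b2"] <- NA          # PROPAGATE_A block
  out_l <- correct_pair_linear(v, sim$meta)
  out_c <- correct_pair_combat(v, sim$meta)
  expect_identical(out_l[1:10, ], v[1:10, ])
  expect_identical(out_c[1:10, ], v[1:10, ])
  expect_false(identical(out_l[11:100, ], v[11:100, ]))
})

test_that("correction reduces between-batch mean differences", {
  sim <- simulate_batches(n_features = 300, n_batches = 2,
                          samples_per_batch = 20, seed = 17)
  b1 <- sim$meta$batch == "b1"
  mean_gap <- function(m) {
    mean(abs(rowMeans(m[, b1]) - rowMeans(m[, !b1])))
  }
  before <- mean_gap(sim$values)
  expect_lt(mean_gap(correct_pair_linear(sim$values, sim$meta)), before)
  expect_lt(mean_gap(correct_pair_combat(sim$values, sim$meta)), before)
})

test_that("EB adjuster matches the reference empirical-Bayes implementation on complete data", {
  skip_if_not_installed("sva")
  sim <- simulate_batches(n_features = 150, n_batches = 2,
                          samples_per_batch = 10, seed = 21)
  mine <- correct_pair_combat(sim$values, sim$meta)
  ref <- suppressMessages(
    sva::ComBat(sim$values, batch = factor(sim$meta$batch)))
  expect_lt(max(abs(mine - ref)), 1e-3)  # convergence tolerances differ
  mine_cov <- correct_pair_combat(sim$values, sim$meta, covariates = "label")
  ref_cov <- suppressMessages(
    sva::ComBat(sim$values, batch = factor(sim$meta$batch),
                mod = model.matrix(~ factor(sim$meta$label))))
  expect_lt(max(abs(mine_cov - ref_cov)), 1e-3)
})

test_that("linear adjuster matches the reference linear-model implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_batches(n_features = 150, n_batches = 2,
                          samples_per_batch = 10, seed = 23)
  mine <- correct_pair_linear(sim$values, sim$meta, covariates = "label")
  ref <- limma::removeBatchEffect(
    sim$values, batch = factor(sim$meta$batch),
    design = model.matrix(~ factor(sim$meta$label)))
  expect_lt(max(abs(mine - ref)), 1e-10)
})

test_that("reference-based correction reproduces the closed-form shift", {
  m <- toy_matrix(rbind(c(0, 0, 10, 10, 3, 3, 13, 13)))
  m <- rbind(m, m + 1); rownames(m) <- c("f1", "f2")
  meta <- toy_meta(rep(c("A", "B"), each = 4),
                   is_reference = rep(c(TRUE, TRUE, FALSE, FALSE), 2))
  out <- correct_pair_references(m, meta)
  expect_equal(unname(out["f1", ]), c(1.5, 1.5, 11.5, 11.5, 1.5, 1.5, 11.5, 11.5))
  expect_equal(unname(out["f2", ]), c(1.5, 1.5, 11.5, 11.5, 1.5, 1.5, 11.5, 11.5) + 1)
})

test_that("identical references across batches produce a zero shift", {
  set.seed(19)
  refs <- matrix(rnorm(20), 5, 4)
  nonrefs <- matrix(rnorm(20, mean = 3), 5, 4)
  m <- toy_matrix(cbind(refs[, 1:2], nonrefs[, 1:2], refs[, 1:2], nonrefs[, 3:4]))
  meta <- toy_meta(rep(c("A", "B"), each = 4),
                   is_reference = rep(c(TRUE, TRUE, FALSE, FALSE), 2))
  out <- correct_pair_references(m, meta)
  expect_equal(out, m)
})

test_that("a batch without references is rejected", {
  m <- toy_matrix(matrix(rnorm(24), 3, 8))
  meta <- toy_meta(rep(c("A", "B"), each = 4),
                   is_reference = c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 4)))
  expect_error(correct_pair_references(m, meta), "reference sample")
})

test_that("zero-variance features are propagated with a warning", {
  sim <- simulate_batches(n_features = 50, n_batches = 2,
                          samples_per_batch = 5, seed = 29)
  v <- sim$values
  v[1, ] <- 7                              # flat feature in both batches
  expect_warning(out <- correct_pair_combat(v, sim$meta), "zero pooled variance")
  expect_identical(out[1, ], v[1, ])
})
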