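test_that("complete-data distances are plain Euclidean", {
  m <- toy_matrix(rbind(c(0, 3), c(0, 4)))
  d <- omics_dist(m)
  expect_equal(d["s1", "s2"], 5)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
})

test_that("shared-feature rescaling recovers the complete-data distance on mirrored vectors", {
  # 4 features; sample 2 misses two of them, but the observed half repeats
  # the same (3, 4) offset pattern, so the rescaled distance is unchanged.
  full <- toy_matrix(rbind(c(0, 3), c(0, 4), c(1, 4), c(1, 5)))
  half <- full
  half[3:4, 2] <- NA
  expect_equal(omics_dist(half)["s1", "s2"],
               sqrt((3^2 + 4^2) * 4 / 2))
  expect_equal(omics_dist(full)["s1", "s2"], omics_dist(half)["s1", "s2"])
})

test_that("distances match a brute-force double loop under missingness", {
  set.seed(55)
  m <- toy_matrix(matrix(rnorm(60), 10, 6))
  m[sample(60, 15)] <- NA
  expect_equal(omics_dist(m), naive_dist(m), tolerance = 1e-12)
})

test_that("disjoint observation patterns are rejected with the pair named", {
  m <- toy_matrix(rbind(c(1, NA), c(NA, 2)))
  expect_error(omics_dist(m), "share no observed features.*s[12], s[12]")
})

test_that("silhouette matches a brute-force computation on a 3-group toy", {
  set.seed(57)
  centers <- rep(c(0, 4, 9), each = 4)
  m <- toy_matrix(matrix(rnorm(5 * 12, mean = rep(centers, each = 5), sd = 1), 5, 12))
  g <- rep(c("x", "y", "z"), each = 4)
  res <- asw(m, g)
  expect_equal(res$asw, naive_asw(omics_dist(m), g), tolerance = 1e-12)
  expect_equal(res$n_samples_used, 12L)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(g)), dmatrix = omics_dist(m))
  expect_equal(res$asw, mean(sil[, "sil_width"]), tolerance = 1e-12)
})

test_that("well-separated groups approach silhouette 1, random groups 0", {
  set.seed(59)
  m <- toy_matrix(cbind(matrix(rnorm(50 * 6, 0, 0.01), 50),
                        matrix(rnorm(50 * 6, 100, 0.01), 50)))
  g <- rep(c("a", "b"), each = 6)
  expect_gt(asw(m, g)$asw, 0.99)
  vals <- replicate(5, {
    mm <- toy_matrix(matrix(rnorm(30 * 200), 30, 200))
    asw(mm, sample(rep(c("a", "b"), 100)))$asw
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("asw is invariant to sample order and per-feature constant shifts", {
  set.seed(61)
  m <- toy_matrix(matrix(rnorm(20 * 9), 20, 9))
  g <- rep(c("a", "b", "c"), each = 3)
  ref <- asw(m, g)$asw
  perm <- sample(9)
  expect_equal(asw(m[, perm], g[perm])$asw, ref, tolerance = 1e-12)
  shifted <- m + rnorm(20)          # constant per feature across samples
  expect_equal(asw(shifted, g)$asw, ref, tolerance = 1e-9)
})

test_that("silhouette edge cases: missing groups, singletons, degenerate groupings", {
  m <- toy_matrix(matrix(rnorm(5 * 6), 5, 6))
  res <- asw(m, c("a", "a", "b", "b", NA, "b"))
  expect_equal(res$n_samples_used, 5L)
  expect_equal(res$n_excluded, 1L)
  # singleton group members contribute width 0
  res2 <- asw(m, c("a", "a", "a", "a", "a", "b"))
  expect_equal(res2$widths$width[res2$widths$group == "b"], 0)
  expect_error(asw(m, rep("a", 6)), "at least 2 groups")
})
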