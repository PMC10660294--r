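test_that("normalization maps the 64-bit range onto [0, 1]", {
  expect_identical(normalize_hashes("0000000000000000"), 0)
  expect_identical(normalize_hashes("ffffffffffffffff"), 1)
  expect_equal(normalize_hashes("7fffffffffffffff"), 0.5, tolerance = 2^-62)
})

test_that("histogram counts are conserved and the mean is exact", {
  set.seed(4)
  v <- runif(12345)
  rep <- uniformity_histogram(v, bins = 100L)
  expect_identical(sum(rep$bin_counts), 12345L)
  expect_identical(rep$mean, 12345 / 100)
  # degenerate pile-up: everything lands in one bin
  rep1 <- uniformity_histogram(rep(0.0005, 1000L), bins = 1000L)
  expect_identical(sort(rep1$bin_counts, decreasing = TRUE)[1L], 1000L)
  expect_identical(sum(rep1$bin_counts > 0L), 1L)
  # mean count 1; variance = ((1000-1)^2 + 999 * 1) / 999 = 1000
  expect_equal(rep1$sd, sqrt(1000))
  expect_error(uniformity_histogram(c(0.5, 1.5)), "\\[0, 1\\]")
  expect_error(uniformity_histogram(numeric(0L)), "nonempty")
})

test_that("K-S against the uniform has its closed-form values on simple inputs", {
  expect_equal(ks_uniform(0.5)$statistic, 0.5)
  n <- 40L
  grid <- (1:n) / n
  expect_equal(ks_uniform(grid)$statistic, 1 / n)
  expect_error(ks_uniform(numeric(0L)), "nonempty")
})

test_that("adjacent pairing is disjoint by default, sliding on request", {
  expect_identical(adjacent_pairs(c(1, 2, 3, 4) / 10),
                   list(u0 = c(0.1, 0.3), u1 = c(0.2, 0.4)))
  expect_identical(adjacent_pairs(c(1, 2, 3) / 10),
                   list(u0 = 0.1, u1 = 0.2))  # trailing element dropped
  ov <- adjacent_pairs(c(1, 2, 3) / 10, overlapping = TRUE)
  expect_identical(ov, list(u0 = c(0.1, 0.2), u1 = c(0.2, 0.3)))
  expect_identical(lengths(adjacent_pairs(0.5)), c(u0 = 0L, u1 = 0L))
  expect_identical(length(adjacent_pairs(runif(226))$u0), 113L)
})

test_that("Box-Muller reproduces hand-computable transforms", {
  bm <- box_muller(1, 0.37)
  expect_equal(c(bm$z0, bm$z1), c(0, 0))
  bm <- box_muller(exp(-1 / 2), 0)
  expect_equal(c(bm$z0, bm$z1), c(1, 0))
  bm <- box_muller(exp(-2), 0.25)
  expect_equal(c(bm$z0, bm$z1), c(0, 2), tolerance = 1e-12)
  # U0 == 0 pairs are skipped, not clamped
  bm <- box_muller(c(0, 0.5), c(0.1, 0.2))
  expect_identical(bm$n_skipped, 1L)
  expect_length(bm$z0, 1L)
  expect_error(box_muller(c(0.1, 0.2), 0.3), "equal length")
})

test_that("Box-Muller on true uniforms passes normality at n = 1000", {
  set.seed(31)
  bm <- box_muller(runif(1000), runif(1000))
  sw <- normality_check(bm$z0)
  expect_gt(sw$p_value, 0.05)
  expect_gt(sw$W, 0.99)
})

test_that("normality check enforces the Shapiro-Wilk size range and has power", {
  expect_error(normality_check(c(1, 2)), "between 3 and 5000")
  expect_error(normality_check(rnorm(5001)), "between 3 and 5000")
  set.seed(13)
  sw_unif <- normality_check(runif(1000))  # far from normal
  expect_lt(sw_unif$p_value, 0.05)
})

test_that("independence check returns Pearson r with the Fisher-z SE", {
  z <- c(-1.2, 0.3, 0.8, 1.7, -0.5)
  expect_equal(independence_check(z, z)$r, 1)
  expect_equal(independence_check(z, -z)$r, -1)
  expect_equal(independence_check(rnorm(1000), rnorm(1000))$se, 1 / sqrt(997))
  expect_error(independence_check(z, z[-1]), "equal length")
})

test_that("paired t-test matches the hand-computed statistic", {
  res <- paired_ttest(c(1, 2, 3), c(1.1, 2.3, 2.9))
  expect_equal(res$t, -0.1 / (0.2 / sqrt(3)), tolerance = 1e-12)  # -0.866
  swapped <- paired_ttest(c(1.1, 2.3, 2.9), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_ttest(1, 2), "at least 2")
  expect_error(paired_ttest(c(1, 2), 3), "equal length")
})

test_that("qq points pair sorted samples with normal quantiles", {
  x <- c(3, 1, 2)
  qq <- qq_points(x)
  expect_identical(qq$sample, c(1, 2, 3))
  expect_equal(qq$theoretical, qnorm(ppoints(3)))
})
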