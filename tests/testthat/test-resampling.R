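test_that("bootstrap resamples whole columns with replacement", {
  # single column: every bootstrap mean is that column's trace
  x <- cbind(c(1, 5, 9))
  S <- bootstrap_mean_samples(x, 20)
  expect_identical(dim(S), c(20L, 3L))
  expect_true(all(t(S) == as.vector(x)))
  # constant data: constant bootstrap means
  S2 <- bootstrap_mean_samples(constant_group(7), 50)
  expect_true(all(S2 == 7))
  # T=1, n=2, values {0,10}: the 4 equally likely draws give means
  # {0,5,10} with probabilities {1/4,1/2,1/4}
  withr::with_seed(99, {
    S3 <- bootstrap_mean_samples(matrix(c(0, 10), 1, 2), 8000)
  })
  freq <- table(factor(S3, levels = c(0, 5, 10))) / 8000
  se3 <- 3 * sqrt(0.25 * 0.75 / 8000)
  expect_lt(abs(freq[["0"]] - 0.25), se3)
  expect_lt(abs(freq[["5"]] - 0.5), 3 * sqrt(0.5 * 0.5 / 8000))
  expect_lt(abs(freq[["10"]] - 0.25), se3)
  expect_error(bootstrap_mean_samples(matrix(numeric(0), 0, 0), 10),
               "non-empty")
})

test_that("adjusted percentile CI widens the raw interval by sqrt(n/(n-1))", {
  # degenerate distribution: zero-width interval at any level and n
  expect_equal(adjusted_percentile_ci(rep(3.5, 100), 0.95, 2), c(3.5, 3.5))
  expect_equal(adjusted_percentile_ci(rep(3.5, 100), 0.99, 7), c(3.5, 3.5))

  # samples 0..100, level 0.95, n=2: oracle recomputed from the stated
  # formula with independent quantile interpolation
  s <- 0:100
  h <- 0.025 * 100  # type-7 index into the 101 order statistics
  q_low <- s[floor(h) + 1] + (h - floor(h)) * (s[floor(h) + 2] - s[floor(h) + 1])
  h2 <- 0.975 * 100
  q_high <- s[floor(h2) + 1] + (h2 - floor(h2)) * (s[floor(h2) + 2] - s[floor(h2) + 1])
  m <- mean(s)
  f <- sqrt(2)
  expect_equal(c(q_low, q_high), c(2.5, 97.5))
  got <- adjusted_percentile_ci(s, 0.95, 2)
  expect_equal(got, c(m - f * (m - q_low), m + f * (q_high - m)),
               tolerance = 1e-12)
  expect_equal(got, c(-17.1751442, 117.1751442), tolerance = 1e-6)

  # large n: factor tends to 1, interval tends to the raw percentiles
  got_big <- adjusted_percentile_ci(s, 0.95, 1e7)
  expect_equal(got_big, c(2.5, 97.5), tolerance = 1e-4)
  # n = 1 is the degenerate case, factor 1
  expect_equal(adjusted_percentile_ci(s, 0.95, 1), c(2.5, 97.5))

  expect_error(adjusted_percentile_ci(s, 1.95, 2), "between 0 and 1")
  expect_error(adjusted_percentile_ci(numeric(0), 0.95, 2), "non-empty")
})

test_that("baseline significance flags CIs strictly excluding the null of 0", {
  cfg <- bootstrap_config(0.95, 100, seed = 1)
  z <- baseline_significance(constant_group(0), cfg)
  expect_equal(z$band$lower, rep(0, 4))
  expect_equal(z$band$upper, rep(0, 4))
  expect_identical(z$map, rep(0L, 4))  # degenerate interval contains 0

  pos <- baseline_significance(constant_group(5), cfg)
  expect_equal(pos$band$lower, rep(5, 4))
  expect_identical(pos$map, rep(1L, 4))

  neg <- baseline_significance(constant_group(-5), cfg)
  expect_identical(neg$map, rep(1L, 4))
})

test_that("between-group difference bootstraps each group and subtracts", {
  cfg <- bootstrap_config(0.95, 200, seed = 2)
  a <- constant_group(3)
  same <- between_group_difference(a, a, cfg)
  expect_identical(same$map, rep(0L, 4))
  off <- between_group_difference(a + 10, a, cfg)
  expect_equal(off$band$lower, rep(10, 4))
  expect_equal(off$band$upper, rep(10, 4))
  expect_identical(off$map, rep(1L, 4))
  # column counts may differ between groups
  b <- constant_group(3, n_cols = 5L)
  expect_identical(between_group_difference(a, b, cfg)$map, rep(0L, 4))
  expect_error(between_group_difference(a, constant_group(3, n_rows = 9L),
                                        cfg),
               "same number of timepoints")
})

test_that("within-group difference is paired and antisymmetric", {
  d <- tiny_dataset(n_groups = 2L, n_rows = 50L, n_cols = 7L, seed = 8L)
  cfg <- bootstrap_config(0.95, 300, design = "within", seed = 31)
  expect_identical(within_group_difference(d$grpA, d$grpA, cfg)$map,
                   rep(0L, 50))
  ab <- within_group_difference(d$grpA, d$grpB, cfg)
  ba <- within_group_difference(d$grpB, d$grpA, cfg)
  # identical seed means identical resample draws, so swapping the groups
  # negates and swaps the band and leaves the map unchanged
  expect_equal(ab$band$lower, -ba$band$upper, tolerance = 1e-12)
  expect_equal(ab$band$upper, -ba$band$lower, tolerance = 1e-12)
  expect_identical(ab$map, ba$map)
  expect_error(
    within_group_difference(d$grpA, d$grpB[, 1:5], cfg),
    "same number of animals/trials")
  # a strong paired effect is detected everywhere
  strong <- within_group_difference(d$grpA + 10, d$grpA +
                                      matrix(rnorm(350, 0, 0.1), 50, 7),
                                    cfg)
  expect_gt(mean(strong$map), 0.99)
})

test_that("consecutive threshold zeroes short runs and keeps long ones", {
  expect_identical(apply_consecutive_threshold(c(1, 1, 0, 1), 2),
                   c(1L, 1L, 0L, 0L))
  expect_identical(apply_consecutive_threshold(c(0, 1, 1, 1, 0, 1, 1), 3),
                   c(0L, 1L, 1L, 1L, 0L, 0L, 0L))
  m <- c(1, 0, 1, 1, 0, 1, 1, 1)
  expect_identical(apply_consecutive_threshold(m, 0), as.integer(m))
  expect_identical(apply_consecutive_threshold(m, 1), as.integer(m))
  expect_error(apply_consecutive_threshold(c(0, 2, 1), 2), "binary")
  expect_error(apply_consecutive_threshold(c(0, 1), -1), "non-negative")
})

test_that("thresholding is monotone in k and idempotent", {
  withr::with_seed(7, {
    for (i in 1:25) {
      m <- rbinom(60, 1, runif(1, 0.2, 0.8))
      prev <- apply_consecutive_threshold(m, 0)
      for (k in c(2L, 4L, 5L, 9L)) {
        cur <- apply_consecutive_threshold(m, k)
        expect_true(all(cur <= prev))           # pointwise non-increasing
        expect_identical(apply_consecutive_threshold(cur, k), cur)
        prev <- cur
      }
    }
  })
})

test_that("99% maps are nested inside 95% maps under shared draws", {
  d <- tiny_dataset(n_groups = 1L, n_rows = 300L, n_cols = 7L, seed = 12L)
  r95 <- baseline_significance(d$grpA,
                               bootstrap_config(0.95, 500, seed = 77))
  r99 <- baseline_significance(d$grpA,
                               bootstrap_config(0.99, 500, seed = 77))
  expect_true(all(r99$band$lower <= r95$band$lower + 1e-12))
  expect_true(all(r99$band$upper >= r95$band$upper - 1e-12))
  expect_true(all(r99$map <= r95$map))
})

test_that("threshold recommender takes the most conservative duration", {
  # dopamine sensor kinetics (~0.08 s rise + ~0.33 s half-decay) at 10 Hz
  expect_identical(recommend_consecutive_threshold(0.08, 0.33, NULL, 10), 4L)
  # 6 Hz low-pass rule of thumb (1 s / filter Hz) at 10 Hz
  expect_identical(recommend_consecutive_threshold(0, 0, 6, 10), 2L)
  # the longer duration wins
  expect_identical(recommend_consecutive_threshold(0.08, 0.33, 6, 10), 4L)
  # a user-defined minimum can dominate (e.g. 0.5 s behaviour duration)
  expect_identical(
    recommend_consecutive_threshold(0.08, 0.33, 6, 10, user_min_s = 0.5), 5L)
  # all constraints zero floors at one sample
  expect_identical(recommend_consecutive_threshold(0, 0, NULL, 10), 1L)
  # thresholds scale with the sampling rate: 10 samples at 10 Hz equals
  # 1 sample of the same duration at 1 Hz
  expect_identical(recommend_consecutive_threshold(0, 0, NULL, 10,
                                                   user_min_s = 1), 10L)
  expect_identical(recommend_consecutive_threshold(0, 0, NULL, 1,
                                                   user_min_s = 1), 1L)
  expect_error(recommend_consecutive_threshold(0.1, 0.1, NULL, 0),
               "positive")
  expect_error(recommend_consecutive_threshold(-0.1, 0.1, NULL, 10),
               "non-negative")
})

test_that("significant_rows lists 0-based flagged indices in order", {
  expect_identical(significant_rows(c(0, 1, 1, 0)), c(1L, 2L))
  expect_identical(significant_rows(c(0, 0, 0)), integer(0))
  expect_identical(significant_rows(c(1, 1, 1)), c(0L, 1L, 2L))
})
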