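test_that("the Monte Carlo oracle recovers the pivotal normal bias", {
  est <- mc_expected_bias("normal", reps = 2e4, seed = 1)
  expect_lt(abs(est$mean_bias - 0.5), 3 * est$mc_se)
  expect_gt(est$mc_se, 0)
  ## point hypotheses are unbiased identically
  est0 <- mc_expected_bias("normal", h = h_point(0), reps = 100, seed = 1)
  expect_identical(est0$mean_bias, 0)
  expect_error(mc_expected_bias("normal", h = h_above(0), reps = 10),
               "flat-prior")
})

test_that("the oracle validates a spot entry of each family table", {
  est <- mc_expected_bias("t", nu = 1, reps = 2e4, seed = 2)
  expect_lt(abs(est$mean_bias - 1.39), 3 * est$mc_se + 0.005)
  est <- mc_expected_bias("binomial", n = 1, reps = 2e4, seed = 3)
  expect_lt(abs(est$mean_bias - 0.231), 3 * est$mc_se + 0.0005)
  est <- mc_expected_bias("f", nu1 = 5, nu2 = 5, reps = 2e4, seed = 4)
  expect_lt(abs(est$mean_bias - 0.527), 3 * est$mc_se + 0.005)
  ## binomial oracle also covers restricted regions
  est <- mc_expected_bias("binomial", n = 5, h = h_interval(0, 0.5),
                          reps = 2e4, seed = 5)
  expect_lt(abs(est$mean_bias - 0.183), 3 * est$mc_se + 0.0005)
})

test_that("identical seeds reproduce bit-for-bit; different seeds do not", {
  a <- mc_expected_bias("normal", reps = 5e3, seed = 7)
  b <- mc_expected_bias("normal", reps = 5e3, seed = 7)
  expect_identical(a$mean_bias, b$mean_bias)
  c2 <- mc_expected_bias("normal", reps = 5e3, seed = 8)
  expect_false(identical(a$mean_bias, c2$mean_bias))
  t1 <- run_limited_multiplicity(scenarios = 1, m_values = 2, reps = 500,
                                 seed = 11)
  t2 <- run_limited_multiplicity(scenarios = 1, m_values = 2, reps = 500,
                                 seed = 11)
  expect_identical(t1, t2)
})

test_that("a single test recovers the single-test bias and near-zero
           adjusted bias", {
  res <- run_limited_multiplicity(scenarios = 1, m_values = 1, reps = 4000,
                                  seed = 3)
  un <- subset(res, quantity == "bias_unadj")
  ad <- subset(res, quantity == "bias_adj")
  expect_lt(abs(un$value - 0.5), 3 * un$mc_se)
  expect_lt(abs(ad$value - 0), 3 * ad$mc_se)
  ## single- and multiple-test errors coincide when m = 1
  expect_equal(subset(res, quantity == "mse_single")$value,
               subset(res, quantity == "mse_multiple")$value,
               tolerance = 1e-12)
})

test_that("well-separated means remove the pooling benefit; shared means
           keep it", {
  res <- run_limited_multiplicity(scenarios = c(1, 3), m_values = 5,
                                  reps = 3000, seed = 9)
  s1 <- subset(res, scenario == 1)
  s3 <- subset(res, scenario == 3)
  ## scenario 3 (grid on [-5, 5], se = 0.1): no pooling benefit
  expect_equal(subset(s3, quantity == "mse_multiple")$value,
               subset(s3, quantity == "mse_single")$value, tolerance = 0.01)
  ## scenario 1 (all means equal): pooling shrinks the error
  expect_lt(subset(s1, quantity == "mse_multiple")$value,
            0.6 * subset(s1, quantity == "mse_single")$value)
  ## unadjusted bias far below 1/2 for pooled identical means
  expect_lt(subset(s1, quantity == "bias_unadj")$value, 0.2)
})

test_that("the large-scale experiment shows shrinkage without reranking", {
  res <- run_large_scale(m = 300, null_fraction = 0.9, seed = 5,
                         p_theta_values = c(1, 0.01))
  tests <- res$tests
  top <- order(-tests$log10_ebf10_single)[1:30]
  expect_true(all(tests$log10_ebf10_p1[top] <=
                    tests$log10_ebf10_single[top] + 1e-9))
  ## mean rank of non-null tests barely moves
  expect_lt(abs(res$mean_ranks["single"] - res$mean_ranks["multiple"]), 15)
  ## p_theta = 0.01 stays in the same ballpark for the top tests
  expect_lt(max(abs(tests$log10_ebf10_p1[top] -
                      tests$log10_ebf10_p0.01[top])), 1)
  ## degenerate input: no non-null tests, proportions reported absent
  res0 <- run_large_scale(m = 50, null_fraction = 1, seed = 6,
                          p_theta_values = 1)
  expect_null(res0$mean_ranks)
  expect_false("tp_single" %in% names(res0$screen$counts))
})
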