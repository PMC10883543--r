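test_that("binomial posterior marginal likelihood has the exact Beta form", {
  ## n = 1, x = 1, uniform prior, full region: B(3,1)/B(2,1) = 2/3
  expect_equal(exp(binom_lml(1, 1, h_full())), 2 / 3, tolerance = 1e-12)
  expect_equal(exp(binom_lml(0, 1, h_full())), 2 / 3, tolerance = 1e-12)
  ## full region: both incomplete-Beta masses are 1
  expect_equal(binom_lml(3, 7, h_full()), binom_lml(3, 7, h_interval(0, 1)),
               tolerance = 1e-12)
  ## region masses against quadrature
  for (case in list(c(2, 6), c(9, 12), c(0, 4)))
    expect_equal(binom_lml(case[1], case[2], h_interval(0.2, 0.7)),
                 oracle_binom_lml(case[1], case[2], 0.2, 0.7),
                 tolerance = 1e-8)
  ## large counts survive in log space
  expect_true(is.finite(binom_lml(4321, 9000, h_interval(0, 0.5))))
})

test_that("the exact double sum reproduces the tabulated bias", {
  full <- c(0.231, 0.316, 0.360, 0.387, 0.405, 0.418, 0.428, 0.436,
            0.442, 0.447)
  half <- c(0.093, 0.133, 0.157, 0.172, 0.183, 0.191, 0.198, 0.203,
            0.207, 0.210)
  for (n in 1:10) {
    expect_lt(abs(bv(binom_bias(n)) - full[n]), 0.0005)
    expect_lt(abs(bv(binom_bias(n, h_interval(0, 0.5))) - half[n]), 0.0005)
  }
  ## n = 1 is exactly (1/3) log 2 by enumerating the four outcomes
  expect_equal(bv(binom_bias(1)), log(2) / 3, tolerance = 1e-12)
  ## the two half-interval biases are equal, hence cancel
  expect_equal(bv(binom_bias(7, h_interval(0.5, 1))),
               bv(binom_bias(7, h_interval(0, 0.5))), tolerance = 1e-12)
})

test_that("bias grows with n towards the normal-theory limits", {
  full <- vapply(c(1:10, 50, 200), function(n) bv(binom_bias(n)), numeric(1))
  half <- vapply(c(1:10, 50, 200),
                 function(n) bv(binom_bias(n, h_interval(0, 0.5))),
                 numeric(1))
  expect_true(all(diff(full) > 0))
  expect_true(all(diff(half) > 0))
  expect_equal(full[length(full)], 0.5, tolerance = 0.02)
  expect_equal(half[length(half)], 0.25, tolerance = 0.02)
})

test_that("the joint prior predictive is a proper distribution and the
           uniform prior gives a uniform predictive", {
  for (n in c(1, 5, 20)) for (alpha in c(0.5, 1, 2)) {
    xy <- expand.grid(x = 0:n, y = 0:n)
    lpr <- lchoose(n, xy$x) + lchoose(n, xy$y) +
      lbeta(xy$x + xy$y + alpha, 2 * n - xy$x - xy$y + alpha) -
      lbeta(alpha, alpha)
    expect_equal(sum(exp(lpr)), 1, tolerance = 1e-10,
                 info = paste(n, alpha))
    if (alpha == 1) {
      marg <- as.vector(tapply(exp(lpr), xy$x, sum))
      expect_equal(marg, rep(1 / (n + 1), n + 1), tolerance = 1e-10)
    }
  }
})

test_that("ebf_binom handles symmetric and point-null comparisons", {
  h_lo <- h_interval(0, 0.5); h_hi <- h_interval(0.5, 1)
  expect_equal(ebf_binom(5, 10, h_lo, h_hi)$ebf01, 1, tolerance = 1e-10)
  ## biases cancel: the EBF equals the raw Eq-15 ratio
  e <- ebf_binom(8, 10, h_lo, h_hi)
  raw <- exp(binom_lml(8, 10, h_lo) - binom_lml(8, 10, h_hi))
  expect_equal(e$ebf01, raw, tolerance = 1e-12)
  expect_identical(e$favoured, "H1")
  ## point null vs full with the Table-2 machinery bias
  e <- ebf_binom(5, 10, h_point(0.5), h_full())
  by_hand <- exp(dbinom(5, 10, 0.5, log = TRUE) -
                 (binom_lml(5, 10, h_full()) - bv(binom_bias(10))))
  expect_equal(e$ebf01, by_hand, tolerance = 1e-12)
})

test_that("negative binomial differs from binomial and averaging sits
           between the models", {
  eb <- ebf_binom(8, 10, h_point(0.5), h_full())
  en <- ebf_negbinom(8, 10, h_point(0.5), h_full(), reps = 5e4)
  expect_false(isTRUE(all.equal(eb$ebf01, en$ebf01, tolerance = 1e-4)))
  ## equal-weight average of identical models returns the model value
  ea <- ebf_binom_averaged(8, 10, h_point(0.5), h_full(), reps = 5e4)
  corr <- function(e, side) exp(e[[side]] - e[[sub("log_m", "bias", side)]])
  m0 <- c(corr(eb, "log_m0"), corr(en, "log_m0"))
  m1 <- c(corr(eb, "log_m1"), corr(en, "log_m1"))
  expect_equal(ea$ebf01, mean(m0) / mean(m1), tolerance = 1e-10)
  ## averaged corrected marginals lie between the per-model ones
  expect_true(min(m1) <= mean(m1) && mean(m1) <= max(m1))
  expect_error(ebf_negbinom(0, 4, h_point(0.5), h_full()))
})

test_that("negative-binomial bias approaches the binomial value for large
           counts and zero for point hypotheses", {
  expect_identical(bv(negbinom_bias(3, h_point(0.5))), 0)
  b <- bv(negbinom_bias(3, reps = 5e4))
  expect_gt(b, 0.2); expect_lt(b, 0.55)
})
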