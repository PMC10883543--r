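test_that("two-sided, one-sided and directional closed forms match the
           printed worked examples", {
  expect_equal(ebf_z_twosided(1.28)$ebf01, 1.03, tolerance = 0.005 / 1.03)
  expect_equal(ebf_z_twosided(0)$ebf01, 2.33, tolerance = 0.002)
  ## z^2 = d leaves only the dimension constant
  for (d in 1:4)
    expect_equal(ebf_z_twosided(sqrt(d), d = d)$ebf01, 2^(d / 2))
  ## Higgs: one-sided at 5 sigma, reported in favour of the alternative
  expect_equal(1 / ebf_z_onesided(5)$ebf01, 1.48e5, tolerance = 0.01)
  ## stent: directional with a clinically meaningful cut at 30 s
  expect_equal(ebf_z_directional(estimate = 16.6, se = 12.96, cut = 30)$ebf01,
               2.29, tolerance = 0.005 / 2.29)
  expect_equal(ebf_z_directional(0)$ebf01, 1)
})

test_that("one-sided forms at z = 0 match quadrature of the truncated
           normal integrals", {
  ## Eq-5 numerator/denominator by brute force plus the bias constant
  l1 <- oracle_normal_lml(0, 1, 0, Inf)
  both <- exp(dnorm(0, log = TRUE) - (l1 - 0.25))
  expect_equal(ebf_z_onesided(0)$ebf01, both, tolerance = 1e-8)
  expect_equal(both, sqrt(2) * exp(1 / 4), tolerance = 1e-8)
  imposs <- exp(dnorm(0, log = TRUE) - (l1 - 0.5))
  expect_equal(ebf_z_onesided(0, sign_restricted = TRUE)$ebf01, imposs,
               tolerance = 1e-8)
  expect_equal(imposs, sqrt(2) * exp(1 / 2), tolerance = 1e-8)
})

test_that("the interval engine agrees with every closed form on a z grid", {
  for (z in seq(-3, 3, by = 0.5)) {
    expect_equal(ebf_z(z = z)$log_ebf01, ebf_z_twosided(z)$log_ebf01,
                 tolerance = 1e-6)
    expect_equal(ebf_z(z = z, h1 = h_above(0))$log_ebf01,
                 ebf_z_onesided(z)$log_ebf01, tolerance = 1e-6)
    expect_equal(ebf_z(z = z, h0 = h_below(0), h1 = h_above(0))$log_ebf01,
                 ebf_z_directional(z)$log_ebf01, tolerance = 1e-6)
  }
})

test_that("interval marginal likelihoods match direct quadrature", {
  for (case in list(c(0, 1, -1, 1), c(1.7, 0.4, 0, 2), c(-2, 3, -4, -1))) {
    h <- h_interval(case[3], case[4])
    expect_equal(normal_lml(case[1], case[2], h),
                 oracle_normal_lml(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-8)
  }
  ## [-1, 1] vs full at x = 0: assembled EBF against the quadrature oracle
  e <- ebf_z(z = 0, h0 = h_interval(-1, 1), h1 = h_full())
  by_hand <- exp((oracle_normal_lml(0, 1, -1, 1) - 0) -
                 (oracle_normal_lml(0, 1, -Inf, Inf) - 0.5))
  expect_equal(e$ebf01, by_hand, tolerance = 1e-8)
})

test_that("EBF reciprocity holds exactly when hypotheses are swapped", {
  for (z in c(-2.2, 0, 0.7, 4)) {
    a <- ebf_z(z = z, h0 = h_point(0), h1 = h_above(0))
    b <- ebf_z(z = z, h0 = h_above(0), h1 = h_point(0))
    expect_equal(a$log_ebf01, -b$log_ebf01)
    expect_equal(ebf_z_directional(z)$log_ebf01,
                 -ebf_z_directional(-z)$log_ebf01)
  }
})

test_that("the two-sided EBF crosses 1 exactly at z^2 = 1 + log 2", {
  zstar <- sqrt(1 + log(2))
  expect_equal(ebf_z_twosided(zstar)$ebf01, 1, tolerance = 1e-12)
  expect_identical(ebf_z_twosided(zstar + 1e-9)$favoured, "H1")
  expect_identical(ebf_z_twosided(zstar - 1e-9)$favoured, "H0")
  ## the knife-edge two-sided P-value
  expect_lt(abs(2 * pnorm(-zstar) - 0.193), 5e-4)
})

test_that("the one-sided form approaches the truncated two-sided form for
           large z", {
  for (z in c(6, 10, 20)) {
    ratio <- ebf_z_onesided(z)$log_ebf01 -
      (0.5 * log(2) + 1 / 4 - z^2 / 2)
    expect_lt(abs(ratio), 1e-6)
  }
})

test_that("extreme z degrades gracefully through the log scale", {
  e <- ebf_z_twosided(50)
  expect_identical(e$ebf01, 0)
  expect_equal(e$log_ebf01, 0.5 * log(2) - (2500 - 1) / 2)
  expect_identical(e$favoured, "H1")
})

test_that("deviance criterion is the penalised maximised deviance", {
  expect_equal(deviance_criterion(0, 1), 1.6931, tolerance = 1e-4)
  expect_identical(deviance_criterion(-3.2, 0), 6.4)
  ## identity with -2 * (log M_H - d/2) for the unrestricted hypothesis:
  ## max log-likelihood of N(x, sigma^2) at mu = x is -log(sqrt(2 pi) sigma)
  x <- 1.3; sigma <- 2.1
  ml <- dnorm(x, x, sigma, log = TRUE)
  expect_equal(deviance_criterion(ml, 1),
               -2 * (normal_lml(x, sigma, h_full()) - 0.5), tolerance = 1e-12)
})

test_that("comparator bounds evaluate their quoted formulas", {
  cmp <- comparator_bfs(z = 0, p = 0.05, n = 100)
  expect_equal(cmp$min_bf, 1)
  expect_equal(cmp$brc, exp(-0.5), tolerance = 1e-12)
  expect_equal(cmp$sellke, -exp(1) * 0.05 * log(0.05))
  expect_equal(cmp$held_ott, -exp(1) * 0.95 * log(0.95))
  ## 1/2.45 and 1/7.55 at p = 0.05
  expect_equal(1 / cmp$sellke, 2.45, tolerance = 0.005)
  expect_equal(1 / cmp$held_ott, 7.55, tolerance = 0.005)
  expect_equal(comparator_bfs(p = exp(-1))$sellke, 1, tolerance = 1e-12)
  expect_error(comparator_bfs(p = 0.5), "valid")
  ## unit-information BF at z = 0 is sqrt(n + 1)
  expect_equal(comparator_bfs(z = 0, n = 8)$unit_information, 3)
})

test_that("under a true null the EBF favours H0 with the stated frequency
           and expected log", {
  set.seed(1)
  z <- rnorm(1e5)
  le <- 0.5 * log(2) - (z^2 - 1) / 2
  p_fav <- mean(le > 0)
  p_theory <- 1 - 2 * pnorm(-sqrt(1 + log(2)))
  se <- sqrt(p_theory * (1 - p_theory) / 1e5)
  expect_lt(abs(p_fav - p_theory), 3 * se)
  expect_equal(p_theory, 0.807, tolerance = 5e-4)
  m_theory <- 0.5 * log(2)
  expect_lt(abs(mean(le) - m_theory), 3 * sd(le) / sqrt(1e5))
})
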