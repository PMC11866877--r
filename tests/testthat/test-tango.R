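test_that("RMLE boundary estimates satisfy the score quadratic", {
  # p101 must solve 2 p^2 + a1 p + ... i.e. be a root of the defining
  # quadratic 4 p^2 + 2 a1 p + 4 b1 / ... ; verify directly from a1, b1
  set.seed(21)
  for (i in 1:50) {
    tab <- random_table(60, missing = FALSE)
    theta_cc <- (tab$n10 - tab$n01) / tab$npp
    p01_hat <- tab$n01 / tab$npp
    delta <- runif(1, 0, 0.3)
    r <- rmle_boundary(p01_hat, theta_cc, delta)
    # p101 is the admissible root of 2 x^2 + a1 x + b1 = 0
    expect_equal(2 * r$p101^2 + r$a1 * r$p101 + r$b1, 0, tolerance = 1e-10)
    expect_gte(r$p101, 0)
    expect_lte(r$p101, 1)
    expect_equal(r$p110, r$p101 - delta)
  }
})

test_that("score statistic at delta = 0 reproduces McNemar's chi-square", {
  set.seed(22)
  for (i in 1:25) {
    tab <- random_table(80, missing = FALSE, min_discordant = 2)
    t0 <- nam_test(tab, delta = 0)
    mc <- mcnemar.test(matrix(c(tab$n00, tab$n01, tab$n10, tab$n11), 2, 2,
                              byrow = TRUE),
                       correct = FALSE)
    expect_equal(t0$statistic^2, unname(mc$statistic), tolerance = 1e-12)
  }
})

test_that("test and confidence interval are dual decision rules", {
  set.seed(23)
  for (i in 1:200) {
    tab <- random_table(sample(20:150, 1), missing = FALSE)
    delta <- runif(1, 0.01, 0.3)
    alpha <- runif(1, 0.01, 0.2)
    te <- nam_test(tab, delta = delta, alpha = alpha)
    ci <- tango_ci(tab, alpha = alpha)
    expect_identical(te$reject, noninferior(ci, delta))
    expect_identical(te$reject, unname(ci$lower > -delta))
  }
})

test_that("Tango endpoints solve the score equation (dense-grid oracle)", {
  set.seed(24)
  for (i in 1:30) {
    tab <- random_table(sample(20:200, 1), missing = FALSE)
    alpha <- 0.05
    z <- qnorm(1 - alpha)
    ci <- tango_ci(tab, alpha = alpha)
    theta_cc <- (tab$n10 - tab$n01) / tab$npp
    # at each endpoint the standardized score equals the normal quantile
    s_lo <- nipaired:::score_std(ci$lower, theta_cc, tab$n01 / tab$npp,
                                 tab$npp)
    s_hi <- nipaired:::score_std(ci$upper, theta_cc, tab$n01 / tab$npp,
                                 tab$npp)
    expect_equal(s_lo, z, tolerance = 1e-6)
    expect_equal(s_hi, -z, tolerance = 1e-6)
    # dense-grid cross-check: the score is above z strictly inside the
    # lower endpoint and below z beyond it
    grid <- seq(-0.999, 0.999, length.out = 2001)
    s <- nipaired:::score_std(grid, theta_cc, tab$n01 / tab$npp, tab$npp)
    expect_true(all(grid[s > z] < ci$lower + 1e-3))
    expect_true(all(grid[s < -z] > ci$upper - 1e-3))
  }
})

test_that("interval widens as alpha decreases and is scale-consistent", {
  tab <- paired_table(n00 = 40, n01 = 10, n10 = 20, n11 = 30)
  ci10 <- tango_ci(tab, alpha = 0.10)
  ci05 <- tango_ci(tab, alpha = 0.05)
  ci01 <- tango_ci(tab, alpha = 0.01)
  expect_lt(ci05$lower, ci10$lower)
  expect_gt(ci05$upper, ci10$upper)
  expect_lt(ci01$lower, ci05$lower)
  expect_gt(ci01$upper, ci05$upper)
  for (ci in list(ci10, ci05, ci01)) {
    expect_lte(ci$lower, 0.1)
    expect_gte(ci$upper, 0.1)
  }
})

test_that("the interval depends only on (n01, n10, npp)", {
  base <- tango_ci(paired_table(n00 = 40, n01 = 10, n10 = 20, n11 = 30))
  moved <- tango_ci(paired_table(n00 = 5, n01 = 10, n10 = 20, n11 = 65))
  expect_equal(base$lower, moved$lower, tolerance = 1e-12)
  expect_equal(base$upper, moved$upper, tolerance = 1e-12)
  # incomplete pairs are ignored by the complete-case method
  with_miss <- tango_ci(paired_table(n00 = 40, n01 = 10, n10 = 20, n11 = 30,
                                     n0x = 7, nx1 = 9))
  expect_equal(base$lower, with_miss$lower, tolerance = 1e-12)
})

test_that("degenerate tables still yield valid intervals", {
  # no discordant pairs: interval is symmetric around 0 and nondegenerate
  conc <- tango_ci(paired_table(n00 = 50, n11 = 50))
  expect_valid_ci(conc)
  expect_lt(conc$lower, 0)
  expect_gt(conc$upper, 0)
  expect_equal(conc$lower, -conc$upper, tolerance = 1e-9)
  # all pairs in one discordant cell
  one <- tango_ci(paired_table(n10 = 10))
  expect_valid_ci(one)
  expect_equal(one$upper, 1)
  expect_lt(one$lower, 1)
  expect_error(tango_ci(paired_table(nx1 = 5)), "no completely observed")
})

test_that("asymptotic power and sample size reproduce the planned design", {
  n <- nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05)
  expect_identical(n, 507L)
  # with 20% of patients losing one observation the complete-case method
  # needs ceiling(507 / 0.8)
  n_cc <- nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05,
                         p_missing = c(0.1, 0.1))
  expect_identical(n_cc, 634L)
  expect_gte(nam_power(507, 0.8, 0.8, 0.375, 0.05), 0.80)
  expect_lt(nam_power(506, 0.8, 0.8, 0.375, 0.05), 0.80)
  # power is increasing in n and in delta
  p <- nam_power(c(100, 200, 400, 800), 0.8, 0.8, 0.375, 0.05)
  expect_true(all(diff(p) > 0))
  expect_gt(nam_power(300, 0.8, 0.8, 0.375, 0.10),
            nam_power(300, 0.8, 0.8, 0.375, 0.05))
  expect_error(nam_power(100, 0.7, 0.8, 0.3, delta = 0.05), "infeasible")
})

test_that("rho = 0.375 with base 0.8 marginals gives concordant mass 0.8", {
  d <- joint_from_marginals(0.8, 0.8, 0.375)
  expect_equal(d$p11 + d$p00, 0.8, tolerance = 1e-12)
})
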