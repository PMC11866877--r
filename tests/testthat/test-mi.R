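test_that("closed-form imputation models match glm on the complete pairs", {
  set.seed(31)
  for (i in 1:10) {
    tab <- random_table(80, min_discordant = 2)
    if (tab$n00 == 0 || tab$n01 == 0 || tab$n10 == 0 || tab$n11 == 0) next
    models <- fit_imputation_models(tab)
    cc <- expand_pairs(paired_table(n00 = tab$n00, n01 = tab$n01,
                                    n10 = tab$n10, n11 = tab$n11))
    g1 <- glm(y1 ~ y2, family = binomial, data = cc)
    g2 <- glm(y2 ~ y1, family = binomial, data = cc)
    expect_equal(unname(models$y1_given_y2$beta), unname(coef(g1)),
                 tolerance = 1e-8)
    expect_equal(unname(models$y2_given_y1$beta), unname(coef(g2)),
                 tolerance = 1e-8)
    # vcov(glm) carries IRLS convergence error in the 6th digit
    expect_equal(unname(models$y1_given_y2$cov), unname(vcov(g1)),
                 tolerance = 1e-4)
    expect_equal(unname(models$y2_given_y1$cov), unname(vcov(g2)),
                 tolerance = 1e-4)
  }
})

test_that("a zero complete cell triggers the continuity correction", {
  tab <- paired_table(n00 = 20, n01 = 0, n10 = 5, n11 = 15, nx1 = 3)
  expect_warning(models <- fit_imputation_models(tab), "zero complete-pair")
  expect_true(all(is.finite(unlist(models$y1_given_y2[c("beta", "cov")]))))
  expect_error(fit_imputation_models(paired_table(nx1 = 5, n1x = 3)),
               "no completely observed pairs")
})

test_that("impute_table completes the table and preserves the total", {
  set.seed(32)
  for (i in 1:20) {
    tab <- random_table(60)
    imp <- suppressWarnings(impute_table(tab))
    expect_equal(imp$npx + imp$nxp, 0)
    expect_equal(imp$n, tab$n)
    expect_equal(imp$npp, tab$n)
    # observed complete cells can only grow
    expect_gte(imp$n00 + imp$n01 + imp$n10 + imp$n11,
               tab$n00 + tab$n01 + tab$n10 + tab$n11)
  }
  # nothing to impute: table returned unchanged
  cc <- paired_table(n00 = 10, n01 = 5, n10 = 7, n11 = 8)
  expect_identical(unclass(impute_table(cc)), unclass(cc))
})

test_that("MI interval collapses to the single Wald interval when complete", {
  tab <- paired_table(n00 = 40, n01 = 10, n10 = 20, n11 = 30)
  ci <- mi_ci(tab, m = 10, alpha = 0.05)
  th <- 0.1
  se <- sqrt(((10 + 20) / 100 - th^2) / 100)
  z <- qnorm(0.95)
  expect_equal(ci$lower, th - z * se, tolerance = 1e-12)
  expect_equal(ci$upper, th + z * se, tolerance = 1e-12)
  expect_equal(ci$between_var, 0)
})

test_that("Rubin pooling inflates the variance and reports its parts", {
  set.seed(33)
  tab <- paired_table(n00 = 30, n01 = 10, n10 = 15, n11 = 25,
                      n0x = 8, n1x = 7, nx0 = 6, nx1 = 9)
  ci <- mi_ci(tab, m = 25)
  expect_valid_ci(ci)
  expect_gt(ci$between_var, 0)
  expect_equal(ci$total_var,
               ci$within_var + (1 + 1 / 25) * ci$between_var,
               tolerance = 1e-12)
  # the t reference can only widen the interval
  set.seed(33)
  ci_t <- mi_ci(tab, m = 25, use_t = TRUE)
  expect_lte(ci_t$lower, ci$lower)
  expect_gte(ci_t$upper, ci$upper)
  expect_error(mi_ci(tab, m = 1), "m >= 2")
})

test_that("fast core and object path agree in distribution", {
  # both implementations draw coefficients from the same asymptotic normal
  # and impute binomially; compare the Monte-Carlo mean and SD of the pooled
  # estimate over independent runs
  tab <- paired_table(n00 = 30, n01 = 10, n10 = 15, n11 = 25,
                      n0x = 10, n1x = 10, nx0 = 10, nx1 = 10)
  nrep <- 400
  pool_obj <- function() {
    models <- fit_imputation_models(tab)
    mean(vapply(1:5, function(j) {
      theta_complete(impute_table(tab, models))$estimate
    }, numeric(1)))
  }
  set.seed(34)
  a <- replicate(nrep, pool_obj())
  set.seed(35)
  b <- replicate(nrep, nipaired:::mi_ci_core(tab, 5, 0.05)[3])
  se <- sqrt(var(a) / nrep + var(b) / nrep)
  expect_lt(abs(mean(a) - mean(b)), 4 * se)
  expect_lt(abs(sd(a) - sd(b)), 0.25 * sd(a))
})

test_that("MI point estimate is centered near the MAR-consistent value", {
  # strongly unbalanced missingness: the complete-case estimator is still
  # unbiased under this outcome-independent mechanism, and MI must agree in
  # expectation with the generating risk difference
  set.seed(36)
  d <- joint_from_marginals(0.75, 0.8, 0.4)
  est <- replicate(300, {
    tab <- nipaired:::r_paired_counts(400, d, 0.05, 0.3)
    nipaired:::mi_ci_core(tab, 10, 0.05)[3]
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - (-0.05)), 4 * se)
})
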