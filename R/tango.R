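#' Restricted MLE of the discordant-pair probabilities at a null boundary
#'
#' For the score test of `H0: theta <= -delta` the variance of the
#' complete-case risk-difference estimator is evaluated at restricted maximum
#' likelihood estimates of the nuisance probabilities, computed at the
#' boundary `theta = -delta`. Writing `p101` for the restricted estimate of
#' the (0,1)-discordant probability and `p110 = p101 - delta` for that of
#' the (1,0) cell (so that their difference sits on the boundary), the
#' closed form is the admissible root of a quadratic:
#' `p101 = (-a1 + sqrt(a1^2 - 8 b1)) / 4` with
#' `a1 = -theta_cc (1 - delta) - 2 (p01_hat + delta)` and
#' `b1 = delta (1 + delta) p01_hat`.
#'
#' @param p01_hat Observed proportion of (0,1)-discordant pairs among
#'   complete pairs.
#' @param theta_cc Complete-case risk-difference estimate.
#' @param delta Boundary value (the margin, or `-theta0` when inverting the
#'   score for a confidence limit), in `(-1, 1)`.
#' @return A list with elements `a1`, `b1`, `p101`, `p110`.
#' @export
rmle_boundary <- function(p01_hat, theta_cc, delta) {
  stopifnot(p01_hat >= 0, p01_hat <= 1, delta > -1, delta < 1)
  a1 <- -theta_cc * (1 - delta) - 2 * (p01_hat + delta)
  b1 <- delta * (1 + delta) * p01_hat
  disc <- a1^2 - 8 * b1
  if (disc < 0) {
    if (disc < -1e-12) stop("invalid parameters: negative discriminant in RMLE")
    disc <- 0
  }
  p101 <- (-a1 + sqrt(disc)) / 4
  if (p101 < 0 || p101 > 1) {
    if (p101 < -1e-12 || p101 > 1 + 1e-12) {
      stop("invalid parameters: restricted estimate outside [0, 1]")
    }
    p101 <- clip01(p101)
  }
  list(a1 = a1, b1 = b1, p101 = p101, p110 = p101 - delta)
}

# Restricted variance (times n = 1) of theta_hat_cc at boundary theta0,
# vectorized over theta0. Returns (p101 + p110 - theta0^2) evaluated with the
# RMLE at delta_eff = -theta0; nonpositive or invalid values come back as NA.
rmle_var1 <- function(theta0, theta_cc, p01_hat) {
  de <- -theta0
  a1 <- -theta_cc * (1 - de) - 2 * (p01_hat + de)
  b1 <- de * (1 + de) * p01_hat
  disc <- pmax(a1^2 - 8 * b1, 0)
  p101 <- (-a1 + sqrt(disc)) / 4
  v <- 2 * p101 + theta0 - theta0^2
  ifelse(is.finite(v) & v > 0, v, NA_real_)
}

# Standardized score (theta_cc - theta0) / sigma_tilde(theta0), vectorized.
# Where the restricted variance degenerates the score is capped at +/- 1e12
# with the sign of (theta_cc - theta0), which preserves root bracketing.
score_std <- function(theta0, theta_cc, p01_hat, n) {
  v <- rmle_var1(theta0, theta_cc, p01_hat) / n
  s <- (theta_cc - theta0) / sqrt(v)
  bad <- !is.finite(s)
  s[bad] <- sign(theta_cc - theta0[bad]) * 1e12
  s
}

#' Score test of non-inferiority for the risk difference (complete pairs)
#'
#' Tests `H0: theta <= -delta` against `H1: theta > -delta` using the score
#' statistic `(theta_cc + delta) / sigma_tilde` with the restricted-MLE null
#' variance `sigma_tilde^2 = (p101 + p110 - delta^2) / npp` from
#' [rmle_boundary]. Only completely observed pairs contribute. At
#' `delta = 0` the squared statistic equals McNemar's chi-square.
#'
#' @param table A [paired_table] (or data frame of pairs).
#' @param delta Non-inferiority margin, `>= 0`.
#' @param alpha One-sided significance level in `(0, 0.5)`.
#' @return An object of class `nam_test` with elements `statistic`,
#'   `p.value`, `reject`, `alpha`, `delta`, `sigma_tilde_sq`, `n_used`.
#' @examples
#' tab <- paired_table(n00 = 70, n01 = 5, n10 = 15, n11 = 10)
#' nam_test(tab, delta = 0.05)
#' @export
nam_test <- function(table, delta, alpha = 0.05) {
  table <- as_paired_table(table)
  stopifnot(delta >= 0, alpha > 0, alpha < 0.5)
  if (table$npp == 0) stop("no completely observed pairs")
  theta_cc <- (table$n10 - table$n01) / table$npp
  p01_hat <- table$n01 / table$npp
  r <- rmle_boundary(p01_hat, theta_cc, delta)
  s2 <- (r$p101 + r$p110 - delta^2) / table$npp
  if (!is.finite(s2) || s2 <= 0) {
    stop("no information: restricted null variance is not positive")
  }
  stat <- (theta_cc + delta) / sqrt(s2)
  structure(list(statistic = stat,
                 p.value = stats::pnorm(stat, lower.tail = FALSE),
                 reject = stat > z_upper(alpha),
                 alpha = alpha, delta = delta,
                 sigma_tilde_sq = s2, theta_cc = theta_cc,
                 n_used = table$npp),
            class = "nam_test")
}

#' @export
print.nam_test <- function(x, ...) {
  cat("Score test of non-inferiority, H0: theta <= ", -x$delta, "\n", sep = "")
  cat(sprintf("  theta_cc = %.6f, statistic = %.4f, one-sided p = %.5f\n",
              x$theta_cc, x$statistic, x$p.value))
  cat(sprintf("  %s at one-sided alpha = %g (complete pairs: %d)\n",
              if (x$reject) "non-inferiority concluded" else "not rejected",
              x$alpha, x$n_used))
  invisible(x)
}

# Fast internal score CI from the three sufficient counts; returns c(lo, hi).
tango_ci_core <- function(n01, n10, npp, alpha, tol = 1e-10) {
  theta_cc <- (n10 - n01) / npp
  p01_hat <- n01 / npp
  z <- z_upper(alpha)
  eps <- 1e-9
  # scalar standardized score minus target, monotone decreasing in t0
  f <- function(t0, target) {
    a1 <- -theta_cc * (1 + t0) - 2 * (p01_hat - t0)
    disc <- a1 * a1 + 8 * t0 * (1 - t0) * p01_hat
    if (disc < 0) disc <- 0
    v <- (0.5 * (-a1 + sqrt(disc)) + t0 - t0 * t0) / npp
    if (!is.finite(v) || v <= 0) {
      # degenerate variance: the score diverges with the sign of
      # theta_cc - t0, and tends to 0 when evaluated at theta_cc itself
      return(sign(theta_cc - t0) * 1e12 - target)
    }
    (theta_cc - t0) / sqrt(v) - target
  }
  lo <- if (theta_cc <= -1 + eps) -1 else {
    stats::uniroot(f, lower = -1 + eps, upper = theta_cc, target = z,
                   tol = tol)$root
  }
  hi <- if (theta_cc >= 1 - eps) 1 else {
    stats::uniroot(f, lower = theta_cc, upper = 1 - eps, target = -z,
                   tol = tol)$root
  }
  c(lo, hi)
}

#' Score confidence interval for the paired risk difference (complete pairs)
#'
#' Inverts the standardized score of [nam_test] over candidate values
#' `theta0`: the limits are the solutions of
#' `(theta_cc - theta0) / sigma_tilde(theta0) = +/- z_alpha`, where
#' `sigma_tilde(theta0)` is the restricted-MLE standard deviation at the
#' boundary `theta = theta0` (obtained from [rmle_boundary] with
#' `delta = -theta0`). The standardized score decreases monotonically in
#' `theta0`, and each limit is found by bracketed root search (Brent) on
#' `(-1, 1)` to absolute tolerance `1e-10`. The interval at level
#' `100*(1-2*alpha)%` is dual to the level-`alpha` test: the test rejects at
#' margin `delta` exactly when the lower limit exceeds `-delta`.
#'
#' @param table A [paired_table] (or data frame of pairs).
#' @param alpha One-sided level; the interval is two-sided `1 - 2*alpha`.
#' @return A `paired_ci` with method tag `"tango"`.
#' @examples
#' tango_ci(paired_table(n00 = 40, n01 = 10, n10 = 20, n11 = 30))
#' @export
tango_ci <- function(table, alpha = 0.05) {
  table <- as_paired_table(table)
  stopifnot(alpha > 0, alpha < 0.5)
  if (table$npp == 0) stop("no completely observed pairs")
  lim <- tango_ci_core(table$n01, table$n10, table$npp, alpha)
  new_paired_ci(lim[1], lim[2],
                estimate = (table$n10 - table$n01) / table$npp,
                alpha = alpha, method = "tango", n_used = table$npp)
}

#' Asymptotic power of the score test for a planned paired design
#'
#' Under true marginal success probabilities `p1`, `p2` and within-pair
#' (phi) correlation `rho`, the complete-case estimator has asymptotic
#' variance `sigma_a^2 / n` with `sigma_a^2 = p10 + p01 - theta^2`, and the
#' restricted null standard deviation converges to the RMLE evaluated at the
#' true nuisance values. The power of the one-sided level-`alpha` score test
#' at margin `delta` is
#' `Phi(((theta + delta) sqrt(n) - z_alpha sigma_0) / sigma_a)`.
#'
#' @param n Number of pairs (complete pairs).
#' @param p1,p2 Marginal success probabilities under interventions 1 and 2.
#' @param rho Within-pair correlation of the two binary outcomes.
#' @param delta Non-inferiority margin.
#' @param alpha One-sided significance level.
#' @return Power as a probability, vectorized over `n`.
#' @export
nam_power <- function(n, p1, p2, rho, delta, alpha = 0.05) {
  d <- joint_from_marginals(p1, p2, rho)
  theta <- p1 - p2
  if (theta + delta <= 0) {
    stop("infeasible design: true risk difference does not exceed -delta")
  }
  sigma_a2 <- d$p10 + d$p01 - theta^2
  r <- rmle_boundary(d$p01, theta, delta)
  sigma0_2 <- r$p101 + r$p110 - delta^2
  stats::pnorm(((theta + delta) * sqrt(n) - z_upper(alpha) * sqrt(sigma0_2)) /
                 sqrt(sigma_a2))
}

#' Sample size for the paired non-inferiority score test
#'
#' Smallest number of pairs for which the asymptotic power of the score test
#' ([nam_power]) reaches `power`. If single observations are expected to be
#' missing with total probability `sum(p_missing)`, the complete-case method
#' discards those patients entirely and the returned total is inflated to
#' `ceiling(n / (1 - sum(p_missing)))`.
#'
#' @inheritParams nam_power
#' @param power Target power in `(alpha, 1)`.
#' @param p_missing Length-2 probabilities that the first or second outcome
#'   of a patient is missing (at most one outcome per patient can be
#'   missing, so the sum must be `< 1`).
#' @return Required number of patients (integer).
#' @examples
#' nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05)          # 507
#' nam_samplesize(0.8, 0.8, rho = 0.375, delta = 0.05,
#'                p_missing = c(0.1, 0.1))                      # 634
#' @export
nam_samplesize <- function(p1, p2, rho, delta, alpha = 0.05, power = 0.80,
                           p_missing = c(0, 0)) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            length(p_missing) == 2, all(p_missing >= 0),
            sum(p_missing) < 1)
  d <- joint_from_marginals(p1, p2, rho)
  theta <- p1 - p2
  if (theta + delta <= 0) {
    stop("infeasible design: true risk difference does not exceed -delta")
  }
  sigma_a2 <- d$p10 + d$p01 - theta^2
  r <- rmle_boundary(d$p01, theta, delta)
  sigma0_2 <- r$p101 + r$p110 - delta^2
  zb <- stats::qnorm(power)
  num <- z_upper(alpha) * sqrt(sigma0_2) + zb * sqrt(sigma_a2)
  n_cc <- if (num <= 0) 1L else as.integer(ceiling((num / (theta + delta))^2))
  n_cc <- max(n_cc, 1L)
  # guard against ceiling landing a hair below target through rounding
  while (nam_power(n_cc, p1, p2, rho, delta, alpha) < power) {
    n_cc <- n_cc + 1L
  }
  pm <- sum(p_missing)
  if (pm > 0) as.integer(ceiling(n_cc / (1 - pm))) else n_cc
}
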