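#' Wilson score interval for a binomial proportion
#'
#' Standard Wilson interval at two-sided level `1 - alpha` using the normal
#' quantile `z = qnorm(1 - alpha/2)`: center `(x + z^2/2) / (n + z^2)` and
#' half-width `z * sqrt(x (n - x) / n + z^2 / 4) / (n + z^2)`.
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param alpha Two-sided error level (e.g. 0.10 for a 90% interval).
#' @return A list with `estimate` (the plain proportion), `lower`, `upper`
#'   and `alpha`.
#' @examples
#' wilson_ci(8, 10, alpha = 0.10)
#' @export
wilson_ci <- function(successes, trials, alpha = 0.10) {
  stopifnot(trials > 0, successes >= 0, successes <= trials,
            alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  z2 <- z^2
  center <- (successes + z2 / 2) / (trials + z2)
  half <- z * sqrt(successes * (trials - successes) / trials + z2 / 4) /
    (trials + z2)
  list(estimate = successes / trials,
       lower = max(0, center - half),
       upper = min(1, center + half),
       alpha = alpha)
}

#' Within-patient (phi) correlation from complete pairs
#'
#' Pearson correlation of the two binary outcomes over the completely
#' observed pairs,
#' `(n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)`, clipped to `[-1, 1]`.
#' Returns 0 with a warning when a margin is degenerate (an all-0 or all-1
#' outcome), where the correlation is undefined.
#'
#' @param table A [paired_table].
#' @return The phi coefficient.
#' @export
phi_correlation <- function(table) {
  table <- as_paired_table(table)
  if (table$npp <= 1) stop("need more than one complete pair")
  # double arithmetic: the margin product overflows integer range for
  # a few hundred pairs
  n1p <- as.numeric(table$n10 + table$n11); n0p <- as.numeric(table$n00 + table$n01)
  np1 <- as.numeric(table$n01 + table$n11); np0 <- as.numeric(table$n00 + table$n10)
  den <- n1p * n0p * np1 * np0
  if (den == 0) {
    warning("degenerate margin in complete pairs; phi set to 0")
    return(0)
  }
  num <- as.numeric(table$n11) * table$n00 - as.numeric(table$n10) * table$n01
  max(-1, min(1, num / sqrt(den)))
}

#' Hybrid Wald-type confidence interval combining complete and partial pairs
#'
#' The approach of Tang and colleagues: estimate the two marginal success
#' probabilities from all pairs in which the respective outcome is observed,
#' `p1. = (n1. + n1x) / (npp + npx)` and `p.1 = (n.1 + nx1) / (npp + nxp)`
#' (valid under MAR), back-solve variance estimates from the half-widths of
#' Wilson score intervals for each margin, and combine them with an estimate
#' `rho` of the within-patient correlation:
#' \deqn{L = \hat\theta - \sqrt{(\hat p_{1.}-\hat l_{1.})^2 +
#'   (\hat u_{.1}-\hat p_{.1})^2 -
#'   2\hat\rho(\hat p_{1.}-\hat l_{1.})(\hat u_{.1}-\hat p_{.1})}}
#' and symmetrically for `U` with the opposite Wilson half-widths. `rho` is
#' the complete-pair phi coefficient ([phi_correlation]). The Wilson bounds
#' are computed at two-sided level `1 - 2*alpha`, the same quantile that the
#' variance back-solve divides out. A negative radicand (possible with
#' extreme `rho`) is clipped to zero with a warning.
#'
#' @param table A [paired_table] (or data frame of pairs).
#' @param alpha One-sided level; the interval is two-sided `1 - 2*alpha`.
#' @return A `paired_ci` with method tag `"hybrid"` and extra element `rho`.
#' @export
hybrid_ci <- function(table, alpha = 0.05) {
  table <- as_paired_table(table)
  stopifnot(alpha > 0, alpha < 0.5)
  t1 <- table$npp + table$npx          # pairs with y1 observed
  t2 <- table$npp + table$nxp          # pairs with y2 observed
  if (t1 == 0 || t2 == 0) stop("no observed outcomes in one arm")
  s1 <- table$n10 + table$n11 + table$n1x
  s2 <- table$n01 + table$n11 + table$nx1
  w1 <- wilson_ci(s1, t1, alpha = 2 * alpha)
  w2 <- wilson_ci(s2, t2, alpha = 2 * alpha)
  p1 <- w1$estimate; p2 <- w2$estimate
  rho <- phi_correlation(table)
  rad_l <- (p1 - w1$lower)^2 + (w2$upper - p2)^2 -
    2 * rho * (p1 - w1$lower) * (w2$upper - p2)
  rad_u <- (w1$upper - p1)^2 + (p2 - w2$lower)^2 -
    2 * rho * (w1$upper - p1) * (p2 - w2$lower)
  if (rad_l < 0 || rad_u < 0) {
    warning("negative radicand in hybrid interval; clipped to zero")
  }
  theta <- p1 - p2
  new_paired_ci(theta - sqrt(max(rad_l, 0)), theta + sqrt(max(rad_u, 0)),
                estimate = theta, alpha = alpha, method = "hybrid",
                n_used = table$n, extra = list(rho = rho))
}
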