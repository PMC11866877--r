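#' Long-format design for the marginal logistic model
#'
#' One row per observed outcome: cluster (patient) id, the intervention
#' indicator `I(k = 2)` and the binary outcome. Complete pairs become
#' clusters of size 2; pairs with one missing outcome become singleton
#' clusters, which still contribute to the marginal mean estimation.
#'
#' @param y1,y2 Outcome vectors (0, 1 or `NA`) under interventions 1 and 2.
#' @param id Optional cluster identifiers (defaults to the record index).
#' @return A data frame of class `gee_design` with columns `cluster`, `k2`
#'   (0/1 indicator of intervention 2) and `y`.
#' @export
gee_design <- function(y1, y2, id = NULL) {
  if (length(y1) != length(y2)) stop("y1 and y2 must have the same length")
  if (is.null(id)) id <- seq_along(y1)
  if (any(is.na(y1) & is.na(y2))) {
    stop("pair(s) with both outcomes missing are not allowed")
  }
  keep1 <- !is.na(y1); keep2 <- !is.na(y2)
  out <- data.frame(
    cluster = c(id[keep1], id[keep2]),
    k2 = c(rep(0L, sum(keep1)), rep(1L, sum(keep2))),
    y = c(y1[keep1], y2[keep2]))
  out <- out[order(out$cluster, out$k2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gee_design", "data.frame")
  out
}

# Convert a gee_design back to the eight sufficient counts.
design_to_table <- function(design) {
  sp <- split(design[c("k2", "y")], design$cluster)
  y1 <- vapply(sp, function(d) {
    i <- which(d$k2 == 0L); if (length(i)) d$y[i] else NA_real_
  }, numeric(1))
  y2 <- vapply(sp, function(d) {
    i <- which(d$k2 == 1L); if (length(i)) d$y[i] else NA_real_
  }, numeric(1))
  tabulate_pairs(y1, y2)
}

# Core exchangeable-working-correlation GEE fit for the two-point marginal
# logistic model, written in scalar arithmetic on the eight cell counts.
# Fisher scoring on beta alternates with moment re-estimation of the
# exchangeable correlation (complete clusters only, denominator npp - p) and
# optionally of the dispersion phi (all Pearson residuals, denominator
# N_obs - p). Returns estimates, model-based and sandwich covariances.
gee_fit_core <- function(tab, phi_fixed = TRUE, tol = 1e-10, maxit = 100L) {
  n00 <- tab$n00; n01 <- tab$n01; n10 <- tab$n10; n11 <- tab$n11
  n0x <- tab$n0x; n1x <- tab$n1x; nx0 <- tab$nx0; nx1 <- tab$nx1
  npp <- tab$npp
  N1 <- npp + tab$npx; N2 <- npp + tab$nxp
  S1 <- n10 + n11 + n1x; S2 <- n01 + n11 + nx1
  if (tab$n < 2) stop("need at least two clusters")
  if (N1 == 0 || N2 == 0 || S1 == 0 || S1 == N1 || S2 == 0 || S2 == N2) {
    stop("separation: an intervention arm has a constant (or no) outcome")
  }
  b0 <- stats::qlogis(S1 / N1)
  b1 <- stats::qlogis(S2 / N2) - b0
  n1p <- n10 + n11; n0p <- n00 + n01
  np1 <- n01 + n11; np0 <- n00 + n10
  n_obs <- N1 + N2
  phi <- 1
  alpha_x <- 0
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(maxit)) {
    mu1 <- stats::plogis(b0); mu2 <- stats::plogis(b0 + b1)
    v1 <- mu1 * (1 - mu1); v2 <- mu2 * (1 - mu2)
    # residual sums over complete clusters
    sr1 <- n1p * (1 - mu1) - n0p * mu1
    sr2 <- np1 * (1 - mu2) - np0 * mu2
    sr11 <- n1p * (1 - mu1)^2 + n0p * mu1^2
    sr22 <- np1 * (1 - mu2)^2 + np0 * mu2^2
    sr12 <- n00 * mu1 * mu2 - n01 * mu1 * (1 - mu2) -
      n10 * (1 - mu1) * mu2 + n11 * (1 - mu1) * (1 - mu2)
    # singleton residual sums
    sr1s <- n1x * (1 - mu1) - n0x * mu1
    sr11s <- n1x * (1 - mu1)^2 + n0x * mu1^2
    sr2s <- nx1 * (1 - mu2) - nx0 * mu2
    sr22s <- nx1 * (1 - mu2)^2 + nx0 * mu2^2
    if (!phi_fixed) {
      phi <- ((sr11 + sr11s) / v1 + (sr22 + sr22s) / v2) / max(n_obs - 2, 1)
    }
    alpha_x <- if (npp > 0) {
      sr12 / (sqrt(v1 * v2) * max(npp - 2, 1) * phi)
    } else 0
    alpha_x <- max(-0.99, min(0.99, alpha_x))

    # complete-cluster working-covariance inverse (times phi*(1-alpha^2))
    den <- phi * (1 - alpha_x^2)
    a <- 1 / (den * v1); cc <- 1 / (den * v2)
    bb <- -alpha_x / (den * sqrt(v1 * v2))
    # M = D' V^{-1} with D = rbind(c(v1, 0), c(v2, v2))
    m11 <- v1 * a + v2 * bb; m12 <- v1 * bb + v2 * cc
    m21 <- v2 * bb;          m22 <- v2 * cc
    # score U and information I0
    u1 <- m11 * sr1 + m12 * sr2 + sr1s / phi + sr2s / phi
    u2 <- m21 * sr1 + m22 * sr2 + sr2s / phi
    i0_11 <- npp * (m11 * v1 + m12 * v2) + (n0x + n1x) * v1 / phi +
      (nx0 + nx1) * v2 / phi
    i0_12 <- npp * (m12 * v2) + (nx0 + nx1) * v2 / phi
    i0_22 <- npp * (m22 * v2) + (nx0 + nx1) * v2 / phi
    det0 <- i0_11 * i0_22 - i0_12^2
    if (!is.finite(det0) || det0 <= 0) stop("singular GEE information matrix")
    d_b0 <- (i0_22 * u1 - i0_12 * u2) / det0
    d_b1 <- (-i0_12 * u1 + i0_11 * u2) / det0
    b0 <- b0 + d_b0; b1 <- b1 + d_b1
    if (max(abs(d_b0), abs(d_b1)) < tol * (1 + max(abs(b0), abs(b1)))) {
      converged <- TRUE
      break
    }
  }

  # final quantities at the converged estimate
  mu1 <- stats::plogis(b0); mu2 <- stats::plogis(b0 + b1)
  v1 <- mu1 * (1 - mu1); v2 <- mu2 * (1 - mu2)
  sr1 <- n1p * (1 - mu1) - n0p * mu1
  sr2 <- np1 * (1 - mu2) - np0 * mu2
  sr11 <- n1p * (1 - mu1)^2 + n0p * mu1^2
  sr22 <- np1 * (1 - mu2)^2 + np0 * mu2^2
  sr12 <- n00 * mu1 * mu2 - n01 * mu1 * (1 - mu2) -
    n10 * (1 - mu1) * mu2 + n11 * (1 - mu1) * (1 - mu2)
  sr1s <- n1x * (1 - mu1) - n0x * mu1
  sr11s <- n1x * (1 - mu1)^2 + n0x * mu1^2
  sr2s <- nx1 * (1 - mu2) - nx0 * mu2
  sr22s <- nx1 * (1 - mu2)^2 + nx0 * mu2^2
  den <- phi * (1 - alpha_x^2)
  a <- 1 / (den * v1); cc <- 1 / (den * v2)
  bb <- -alpha_x / (den * sqrt(v1 * v2))
  m11 <- v1 * a + v2 * bb; m12 <- v1 * bb + v2 * cc
  m21 <- v2 * bb;          m22 <- v2 * cc
  u1 <- m11 * sr1 + m12 * sr2 + sr1s / phi + sr2s / phi
  u2 <- m21 * sr1 + m22 * sr2 + sr2s / phi
  i0_11 <- npp * (m11 * v1 + m12 * v2) + (n0x + n1x) * v1 / phi +
    (nx0 + nx1) * v2 / phi
  i0_12 <- npp * (m12 * v2) + (nx0 + nx1) * v2 / phi
  i0_22 <- npp * (m22 * v2) + (nx0 + nx1) * v2 / phi
  # I1 with empirical Cov(y_c): complete clusters via residual cross moments,
  # singletons via squared residuals
  j11 <- m11 * (m11 * sr11 + m12 * sr12) + m12 * (m11 * sr12 + m12 * sr22) +
    sr11s / phi^2 + sr22s / phi^2
  j12 <- m21 * (m11 * sr11 + m12 * sr12) + m22 * (m11 * sr12 + m12 * sr22) +
    sr22s / phi^2
  j22 <- m21 * (m21 * sr11 + m22 * sr12) + m22 * (m21 * sr12 + m22 * sr22) +
    sr22s / phi^2
  i0 <- matrix(c(i0_11, i0_12, i0_12, i0_22), 2, 2)
  i1 <- matrix(c(j11, j12, j12, j22), 2, 2)
  det0 <- i0_11 * i0_22 - i0_12^2
  i0_inv <- matrix(c(i0_22, -i0_12, -i0_12, i0_11), 2, 2) / det0
  dimnames(i0_inv) <- list(c("(Intercept)", "k2"), c("(Intercept)", "k2"))
  cov_sw <- i0_inv %*% i1 %*% i0_inv

  structure(list(beta = c("(Intercept)" = b0, k2 = b1),
                 cov_model = i0_inv, cov_sandwich = cov_sw,
                 alpha_exch = alpha_x, phi = phi,
                 mu = c(mu1 = mu1, mu2 = mu2),
                 n_clusters = tab$n, n_obs = n_obs,
                 iterations = iter, converged = converged,
                 score_norm = sqrt(u1^2 + u2^2)),
            class = "gee_fit")
}

#' Fit the marginal logistic model by generalized estimating equations
#'
#' Fits `logit P(Y = 1 | k) = b0 + b1 I(k = 2)` to all observed outcomes,
#' treating the two outcomes of a patient as a cluster, with an exchangeable
#' working correlation. The coefficient estimate solves the estimating
#' equation `sum_c D_c' V_c^{-1} (y_c - mu_c) = 0` by iteratively reweighted
#' Fisher scoring, alternating with a moment re-estimate of the exchangeable
#' correlation (from complete clusters only; singleton clusters carry no
#' correlation information but contribute fully to the mean estimation). The
#' dispersion `phi` is fixed at 1 by default, appropriate for binary
#' outcomes; `phi_fixed = FALSE` enables a Pearson-residual moment estimate.
#' Both the model-based covariance `I0^{-1}` and the robust sandwich
#' covariance `I0^{-1} I1 I0^{-1}` (with the per-cluster empirical
#' outer-product residual estimate of `Cov(y_c)`) are returned.
#'
#' @param x A [paired_table], a data frame of pairs (`y1`, `y2`), or a
#'   [gee_design].
#' @param phi_fixed Keep the dispersion fixed at 1 (default).
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param maxit Maximum number of scoring iterations.
#' @return An object of class `gee_fit`; see [gee_risk_difference] to map it
#'   to the risk-difference scale.
#' @export
gee_fit <- function(x, phi_fixed = TRUE, tol = 1e-10, maxit = 100L) {
  tab <- if (inherits(x, "gee_design")) design_to_table(x) else
    as_paired_table(x)
  gee_fit_core(tab, phi_fixed = phi_fixed, tol = tol, maxit = maxit)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE marginal logistic fit (exchangeable working correlation)\n")
  cat(sprintf("  beta: (%.6f, %.6f)   alpha_exch: %.4f   phi: %.4f\n",
              x$beta[1], x$beta[2], x$alpha_exch, x$phi))
  cat(sprintf("  clusters: %d   observations: %d   iterations: %d%s\n",
              x$n_clusters, x$n_obs, x$iterations,
              if (x$converged) "" else "   (NOT converged)"))
  invisible(x)
}

#' Risk difference and delta-method standard error from a GEE fit
#'
#' Maps the logit-scale coefficients to the risk difference
#' `theta = plogis(b0) - plogis(b0 + b1)` and propagates the coefficient
#' covariance through the gradient
#' `g = (mu1 (1 - mu1) - mu2 (1 - mu2), -mu2 (1 - mu2))`.
#'
#' @param fit A [gee_fit].
#' @param robust Use the sandwich covariance (default) or the model-based
#'   one.
#' @return A list with `theta`, `se` and `gradient`.
#' @export
gee_risk_difference <- function(fit, robust = TRUE) {
  stopifnot(inherits(fit, "gee_fit"))
  mu1 <- fit$mu[["mu1"]]; mu2 <- fit$mu[["mu2"]]
  v1 <- mu1 * (1 - mu1); v2 <- mu2 * (1 - mu2)
  g <- c(v1 - v2, -v2)
  cov <- if (robust) fit$cov_sandwich else fit$cov_model
  se <- sqrt(max(0, drop(t(g) %*% cov %*% g)))
  list(theta = mu1 - mu2, se = se, gradient = g)
}

#' GEE delta-method confidence interval for the paired risk difference
#'
#' Wald interval `theta_gee +/- z_alpha * se` on the risk-difference scale,
#' where `theta_gee` and its delta-method standard error come from the
#' exchangeable-working-correlation GEE fit of [gee_fit] on all observed
#' outcomes (singleton clusters included). The robust sandwich standard
#' error is the default.
#'
#' @param table A [paired_table], data frame of pairs, or [gee_design].
#' @param alpha One-sided level; the interval is two-sided `1 - 2*alpha`.
#' @param robust Use the sandwich covariance (default).
#' @param ... Passed to [gee_fit].
#' @return A `paired_ci` with method tag `"gee"` and extra element `fit`.
#' @export
gee_ci <- function(table, alpha = 0.05, robust = TRUE, ...) {
  stopifnot(alpha > 0, alpha < 0.5)
  fit <- gee_fit(table, ...)
  rd <- gee_risk_difference(fit, robust = robust)
  z <- z_upper(alpha)
  new_paired_ci(rd$theta - z * rd$se, rd$theta + z * rd$se,
                estimate = rd$theta, alpha = alpha, method = "gee",
                n_used = fit$n_clusters, extra = list(fit = fit))
}
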