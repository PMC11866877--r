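#' Logistic imputation models for partially observed pairs
#'
#' Fits, on the completely observed pairs, the two cross-outcome logistic
#' regressions used to impute missing single observations:
#' `logit P(y1 = 1 | y2) = b0 + b1 y2` (direction `"y1_given_y2"`) and
#' `logit P(y2 = 1 | y1) = b0 + b1 y1` (direction `"y2_given_y1"`).
#' With a single binary covariate the model is saturated, so the ML
#' estimates and their inverse-observed-information covariance have closed
#' forms in the four complete-pair counts, e.g. for `"y2_given_y1"`:
#' `b1 = log(n11 n00 / (n10 n01))` (the log odds ratio). When any complete
#' cell is zero the fit is degenerate (separation); 0.5 is then added to each
#' complete-pair cell for the purpose of fitting only, with a warning.
#'
#' @param table A [paired_table].
#' @return A list with components `y1_given_y2` and `y2_given_y1`, each an
#'   `imputation_model`: a list with `beta` (length-2 coefficient vector),
#'   `cov` (2 x 2 covariance) and `direction`.
#' @export
fit_imputation_models <- function(table) {
  table <- as_paired_table(table)
  if (table$npp == 0) stop("no completely observed pairs to fit on")
  n <- c(n00 = table$n00, n01 = table$n01, n10 = table$n10, n11 = table$n11)
  if (any(n == 0)) {
    warning("zero complete-pair cell: adding 0.5 to each cell for the ",
            "imputation-model fit")
    n <- n + 0.5
  }
  sat_fit <- function(s0, f0, s1, f1, direction) {
    # group 0: covariate = 0 with s0 successes / f0 failures; group 1 likewise
    b0 <- log(s0 / f0)
    b1 <- log(s1 / f1) - b0
    w0 <- s0 * f0 / (s0 + f0)
    w1 <- s1 * f1 / (s1 + f1)
    cov <- matrix(c(1 / w0, -1 / w0, -1 / w0, 1 / w0 + 1 / w1), 2, 2)
    structure(list(beta = c(b0, b1), cov = cov, direction = direction),
              class = "imputation_model")
  }
  list(
    # P(y1 = 1 | y2): groups by y2
    y1_given_y2 = sat_fit(n[["n10"]], n[["n00"]], n[["n11"]], n[["n01"]],
                          "y1_given_y2"),
    # P(y2 = 1 | y1): groups by y1
    y2_given_y1 = sat_fit(n[["n01"]], n[["n00"]], n[["n11"]], n[["n10"]],
                          "y2_given_y1"))
}

# One bivariate-normal draw from the asymptotic coefficient distribution.
draw_coef <- function(model) {
  s <- model$cov
  l11 <- sqrt(s[1, 1])
  l21 <- s[2, 1] / l11
  l22 <- sqrt(max(s[2, 2] - l21^2, 0))
  z <- stats::rnorm(2)
  model$beta + c(l11 * z[1], l21 * z[1] + l22 * z[2])
}

#' Single stochastic imputation of a paired-count table
#'
#' Draws one coefficient vector per model from its asymptotic normal
#' distribution, converts each incomplete pair's predicted score to a success
#' probability through the inverse logit, and dichotomizes by comparison with
#' uniform draws (equivalently, binomial draws per cell). The returned table
#' has no missing cells and the same total number of patients.
#'
#' @param table A [paired_table].
#' @param models As returned by [fit_imputation_models]; fitted on `table`'s
#'   complete pairs if omitted.
#' @return A completed [paired_table] with `npx = nxp = 0` and `npp` equal
#'   to the original `n`.
#' @export
impute_table <- function(table, models = fit_imputation_models(table)) {
  table <- as_paired_table(table)
  if (table$npx + table$nxp == 0) return(table)
  b_y1 <- draw_coef(models$y1_given_y2)
  b_y2 <- draw_coef(models$y2_given_y1)
  # pairs with y1 missing, observed y2 = 0 / 1
  k10 <- stats::rbinom(1L, table$nx0, stats::plogis(b_y1[1]))
  k11 <- stats::rbinom(1L, table$nx1, stats::plogis(b_y1[1] + b_y1[2]))
  # pairs with y2 missing, observed y1 = 0 / 1
  k01 <- stats::rbinom(1L, table$n0x, stats::plogis(b_y2[1]))
  k21 <- stats::rbinom(1L, table$n1x, stats::plogis(b_y2[1] + b_y2[2]))
  paired_table(n00 = table$n00 + (table$nx0 - k10) + (table$n0x - k01),
               n01 = table$n01 + k01 + (table$nx1 - k11),
               n10 = table$n10 + k10 + (table$n1x - k21),
               n11 = table$n11 + k11 + k21)
}

# Fast internal MI Wald CI from raw counts; rng state is taken as-is.
# Scalar re-implementation of fit_imputation_models + impute_table (tested
# for agreement with the object path), written this way so that
# 10'000-replicate scenarios stay cheap.
mi_ci_core <- function(tab, m, alpha, use_t = FALSE) {
  n <- tab$n
  if (tab$npx + tab$nxp == 0) {
    th <- (tab$n10 - tab$n01) / tab$npp
    s2 <- ((tab$n01 + tab$n10) / tab$npp - th^2) / tab$npp
    z <- z_upper(alpha)
    return(c(th - z * sqrt(s2), th + z * sqrt(s2), th, 0, s2))
  }
  c00 <- tab$n00; c01 <- tab$n01; c10 <- tab$n10; c11 <- tab$n11
  if (c00 == 0 || c01 == 0 || c10 == 0 || c11 == 0) {
    c00 <- c00 + 0.5; c01 <- c01 + 0.5; c10 <- c10 + 0.5; c11 <- c11 + 0.5
  }
  # saturated logistic fits: independent group logits with SDs 1/sqrt(w)
  # model A: P(y1 = 1 | y2), groups by y2
  la0 <- log(c10 / c00); la1 <- log(c11 / c01)
  sa0 <- sqrt(1 / c10 + 1 / c00); sa1 <- sqrt(1 / c11 + 1 / c01)
  # model B: P(y2 = 1 | y1), groups by y1
  lb0 <- log(c01 / c00); lb1 <- log(c11 / c10)
  sb0 <- sqrt(1 / c01 + 1 / c00); sb1 <- sqrt(1 / c11 + 1 / c10)
  # one coefficient draw per model per imputation, vectorized over the m
  # imputations (independent group logits, see fit_imputation_models)
  pa0 <- stats::plogis(la0 + sa0 * stats::rnorm(m))  # y1 | y2 = 0
  pa1 <- stats::plogis(la1 + sa1 * stats::rnorm(m))  # y1 | y2 = 1
  pb0 <- stats::plogis(lb0 + sb0 * stats::rnorm(m))  # y2 | y1 = 0
  pb1 <- stats::plogis(lb1 + sb1 * stats::rnorm(m))  # y2 | y1 = 1
  k10 <- stats::rbinom(m, tab$nx0, pa0)  # imputed y1 = 1, observed y2 = 0
  k11 <- stats::rbinom(m, tab$nx1, pa1)  # imputed y1 = 1, observed y2 = 1
  k01 <- stats::rbinom(m, tab$n0x, pb0)  # observed y1 = 0, imputed y2 = 1
  k21 <- stats::rbinom(m, tab$n1x, pb1)  # observed y1 = 1, imputed y2 = 1
  m10 <- tab$n10 + k10 + (tab$n1x - k21)
  m01 <- tab$n01 + k01 + (tab$nx1 - k11)
  th <- (m10 - m01) / n
  s2 <- ((m01 + m10) / n - th^2) / n
  tbar <- mean(th)
  w <- mean(s2)
  b <- if (m > 1) stats::var(th) else 0
  total <- w + (1 + 1 / m) * b
  q <- if (use_t && b > 0) {
    lam <- (1 + 1 / m) * b / total
    df_old <- (m - 1) / lam^2
    nu_com <- n - 1
    df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lam)
    stats::qt(1 - alpha, df_old * df_obs / (df_old + df_obs))
  } else {
    z_upper(alpha)
  }
  c(tbar - q * sqrt(total), tbar + q * sqrt(total), tbar, b, w)
}

#' Multiple-imputation Wald confidence interval for the risk difference
#'
#' Imputes the missing single observations `m` times via [impute_table],
#' computes on each completed table the complete-data estimator
#' `theta = (n10 - n01)/n` and its unrestricted ML variance
#' `sigma^2 = ((p01 + p10) - theta^2)/n`, pools by Rubin's rules
#' (`total = within + (1 + 1/m) between`), and forms the Wald interval
#' `theta_bar +/- z_alpha sqrt(total)`. The normal reference quantile is the
#' default; `use_t = TRUE` switches to the Barnard-Rubin small-sample t
#' reference as a sensitivity option. With no missing observations the
#' interval equals the single-dataset Wald interval exactly.
#'
#' @param table A [paired_table] (or data frame of pairs).
#' @param m Number of imputations (default 10).
#' @param alpha One-sided level; the interval is two-sided `1 - 2*alpha`.
#' @param use_t Use the Barnard-Rubin t reference instead of the normal.
#' @return A `paired_ci` with method tag `"mi_wald"` and extra elements
#'   `m`, `within_var`, `between_var`, `total_var`.
#' @export
mi_ci <- function(table, m = 10, alpha = 0.05, use_t = FALSE) {
  table <- as_paired_table(table)
  stopifnot(m >= 2, alpha > 0, alpha < 0.5)
  if (table$npp == 0) stop("no completely observed pairs")
  r <- mi_ci_core(table, m, alpha, use_t)
  new_paired_ci(r[1], r[2], estimate = r[3], alpha = alpha,
                method = "mi_wald", n_used = table$n,
                extra = list(m = m, between_var = r[4], within_var = r[5],
                             total_var = r[5] + (1 + 1 / m) * r[4]))
}
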