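#' Define one Monte-Carlo scenario
#'
#' A scenario fixes the design of one cell of the simulation grid: the number
#' of pairs, the within-pair correlation, the non-inferiority margin `delta`,
#' the true risk difference `theta` (signed; `theta = -delta` places the data
#' on the null boundary, where power equals the type-I error rate), the
#' per-arm missingness probabilities, the one-sided level and the number of
#' replicates. Marginal success probabilities are anchored at `base` (0.8):
#' a negative `theta` lowers the intervention-1 marginal
#' (`p1 = base + theta`), a positive one lowers the intervention-2 marginal,
#' so one marginal always stays at `base`.
#'
#' @param n Number of patients (pairs) per replicate.
#' @param rho Within-pair correlation of the binary outcomes.
#' @param delta Non-inferiority margin (`>= 0`).
#' @param theta True risk difference `p1 - p2`.
#' @param p_miss1,p_miss2 Probabilities that the first / second outcome of a
#'   pair is missing.
#' @param alpha One-sided significance level (two-sided CIs at `1-2*alpha`).
#' @param n_sim Number of Monte-Carlo replicates.
#' @param seed Scenario seed; replicate sub-streams are derived from it.
#' @param methods Subset of `c("tango", "mi", "hybrid", "gee")`.
#' @param base Anchor marginal success probability.
#' @param m Number of imputations for the MI method.
#' @return A list of class `ni_scenario`.
#' @export
scenario <- function(n, rho, delta, theta, p_miss1 = 0, p_miss2 = 0,
                     alpha = 0.05, n_sim = 10000, seed = 1,
                     methods = c("tango", "mi", "hybrid", "gee"),
                     base = 0.8, m = 10) {
  stopifnot(n >= 1, delta >= 0, abs(theta) <= 1,
            p_miss1 >= 0, p_miss2 >= 0, p_miss1 + p_miss2 <= 1,
            alpha > 0, alpha < 0.5, n_sim >= 1)
  methods <- match.arg(methods, c("tango", "mi", "hybrid", "gee"),
                       several.ok = TRUE)
  p1 <- base + min(theta, 0)
  p2 <- base - max(theta, 0)
  structure(list(n = n, rho = rho, delta = delta, theta = theta,
                 p1 = p1, p2 = p2, p_miss1 = p_miss1, p_miss2 = p_miss2,
                 alpha = alpha, n_sim = n_sim, seed = seed,
                 methods = methods, base = base, m = m),
            class = "ni_scenario")
}

# Split a complete paired table's cells by the multinomial missingness
# indicator; distributionally identical to impose_missing on pair level
# (sequential binomial decomposition of the per-cell multinomial).
split_missing <- function(tab, p_miss1, p_miss2) {
  if (p_miss1 + p_miss2 == 0) return(tab)
  cells <- c(tab$n11, tab$n10, tab$n01, tab$n00)
  g1 <- stats::rbinom(4L, cells, p_miss1)
  p2c <- if (p_miss1 < 1) p_miss2 / (1 - p_miss1) else 0
  g2 <- stats::rbinom(4L, cells - g1, p2c)
  keep <- cells - g1 - g2
  new_ptab(n11 = keep[1], n10 = keep[2], n01 = keep[3], n00 = keep[4],
           n1x = g2[1] + g2[2], n0x = g2[3] + g2[4],
           nx1 = g1[1] + g1[3], nx0 = g1[2] + g1[4])
}

# One CI per method on one table; returns c(lower, upper) or throws.
method_ci <- function(method, tab, alpha, m) {
  switch(method,
         tango = {
           if (tab$npp == 0) stop("no complete pairs")
           tango_ci_core(tab$n01, tab$n10, tab$npp, alpha)
         },
         mi = {
           if (tab$npp == 0) stop("no complete pairs")
           mi_ci_core(tab, m, alpha)[1:2]
         },
         hybrid = {
           ci <- hybrid_ci(tab, alpha)
           c(ci$lower, ci$upper)
         },
         gee = {
           fit <- gee_fit_core(tab)
           rd <- gee_risk_difference(fit)
           z <- z_upper(alpha)
           c(rd$theta - z * rd$se, rd$theta + z * rd$se)
         })
}

#' Run one Monte-Carlo scenario
#'
#' For each replicate, pairs are generated from the joint law implied by the
#' scenario's marginals and correlation, missingness is imposed through the
#' multinomial single-missingness indicator, and each requested method's
#' two-sided `100*(1-2*alpha)%` interval is computed. Non-inferiority is
#' declared when the interval's lower bound exceeds `-delta` (the same
#' decision surface for all methods); coverage is with respect to the true
#' `theta`. Replicate-level method failures (degenerate tables, separation,
#' non-convergence) are counted and excluded from the proportions, with a
#' warning when they exceed 1% of replicates.
#'
#' Pair generation, missingness and any analysis randomness (MI draws) use
#' separate seed sub-streams derived from `(seed, replicate)`, so results do
#' not depend on which methods are run, whether missingness is imposed, or
#' the order of execution.
#'
#' @param sc A [scenario].
#' @return A data frame with one row per method: `power`, `coverage`,
#'   `mean_width`, Monte-Carlo standard errors `mcse_power` and
#'   `mcse_coverage` (`sqrt(p(1-p)/n_eval)`), `n_failed`, and the scenario
#'   parameters.
#' @export
run_scenario <- function(sc) {
  stopifnot(inherits(sc, "ni_scenario"))
  dist <- joint_from_marginals(sc$p1, sc$p2, sc$rho)
  methods <- sc$methods
  nm <- length(methods)
  rej <- cov <- wid <- fail <- stats::setNames(numeric(nm), methods)
  has_missing <- sc$p_miss1 + sc$p_miss2 > 0
  for (r in seq_len(sc$n_sim)) {
    set.seed(derive_seed(sc$seed, r, 1))
    tab <- r_paired_counts(sc$n, dist)
    if (has_missing) {
      set.seed(derive_seed(sc$seed, r, 2))
      tab <- split_missing(tab, sc$p_miss1, sc$p_miss2)
    }
    for (meth in methods) {
      if (meth == "mi") set.seed(derive_seed(sc$seed, r, 3))
      lim <- tryCatch(suppressWarnings(method_ci(meth, tab, sc$alpha, sc$m)),
                      error = function(e) NULL)
      if (is.null(lim) || any(!is.finite(lim))) {
        fail[meth] <- fail[meth] + 1
      } else {
        rej[meth] <- rej[meth] + (lim[1] > -sc$delta)
        cov[meth] <- cov[meth] + (lim[1] <= sc$theta && sc$theta <= lim[2])
        wid[meth] <- wid[meth] + (lim[2] - lim[1])
      }
    }
  }
  n_eval <- sc$n_sim - fail
  if (any(fail > 0.01 * sc$n_sim)) {
    warning(sprintf("method failure rate above 1%% in scenario (n=%d): %s",
                    sc$n, paste(methods[fail > 0.01 * sc$n_sim],
                                collapse = ", ")))
  }
  power <- ifelse(n_eval > 0, rej / n_eval, NA_real_)
  coverage <- ifelse(n_eval > 0, cov / n_eval, NA_real_)
  data.frame(method = methods,
             power = power,
             coverage = coverage,
             mean_width = ifelse(n_eval > 0, wid / n_eval, NA_real_),
             mcse_power = sqrt(power * (1 - power) / pmax(n_eval, 1)),
             mcse_coverage = sqrt(coverage * (1 - coverage) / pmax(n_eval, 1)),
             n_failed = as.integer(fail),
             n_sim = sc$n_sim,
             n = sc$n, rho = sc$rho, delta = sc$delta, theta = sc$theta,
             p_miss1 = sc$p_miss1, p_miss2 = sc$p_miss2, alpha = sc$alpha,
             seed = sc$seed,
             row.names = NULL)
}

#' The default 468-cell scenario grid
#'
#' Crosses 13 sample sizes (20-100 by 10, then 200, 300, 400, 507), three
#' within-pair correlations (0, 0.37, 0.5), three margin/effect combinations
#' (the null boundary at `delta = 0.05`, and the alternatives
#' `delta = 0.05, theta = 0` and `delta = 0.1, theta = 0`) and four
#' missingness settings (none, MCAR 15%/15%, MCAR 25%/25%, MAR 10%/30%).
#'
#' @param n_sim Replicates per scenario.
#' @return A data frame with 468 rows of scenario parameters.
#' @export
scenario_grid <- function(n_sim = 10000) {
  dt <- data.frame(delta = c(0.05, 0.05, 0.10),
                   theta = c(-0.05, 0, 0))
  miss <- data.frame(p_miss1 = c(0, 0.15, 0.25, 0.1),
                     p_miss2 = c(0, 0.15, 0.25, 0.3))
  g <- expand.grid(n = c(seq(20, 100, by = 10), 200, 300, 400, 507),
                   rho = c(0, 0.37, 0.5),
                   dt = seq_len(nrow(dt)),
                   miss = seq_len(nrow(miss)))
  out <- data.frame(n = g$n, rho = g$rho,
                    delta = dt$delta[g$dt], theta = dt$theta[g$dt],
                    p_miss1 = miss$p_miss1[g$miss],
                    p_miss2 = miss$p_miss2[g$miss],
                    alpha = 0.05, n_sim = n_sim)
  out
}

#' Run a grid of scenarios
#'
#' Each row of `grid` is run through [run_scenario] with a per-scenario seed
#' derived deterministically from `(seed, row index)`, so results are
#' independent of execution order.
#'
#' @param grid Data frame with columns `n`, `rho`, `delta`, `theta`,
#'   `p_miss1`, `p_miss2` and optionally `alpha`, `n_sim`.
#' @param seed Root seed.
#' @param methods Methods to evaluate.
#' @param n_sim Default replicates when the grid carries no `n_sim` column.
#' @param m Imputations for the MI method.
#' @param verbose Print one line per completed scenario.
#' @return A data frame with one row per scenario x method.
#' @export
run_grid <- function(grid, seed = 1,
                     methods = c("tango", "mi", "hybrid", "gee"),
                     n_sim = 10000, m = 10, verbose = FALSE) {
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- scenario(n = grid$n[i], rho = grid$rho[i], delta = grid$delta[i],
                   theta = grid$theta[i],
                   p_miss1 = grid$p_miss1[i], p_miss2 = grid$p_miss2[i],
                   alpha = grid$alpha[i] %||% 0.05,
                   n_sim = (grid$n_sim[i] %||% n_sim),
                   seed = derive_seed(seed, i, 17),
                   methods = methods, m = m)
    res[[i]] <- cbind(scenario_id = i, run_scenario(sc))
    if (verbose) {
      message(sprintf("scenario %d/%d done (n=%d)", i, nrow(grid), grid$n[i]))
    }
  }
  do.call(rbind, res)
}

#' Simulation-based sample-size search
#'
#' Estimates power by Monte Carlo on a grid of sample sizes for a single
#' method and applies the conservative rule: the smallest grid value whose
#' estimated power exceeds `target_power` at that size *and at every larger
#' grid size*. Replicate seeds are shared across grid points (common random
#' numbers), which makes the estimated power curve smooth in `n`.
#'
#' @param method One of `"tango"`, `"mi"`, `"hybrid"`, `"gee"`.
#' @param n_grid Strictly increasing integer sample sizes.
#' @param rho,delta,theta,p_miss1,p_miss2,alpha,base,m Design parameters, as
#'   in [scenario].
#' @param target_power Required power.
#' @param n_sim Replicates per grid point.
#' @param seed Root seed (shared across grid points).
#' @return The selected sample size (integer), with the estimated power
#'   curve attached as attribute `"power"`.
#' @export
sample_size_search <- function(method, n_grid, rho, delta, theta = 0,
                               p_miss1 = 0, p_miss2 = 0, alpha = 0.05,
                               target_power = 0.80, n_sim = 10000, seed = 1,
                               base = 0.8, m = 10) {
  stopifnot(length(n_grid) >= 1, !is.unsorted(n_grid, strictly = TRUE))
  method <- match.arg(method, c("tango", "mi", "hybrid", "gee"))
  pow <- vapply(n_grid, function(n) {
    sc <- scenario(n = n, rho = rho, delta = delta, theta = theta,
                   p_miss1 = p_miss1, p_miss2 = p_miss2, alpha = alpha,
                   n_sim = n_sim, seed = seed, methods = method,
                   base = base, m = m)
    run_scenario(sc)$power
  }, numeric(1))
  ok <- rev(cumprod(rev(pow > target_power))) == 1
  if (!any(ok)) {
    stop(sprintf("target power %.2f not achieved on the grid (max %.4f)",
                 target_power, max(pow)))
  }
  structure(n_grid[which(ok)[1]], power = stats::setNames(pow, n_grid))
}
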