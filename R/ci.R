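# Common confidence-interval result container used by all four methods.

new_paired_ci <- function(lower, upper, estimate, alpha, method, n_used,
                          extra = list()) {
  out <- c(list(lower = clip_theta(lower), upper = clip_theta(upper),
                estimate = estimate, level = 1 - 2 * alpha, alpha = alpha,
                method = method, n_used = n_used), extra)
  structure(out, class = "paired_ci")
}

#' @export
print.paired_ci <- function(x, ...) {
  cat(sprintf("%s %.0f%% CI for the risk difference\n",
              switch(x$method,
                     tango = "Tango score (RMLE)",
                     mi_wald = "Multiple-imputation Wald",
                     hybrid = "Hybrid Wilson-based Wald",
                     gee = "GEE delta-method",
                     x$method),
              100 * x$level))
  cat(sprintf("  estimate: %.6f   interval: [%.6f, %.6f]   n used: %d\n",
              x$estimate, x$lower, x$upper, x$n_used))
  invisible(x)
}

#' Non-inferiority decision from a confidence interval
#'
#' Rejects the null hypothesis of inferiority, `theta <= -delta`, when the
#' lower bound of the two-sided `100*(1-2*alpha)%` interval exceeds `-delta`.
#' This is the uniform decision rule used for all four interval methods.
#'
#' @param ci A `paired_ci` as returned by [tango_ci], [mi_ci], [hybrid_ci]
#'   or [gee_ci].
#' @param delta Non-inferiority margin (nonnegative).
#' @return `TRUE` if non-inferiority is concluded.
#' @export
noninferior <- function(ci, delta) {
  stopifnot(inherits(ci, "paired_ci"), delta >= 0)
  ci$lower > -delta
}
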