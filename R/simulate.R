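#' Joint distribution of a correlated binary pair from marginals and rho
#'
#' For two Bernoulli outcomes the joint law is fully determined by the two
#' marginal success probabilities and their Pearson (phi) correlation:
#' `p11 = p1 p2 + rho * sqrt(p1 (1-p1) p2 (1-p2))`, with the remaining cells
#' by subtraction. The requested correlation must keep `p11` inside the
#' Frechet bounds `max(0, p1 + p2 - 1) <= p11 <= min(p1, p2)`.
#'
#' @param p1,p2 Marginal success probabilities in `(0, 1)`.
#' @param rho Within-pair correlation.
#' @return An object of class `joint_pair_dist`: list with cells `p11`,
#'   `p10`, `p01`, `p00` and the inputs `p1`, `p2`, `rho`.
#' @examples
#' joint_from_marginals(0.8, 0.8, 0.375)  # concordant mass 0.80
#' @export
joint_from_marginals <- function(p1, p2, rho) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- p1 * p2 + rho * s
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop(sprintf(
      "infeasible correlation: rho must lie in [%.6f, %.6f] for these marginals",
      (lo - p1 * p2) / s, (hi - p1 * p2) / s))
  }
  p11 <- min(max(p11, lo), hi)
  structure(list(p11 = p11, p10 = p1 - p11, p01 = p2 - p11,
                 p00 = 1 - p1 - p2 + p11, p1 = p1, p2 = p2, rho = rho),
            class = "joint_pair_dist")
}

#' Generate correlated binary matched pairs
#'
#' Draws `n` independent pairs from the four-cell multinomial law of a
#' [joint_from_marginals] distribution. For two binary outcomes this is
#' distributionally identical to latent-Gaussian threshold generators: the
#' joint law has no freedom beyond `(p1, p2, rho)`.
#'
#' @param n Number of pairs.
#' @param dist A `joint_pair_dist`.
#' @return A data frame with columns `id`, `y1`, `y2` (no missing values).
#' @export
generate_pairs <- function(n, dist) {
  stopifnot(inherits(dist, "joint_pair_dist"), n >= 1)
  idx <- sample.int(4L, n, replace = TRUE,
                    prob = c(dist$p11, dist$p10, dist$p01, dist$p00))
  data.frame(id = seq_len(n),
             y1 = as.integer(idx <= 2L),
             y2 = as.integer(idx == 1L | idx == 3L))
}

#' Impose MCAR/MAR missingness on matched pairs
#'
#' For each pair, one multinomial indicator is drawn taking value 1 (set
#' `y1` missing) with probability `p_miss1`, value 2 (set `y2` missing) with
#' probability `p_miss2`, and value 3 (keep both) otherwise. At most one
#' outcome per pair can be removed, and removal never depends on the outcome
#' values, so the mechanism is MCAR when `p_miss1 = p_miss2` and MAR (arm-
#' dependent) otherwise.
#'
#' @param pairs Data frame with columns `y1`, `y2`.
#' @param p_miss1,p_miss2 Per-pair probabilities of losing the first or
#'   second observation; `p_miss1 + p_miss2 <= 1`.
#' @return The data frame with missing outcomes set to `NA`.
#' @export
impose_missing <- function(pairs, p_miss1, p_miss2) {
  stopifnot(p_miss1 >= 0, p_miss2 >= 0, p_miss1 + p_miss2 <= 1)
  if (p_miss1 + p_miss2 == 0) return(pairs)
  g <- sample.int(3L, nrow(pairs), replace = TRUE,
                  prob = c(p_miss1, p_miss2, 1 - p_miss1 - p_miss2))
  pairs$y1[g == 1L] <- NA
  pairs$y2[g == 2L] <- NA
  pairs
}

# Fast count-level equivalent of generate_pairs + impose_missing +
# tabulate_pairs: draws the complete-pair cell counts from the four-cell
# multinomial, then splits each cell multinomially into (y1 missing,
# y2 missing, kept). The missingness indicators are independent of the
# outcomes, so this is the same law as the pair-level path. Generation and
# missingness use the RNG in that order, so the complete-pair counts are
# unchanged by toggling missingness.
r_paired_counts <- function(n, dist, p_miss1 = 0, p_miss2 = 0) {
  cells <- stats::rmultinom(1L, n, c(dist$p11, dist$p10, dist$p01, dist$p00))
  tab <- new_ptab(n11 = cells[1L], n10 = cells[2L],
                  n01 = cells[3L], n00 = cells[4L])
  if (p_miss1 + p_miss2 == 0) tab else {
    split_missing(tab, p_miss1, p_miss2)
  }
}
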