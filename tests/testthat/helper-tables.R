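# Shared helpers for the test suite.

# Random paired-count table with at least `min_discordant` discordant pairs,
# optionally with incomplete margins.
random_table <- function(n = 100, missing = TRUE, min_discordant = 1) {
  repeat {
    p <- as.numeric(stats::rmultinom(1, n, c(4, 2, 2, 4, 1, 1, 1, 1)))
    if (!missing) {
      p <- c(as.numeric(stats::rmultinom(1, n, c(4, 2, 2, 4))), 0, 0, 0, 0)
    }
    tab <- paired_table(n00 = p[1], n01 = p[2], n10 = p[3], n11 = p[4],
                        n0x = p[5], n1x = p[6], nx0 = p[7], nx1 = p[8])
    if (tab$n01 + tab$n10 >= min_discordant && tab$npp >= 4) return(tab)
  }
}

# Long-format pairs (with NAs) from a paired_table, in randomized row order.
table_to_pairs <- function(tab, shuffle = FALSE) {
  df <- expand_pairs(tab)
  if (shuffle) df <- df[sample.int(nrow(df)), , drop = FALSE]
  df
}

# Brute-force GEE reference: evaluate score, model and sandwich covariance
# by an explicit matrix-algebra loop over clusters at a given
# (beta, alpha, phi).
gee_reference <- function(tab, beta, alpha_x, phi) {
  df <- expand_pairs(tab)
  U <- c(0, 0); I0 <- matrix(0, 2, 2); I1 <- matrix(0, 2, 2)
  for (i in seq_len(nrow(df))) {
    y <- c(df$y1[i], df$y2[i])
    obs <- !is.na(y)
    X <- cbind(1, c(0, 1))[obs, , drop = FALSE]
    y <- y[obs]
    mu <- plogis(drop(X %*% beta))
    v <- mu * (1 - mu)
    A <- diag(sqrt(v), nrow = length(v))
    R <- if (length(v) == 2) matrix(c(1, alpha_x, alpha_x, 1), 2, 2) else
      matrix(1, 1, 1)
    V <- phi * A %*% R %*% A
    D <- v * X                       # d mu / d beta for the logit link
    W <- t(D) %*% solve(V)
    r <- y - mu
    U <- U + drop(W %*% r)
    I0 <- I0 + W %*% D
    I1 <- I1 + W %*% r %*% t(r) %*% t(W)
  }
  list(U = U, cov_model = solve(I0),
       cov_sandwich = solve(I0) %*% I1 %*% solve(I0))
}

expect_valid_ci <- function(ci, level = 0.90) {
  expect_s3_class(ci, "paired_ci")
  expect_true(is.finite(ci$lower) && is.finite(ci$upper))
  expect_lte(ci$lower, ci$upper)
  expect_gte(ci$lower, -1)
  expect_lte(ci$upper, 1)
  expect_equal(ci$level, level)
}
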