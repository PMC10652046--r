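# Independent oracles and small fixtures used across test files.

# Brute-force normal-equations OLS (independent of the package's QR path).
ols_normal_equations <- function(M, y) {
  drop(solve(t(M) %*% M) %*% (t(M) %*% y))
}

# Adjusted Rand index from the contingency table (direct formula).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Two well-separated spherical blobs in 2D with known labels.
make_blobs <- function(n_per = 30, sep = 8, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(2 * n_per), ncol = 2),
    matrix(rnorm(2 * n_per), ncol = 2) + sep
  )
  list(X = X, labels = rep(1:2, each = n_per))
}

# A small pooled-days averaged design matrix from the screen-like fixture.
fixture_design_matrix <- function(property = "cell_number", seed = 1,
                                  transform = TRUE) {
  ds <- make_screen_fixture(seed = seed)
  avg <- average_replicates(ds$measurements)
  sub <- avg[avg$property == property, , drop = FALSE]
  if (transform) {
    sub$value <- apply_transform(sub$value, default_transforms()[[property]])
  }
  encode_one_hot(sub, response = "value")
}
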