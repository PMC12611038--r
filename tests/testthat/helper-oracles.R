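# Independent oracle implementations used to cross-check the package's
# computations. These are written step-by-step, without reusing any
# package internals, so agreement is a two-route check.

# Step-by-step TOPSIS with explicit loops (benefit criteria only).
oracle_topsis <- function(mat, weights) {
  n <- nrow(mat); m <- ncol(mat)
  r <- matrix(0, n, m)
  for (j in 1:m) {
    denom <- sqrt(sum(mat[, j]^2))
    for (i in 1:n) r[i, j] <- mat[i, j] / denom
  }
  v <- matrix(0, n, m)
  for (j in 1:m) for (i in 1:n) v[i, j] <- r[i, j] * weights[j]
  ideal <- apply(v, 2, max)
  anti <- apply(v, 2, min)
  cc <- numeric(n)
  for (i in 1:n) {
    dp <- sqrt(sum((v[i, ] - ideal)^2))
    dm <- sqrt(sum((v[i, ] - anti)^2))
    cc[i] <- dm / (dp + dm)
  }
  cc
}

# Spreadsheet-style enumeration of the cumulative variance-ratio curve:
# explicit sort, loop over splits, running sums.
oracle_cumvar <- function(values, fqi, m_min = 3) {
  ord <- order(fqi, decreasing = TRUE)
  v <- values[ord]; f <- fqi[ord]
  n <- length(v)
  xs <- c(); ratios <- c()
  for (j in m_min:(n - m_min)) {
    if (f[j] <= f[j + 1]) next  # tie group: not a valid boundary
    top <- v[1:j]; rest <- v[(j + 1):n]
    vr <- var(top) / var(rest)
    xs <- c(xs, f[j]); ratios <- c(ratios, vr)
  }
  data.frame(x = xs, F = 100 * cumsum(ratios) / sum(ratios))
}

# Brute-force pairwise LSD decisions (TRUE = significantly different).
oracle_lsd_pairs <- function(records, trait, treatment = "treatment",
                             alpha = 0.05) {
  tr <- factor(records[[treatment]])
  y <- records[[trait]]
  means <- tapply(y, tr, mean); ns <- tapply(y, tr, length)
  df_err <- length(y) - nlevels(tr)
  mse <- sum(tapply(y, tr, function(z) sum((z - mean(z))^2))) / df_err
  tcrit <- qt(1 - alpha / 2, df_err)
  lv <- levels(tr)
  out <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i == j) next
    lsd <- tcrit * sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    out[i, j] <- abs(means[i] - means[j]) > lsd
  }
  out
}

# A small deterministic quality-record table with known group structure.
make_two_group_records <- function(n_rep = 6, delta = 10, sd = 0.01,
                                   seed = 42) {
  set.seed(seed)
  data.frame(
    treatment = rep(c("A", "B"), each = n_rep),
    value = c(rnorm(n_rep, 0, sd), rnorm(n_rep, delta, sd))
  )
}
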