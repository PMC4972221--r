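# Shared fixtures and independent oracles used across the test files.

tinyParams <- function(...) {
  args <- list(...)
  defaults <- list(n_streams = 4, n_taxa = 15, seed = 11)
  do.call(simParams, utils::modifyList(defaults, args))
}

noiselessParams <- function(...) {
  args <- list(...)
  defaults <- list(n_streams = 4, n_taxa = 15, seed = 11,
                   sigma_si = 0, sigma_spear = 0, sigma_spear_delta = 0,
                   sigma_oligo = 0, dispersion = Inf)
  do.call(simParams, utils::modifyList(defaults, args))
}

# brute-force hierarchical partitioning: enumerate every subset with lm()
# and average the R^2 increments per hierarchy level
bruteForceHierpart <- function(y, X) {
  X <- as.matrix(X)
  k <- ncol(X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  subsets <- lapply(0:(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  vapply(seq_len(k), function(j) {
    inc_by_level <- tapply(
      vapply(subsets, function(s) {
        if (j %in% s) return(NA_real_)
        r2(sort(c(s, j))) - r2(s)
      }, numeric(1)),
      vapply(subsets, length, integer(1)),
      mean, na.rm = TRUE)
    mean(inc_by_level, na.rm = TRUE)
  }, numeric(1))
}

# textbook pseudo-F from squared distances (Anderson's decomposition)
pseudoFOracle <- function(d2, groups) {
  n <- length(groups)
  a <- length(unique(groups))
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- sum(vapply(unique(groups), function(g) {
    i <- which(groups == g)
    sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }, numeric(1)))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# resampling estimate of rarefied richness (mean +- SE)
rarefyBrute <- function(counts, n, B = 10000) {
  pool <- rep(seq_along(counts), counts)
  s <- replicate(B, length(unique(sample(pool, n))))
  c(mean = mean(s), se = stats::sd(s) / sqrt(B))
}
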