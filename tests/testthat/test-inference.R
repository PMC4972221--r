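test_that("hierarchical partitioning obeys its variance identities", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    n <- 30
    X <- matrix(rnorm(n * k), n, k) %*%
      (diag(k) + 0.4 * matrix(runif(k * k), k, k)) # correlated predictors
    y <- X %*% rnorm(k) + rnorm(n)
    hp <- hierPart(y, X)
    eff <- hp@effects
    expect_equal(sum(eff$I), hp@r2_full, tolerance = 1e-10)
    expect_equal(eff$I + eff$J, eff$total, tolerance = 1e-10)
    expect_equal(sum(eff$pct_I), 100, tolerance = 1e-8)
    uni <- vapply(seq_len(k), function(j)
      summary(stats::lm(y ~ X[, j]))$r.squared, numeric(1))
    expect_equal(eff$total, uni, tolerance = 1e-10)
  }
})

test_that("single-predictor partitioning is the univariate R2", {
  set.seed(32)
  x <- rnorm(25)
  y <- 2 * x + rnorm(25)
  hp <- hierPart(y, matrix(x, ncol = 1))
  expect_equal(hp@effects$I, summary(stats::lm(y ~ x))$r.squared,
               tolerance = 1e-12)
  expect_equal(hp@effects$J, 0, tolerance = 1e-12)
})

test_that("orthogonal predictors have no joint effects", {
  set.seed(33)
  X <- qr.Q(qr(scale(matrix(rnorm(40 * 3), 40, 3), scale = FALSE)))
  y <- X %*% c(1, -2, 0.5) + rnorm(40)
  hp <- hierPart(y, X)
  expect_equal(hp@effects$J, rep(0, 3), tolerance = 1e-10)
})

test_that("partitioning matches the subset-enumeration oracle (k = 3)", {
  set.seed(34)
  n <- 30
  z <- rnorm(n)
  X <- cbind(z + rnorm(n), z + rnorm(n), rnorm(n))
  y <- X %*% c(1, 0.5, -1) + rnorm(n)
  hp <- hierPart(y, X)
  expect_equal(hp@effects$I, bruteForceHierpart(y, X), tolerance = 1e-8)
})

test_that("two-predictor partitioning matches commonality analysis", {
  set.seed(35)
  n <- 40
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n), b = z + rnorm(n))
  y <- X %*% c(1, 1) + rnorm(n)
  hp <- hierPart(y, X)
  r2_full <- summary(stats::lm(y ~ X))$r.squared
  r2_1 <- summary(stats::lm(y ~ X[, 1]))$r.squared
  r2_2 <- summary(stats::lm(y ~ X[, 2]))$r.squared
  expect_equal(hp@effects$I[1], (r2_1 + r2_full - r2_2) / 2,
               tolerance = 1e-12)
  expect_equal(hp@effects$I[2], (r2_2 + r2_full - r2_1) / 2,
               tolerance = 1e-12)
})

test_that("hierPart rejects unusable inputs", {
  set.seed(36)
  X <- matrix(rnorm(40), 20, 2)
  expect_error(hierPart(rnorm(19), X), "lengths")
  expect_error(hierPart(rep(1, 20), X), "variance")
  Xs <- cbind(a = X[, 1], b = X[, 1])
  expect_error(hierPart(rnorm(20), Xs), "singular")
  expect_error(hierPart(rnorm(20), matrix(rnorm(20 * 13), 20, 13)), "12")
})

test_that("randomization Z-scores flag a strong driver and are reproducible", {
  set.seed(37)
  n <- 30
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1] + 0.3 * rnorm(n)
  h1 <- hierPartZ(y, X, n_rand = 199, seed = 5)
  h2 <- hierPartZ(y, X, n_rand = 199, seed = 5)
  expect_identical(h1@effects$Z, h2@effects$Z)
  expect_true(h1@effects["x1", "significant"])
  expect_gt(h1@effects["x1", "Z"], 1.65)
  # power: the true driver is flagged in nearly all replicates
  hits <- 0L
  for (r in 1:60) {
    set.seed(r + 100)
    Xr <- matrix(rnorm(n * 4), n, 4)
    yr <- Xr[, 1] + 0.3 * rnorm(n)
    hr <- hierPartZ(yr, Xr, n_rand = 99, seed = r)
    hits <- hits + (hr@effects$Z[1] > 1.65)
  }
  expect_gte(hits, 57) # >= 95% power
})

test_that("partial correlation matches the recursive closed form", {
  set.seed(38)
  n <- 200
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n)
  y <- -0.5 * z + 0.4 * x + rnorm(n)
  expect_equal(partialCorrelation(y, x), stats::cor(y, x))
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  oracle <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(partialCorrelation(y, x, matrix(z)), oracle,
               tolerance = 1e-10)
  # controlling a variable for itself leaves nothing
  expect_lt(abs(partialCorrelation(y, x, cbind(z, x))), 1e-10)
  expect_error(partialCorrelation(y, x, cbind(z, z)), "collinear")
})

test_that("blocked ANOVA equals the balanced mixed model", {
  set.seed(39)
  streams <- rep(paste0("s", 1:8), each = 3)
  loc <- rep(c("U2", "U1", "D"), 8)
  y <- rnorm(8)[as.integer(factor(streams))] +
    c(U2 = 0, U1 = 0.1, D = 0.8)[loc] + 0.3 * rnorm(24)
  ba <- blockedAnova(y, loc, streams)
  lmm <- lmerTest::lmer(y ~ loc + (1 | streams))
  an <- stats::anova(lmm)
  expect_equal(ba$F, an$`F value`[1], tolerance = 1e-6)
  expect_equal(unname(ba$df), c(an$NumDF[1], an$DenDF[1]), tolerance = 1e-6)
  # variance share agrees with the REML variance components under balance
  vc <- as.data.frame(lme4::VarCorr(lmm))
  icc <- 100 * vc$vcov[1] / sum(vc$vcov)
  expect_equal(ba$stream_var_pct, icc, tolerance = 1e-4)
  expect_true(all(ba$tukey$p_adj >= 0 & ba$tukey$p_adj <= 1))
})

test_that("blocked ANOVA handles degenerate and unbalanced inputs", {
  streams <- rep(paste0("s", 1:5), each = 3)
  loc <- rep(c("U2", "U1", "D"), 5)
  # identical within every stream: no location effect at all
  y0 <- as.integer(factor(streams))
  ba0 <- blockedAnova(y0, loc, streams)
  expect_equal(ba0$F, 0)
  expect_equal(ba0$p, 1)
  expect_true(all(ba0$tukey$p_adj == 1))
  # large stream offsets and no location effect: stream soaks the variance
  set.seed(40)
  y1 <- 100 * as.integer(factor(streams)) + rnorm(15)
  ba1 <- blockedAnova(y1, loc, streams)
  expect_gt(ba1$stream_var_pct, 99)
  expect_gt(ba1$p, 0.001) # F near its null expectation
  # a stream missing one location is dropped with a warning
  expect_warning(
    ba2 <- blockedAnova(y1[-1], loc[-1], streams[-1]), "s1")
  expect_equal(ba2$n_streams, 4)
})

test_that("blocked ANOVA is null-calibrated", {
  set.seed(41)
  rej <- 0L
  for (r in 1:300) {
    streams <- rep(paste0("s", 1:6), each = 3)
    loc <- rep(c("U2", "U1", "D"), 6)
    y <- rnorm(6)[as.integer(factor(streams))] + rnorm(18)
    rej <- rej + (blockedAnova(y, loc, streams)$p <= 0.05)
  }
  expect_lte(rej / 300, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 300))
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  # means exactly one pooled SD apart
  x <- c(-1, 1)
  expect_equal(cohensD(x + sqrt(2), x), 1, tolerance = 1e-12)
  expect_equal(cohensD(c(3, 5), c(1, 3)), sqrt(2), tolerance = 1e-12)
  expect_error(cohensD(c(1, 1), c(1, 1)), "zero pooled")
  expect_error(cohensD(1, c(1, 2)), "two values")
})
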