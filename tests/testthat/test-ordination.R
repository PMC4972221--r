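test_that("Hellinger transform gives unit-norm square-root shares", {
  h <- hellingerTransform(matrix(c(1, 0, 3), 1, 3,
                                 dimnames = list("L1", NULL)))
  expect_equal(as.numeric(h), c(0.5, 0, sqrt(0.75)), tolerance = 1e-9)
  se <- simulateStreams(tinyParams())
  H <- hellingerTransform(se)
  expect_equal(unname(rowSums(H^2)), rep(1, nrow(H)), tolerance = 1e-10)
  expect_true(all(H >= 0 & H <= 1))
  # disjoint compositions sit at the maximal distance sqrt(2)
  m <- rbind(a = c(4, 0), b = c(0, 9))
  expect_equal(max(stats::dist(hellingerTransform(m))), sqrt(2),
               tolerance = 1e-12)
  bad <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("ok", "empty"), NULL))
  expect_error(hellingerTransform(bad), "empty")
})

test_that("PCA reports variance fractions and reconstructs the data", {
  x <- cbind(1:10, 2 * (1:10))
  p <- runPCA(x)
  expect_equal(p$var_fraction[1], 1, tolerance = 1e-12)
  set.seed(2)
  X <- matrix(rnorm(80), 20, 4)
  p2 <- runPCA(X)
  rec <- p2$scores %*% t(p2$loadings) +
    matrix(p2$center, 20, 4, byrow = TRUE)
  expect_equal(rec, X, ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(all(diff(p2$var_fraction) <= 1e-12))
  Xc <- cbind(X, constant = 1)
  expect_error(runPCA(Xc, scale = TRUE), "constant")
})

test_that("NMDS embeds planar configurations exactly and reproducibly", {
  set.seed(10)
  cfg <- matrix(rnorm(12), 6, 2)
  d <- stats::dist(cfg)
  fit <- runNMDS(d, k = 2, n_starts = 5, seed = 42)
  expect_lt(fit$stress, 1e-6)
  expect_true(fit$converged)
  # stress-1 is invariant to a uniform dilation of the distances
  se <- simulateStreams(tinyParams())
  dd <- stats::dist(hellingerTransform(se))
  f1 <- runNMDS(dd, n_starts = 5, seed = 7)
  f2 <- runNMDS(dd * 2, n_starts = 5, seed = 7)
  expect_equal(f1$stress, f2$stress, tolerance = 1e-10)
  # same seed, same configuration
  f3 <- runNMDS(dd, n_starts = 5, seed = 7)
  expect_identical(f1$points, f3$points)
  # multi-start never does worse than its own single starts
  singles <- vapply(1:5, function(s)
    runNMDS(dd, n_starts = 1, seed = s)$stress, numeric(1))
  expect_lte(runNMDS(dd, n_starts = 5, seed = 1)$stress, min(singles) + 1e-12)
})

test_that("PERMANOVA matches exact enumeration and flags degeneracy", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  d <- stats::dist(pts)
  groups <- c("a", "a", "b", "b")
  d2 <- as.matrix(d)^2
  combos <- utils::combn(4, 2)
  Fs <- apply(combos, 2, function(i) {
    g <- rep("b", 4); g[i] <- "a"
    pseudoFOracle(d2, g)
  })
  Fobs <- pseudoFOracle(d2, groups)
  res <- suppressMessages(runPERMANOVA(d, groups, exact = TRUE))
  expect_equal(res$F, Fobs, tolerance = 1e-8)
  expect_equal(res$p, mean(Fs >= Fobs), tolerance = 1e-12)

  expect_warning(
    r0 <- runPERMANOVA(stats::dist(matrix(0, 8, 2)),
                       rep(c("a", "b"), each = 4), n_perm = 49, seed = 1),
    "degenerate")
  expect_true(is.na(r0$p))
  expect_error(runPERMANOVA(d, c("a", "a", "a", "b")), "two members")
})

test_that("PCNM eigenvectors are orthogonal, centred sinusoids", {
  n <- 25
  coords <- cbind(seq_len(n), 0)
  pe <- spatialEigenvectors(coords)
  V <- pe$vectors
  expect_lte(ncol(V), n - 1)
  expect_equal(colMeans(V), rep(0, ncol(V)), tolerance = 1e-10,
               ignore_attr = TRUE)
  G <- crossprod(V)
  expect_equal(G[upper.tri(G)], rep(0, sum(upper.tri(G))),
               tolerance = 1e-8)
  # on a transect the leading eigenvectors are sine/cosine waves of
  # increasing frequency
  t <- seq_len(n)
  bestfreq <- vapply(1:3, function(j) {
    cors <- vapply(1:8, function(kk) {
      max(abs(stats::cor(V[, j], cos(pi * kk * (t - 0.5) / n))),
          abs(stats::cor(V[, j], sin(pi * kk * t / (n + 1)))))
    }, numeric(1))
    expect_gt(max(cors), 0.95)
    which.max(cors)
  }, integer(1))
  expect_true(all(diff(bestfreq) > 0))
  expect_error(spatialEigenvectors(matrix(1, 5, 2)), "distinct")
})

test_that("partial RDA reduces to plain RDA without conditioning", {
  set.seed(3)
  Y <- matrix(rnorm(60), 12, 5)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  pr <- partialRDA(Y, X, n_perm = 0)
  ref <- vegan::rda(Y, X)
  expect_equal(unname(pr$eigenvalues), unname(ref$CCA$eig),
               tolerance = 1e-10)
  expect_equal(pr$r2, vegan::RsquareAdj(ref)$r.squared, tolerance = 1e-10)
  # constrained + unconstrained eigenvalues exhaust the total variance
  m <- pr$model
  expect_equal(sum(m$CCA$eig) + sum(m$CA$eig), m$tot.chi, tolerance = 1e-10)
})

test_that("partial RDA sees exact fits and rejects rank deficiency", {
  set.seed(4)
  X <- matrix(rnorm(30), 15, 2)
  Y <- X %*% matrix(c(1, 2, 0, 1, -1, 0.5), 2, 3)
  pr <- suppressMessages(partialRDA(Y, X, n_perm = 0))
  expect_equal(pr$constrained_fraction, 1, tolerance = 1e-10)
  Xdup <- cbind(x1 = X[, 1], x2 = X[, 2], x1copy = X[, 1])
  expect_error(partialRDA(Y, Xdup, n_perm = 0), "x1")
})

test_that("partial RDA is null-calibrated when X is unrelated to Y", {
  adj <- p <- numeric(60)
  for (i in seq_len(60)) {
    set.seed(i)
    Z <- matrix(rnorm(40), 20, 2)
    Y <- Z %*% matrix(rnorm(8), 2, 4) + 0.05 * matrix(rnorm(80), 20, 4)
    X <- matrix(rnorm(20), 20, 1)
    pr <- partialRDA(Y, X, Z, n_perm = 99, seed = i)
    adj[i] <- pr$adj_r2
    p[i] <- pr$p
  }
  expect_lt(abs(mean(adj)), 0.05)
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("variation partitioning obeys inclusion-exclusion identities", {
  set.seed(6)
  n <- 30
  X1 <- matrix(rnorm(n), n, 1)
  X2 <- matrix(stats::resid(stats::lm(rnorm(n) ~ X1)), n, 1)
  Y <- cbind(X1 %*% t(rep(1, 3)) + 0.2 * matrix(rnorm(3 * n), n),
             X2 %*% t(rep(1, 2)) + 0.2 * matrix(rnorm(2 * n), n))
  vp <- variationPartitioning(Y, list(a = X1, b = X2), n_perm = 0)
  fr <- vp$fractions # rows: unique a, unique b, shared, residual
  expect_equal(sum(fr$adj_r2), 1, tolerance = 1e-10)
  expect_lt(abs(fr$adj_r2[3]), 0.05)
  # duplicating a block moves everything into the shared fraction
  vp2 <- suppressWarnings(
    variationPartitioning(Y, list(a = X1, b = X1), n_perm = 0))
  fr2 <- vp2$fractions
  expect_true(all(abs(fr2$adj_r2[1:2]) < 1e-10))
  expect_gt(fr2$adj_r2[3], 0.3)
  expect_error(variationPartitioning(Y, list(X1, X2, X1, X2)), "2 or 3")
})

test_that("forward selection finds true drivers and honors alpha = 1", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  Y <- X[, 1] %*% t(rep(1, 3)) + 0.3 * matrix(rnorm(3 * n), n)
  fs <- forwardSelect(Y, X, alpha = 0.05, n_perm = 199, seed = 1)
  expect_identical(fs$selected[1], "x1")
  fs_all <- forwardSelect(Y, X, alpha = 1, n_perm = 19, seed = 1)
  expect_setequal(fs_all$selected, colnames(X))
  # entry order follows the gain
  expect_identical(fs_all$selected[1], "x1")
  # double stopping on the adjusted-R2 ceiling
  fs_stop <- forwardSelect(Y, X, alpha = 1, n_perm = 19,
                           adj_r2_stop = 0.1, seed = 1)
  expect_lt(length(fs_stop$selected), 4)
})

test_that("collinearity filter retains by priority order", {
  set.seed(9)
  x1 <- rnorm(50)
  X <- cbind(a = x1, b = x1, c = rnorm(50))
  cf <- collinearityFilter(X, r_max = 0.6)
  expect_identical(cf$retained, c("a", "c"))
  expect_identical(cf$dropped$column, "b")
  # orthogonal columns all retained
  Xo <- qr.Q(qr(matrix(rnorm(50 * 3), 50, 3)))
  colnames(Xo) <- c("p", "q", "r")
  expect_identical(collinearityFilter(Xo)$retained, c("p", "q", "r"))
  # r(1,2) = 0.9 drops 2; r(1,3) = 0.1 keeps 3
  z <- rnorm(200)
  X3 <- cbind(v1 = z, v2 = 0.9 * z + sqrt(1 - 0.81) * rnorm(200),
              v3 = 0.1 * z + sqrt(1 - 0.01) * rnorm(200))
  expect_identical(collinearityFilter(X3, 0.6)$retained, c("v1", "v3"))
})
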