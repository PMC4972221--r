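traits3 <- data.frame(
  saprobic = c(1.8, 2.8, 3.5), weight = c(4L, 2L, 3L),
  spear = c(TRUE, FALSE, FALSE), ept = c(TRUE, FALSE, FALSE),
  oligochaete = c(FALSE, FALSE, TRUE))

test_that("taxa richness counts positive taxa and rejects empty rows", {
  expect_equal(taxaRichness(c(5, 0, 2)), 2)
  expect_equal(taxaRichness(c(0, 7, 0)), 1)
  expect_error(taxaRichness(c(0, 0)), "zero")
  expect_error(taxaRichness(c(-1, 2)), "negative")
})

test_that("Hurlbert rarefaction matches exact hypergeometric arithmetic", {
  expect_equal(rarefiedRichness(c(5, 5), 2), 14 / 9, tolerance = 1e-12)
  x <- c(7, 3, 1, 9)
  expect_equal(rarefiedRichness(x, sum(x)), taxaRichness(x))
  expect_equal(rarefiedRichness(x, 1), 1, tolerance = 1e-12)
  expect_error(rarefiedRichness(x, sum(x) + 1), "20")
  # agrees with the vegan implementation
  expect_equal(rarefiedRichness(x, 5), as.numeric(vegan::rarefy(x, 5)),
               tolerance = 1e-10)
})

test_that("rarefaction equals the resampling mean within 3 SE", {
  set.seed(99)
  fixtures <- list(c(5, 5), c(10, 3, 1), c(20, 1, 1, 1), c(4, 4, 4),
                   c(50, 10, 5, 2, 1))
  for (x in fixtures) {
    n <- max(2, floor(sum(x) / 2))
    bf <- rarefyBrute(x, n, B = 10000)
    expect_lt(abs(rarefiedRichness(x, n) - bf["mean"]), 3 * bf["se"] + 1e-9)
  }
})

test_that("Pielou evenness behaves at uniformity, dominance and by hand", {
  expect_equal(pielouEvenness(c(2, 2, 2, 2)), 1, tolerance = 1e-12)
  expect_lt(pielouEvenness(c(1000, 1)), 0.02)
  # hand entropy: p = (0.8, 0.2), H' = 0.500402, J = H'/ln 2
  expect_equal(pielouEvenness(c(8, 2)), 0.5004024 / log(2), tolerance = 1e-6)
  expect_warning(j <- pielouEvenness(c(5, 0)), "undefined")
  expect_true(is.na(j))
})

test_that("Fisher's alpha solves its defining identity", {
  a <- fisherAlpha(20, 100)
  # independent bisection oracle
  f <- function(a) a * log(1 + 100 / a) - 20
  lo <- 1e-6; hi <- 100
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  expect_equal(a, (lo + hi) / 2, tolerance = 1e-8)
  expect_equal(a, 7.52, tolerance = 0.01)
  expect_equal(a, unname(vegan::fisher.alpha(c(rep(1, 19), 81))),
               tolerance = 1e-4)
  # defining identity across a grid, and monotonicity in N
  for (S in c(2, 5, 10, 20, 50, 100)) {
    prev <- Inf
    for (N in unique(c(S + 1, 10 * S, 1e5))) {
      al <- fisherAlpha(S, N)
      expect_lt(abs(al * log(1 + N / al) - S), 1e-8)
      expect_lt(al, prev)
      prev <- al
    }
  }
  expect_error(fisherAlpha(10, 10), "diverges")
})

test_that("Berger-Parker dominance is the top relative abundance", {
  expect_equal(bergerParker(c(8, 2)), 0.8)
  expect_equal(bergerParker(rep(3, 4)), 0.25)
  expect_equal(bergerParker(c(0, 9)), 1)
  expect_error(bergerParker(c(0, 0)), "zero")
})

test_that("Saprobic Index is the g-weighted abundance mean of s", {
  expect_equal(saprobicIndex(c(0, 5, 0), traits3), 2.8)
  tr <- data.frame(saprobic = c(1.8, 2.8), weight = c(4L, 2L),
                   spear = FALSE, ept = FALSE, oligochaete = FALSE)
  expect_equal(saprobicIndex(c(10, 5), tr), 2.0, tolerance = 1e-12)
  expect_equal(saprobicIndex(c(20, 10), tr), 2.0, tolerance = 1e-12)
  # unscored taxa are excluded, not imputed
  tr$saprobic[2] <- NA
  expect_equal(saprobicIndex(c(10, 5), tr), 1.8)
  tr$saprobic <- NA
  expect_warning(si <- saprobicIndex(c(10, 5), tr), "undefined")
  expect_true(is.na(si))
  # abundance-class hook
  expect_equal(saprobicIndex(c(10, 5), traits3[1:2, ],
                             abundance_class = function(x) pmin(x, 1)),
               (1.8 * 4 + 2.8 * 2) / 6, tolerance = 1e-12)
})

test_that("SPEAR index uses log-damped weights and stays in [0, 100]", {
  expect_equal(spearIndex(c(5, 0, 0), traits3), 100)
  expect_equal(spearIndex(c(0, 5, 3), traits3), 0)
  expect_equal(spearIndex(c(7, 7, 0), traits3), 50, tolerance = 1e-12)
  w <- log10(4 * c(10, 3, 2) + 1)
  expect_equal(spearIndex(c(10, 3, 2), traits3), 100 * w[1] / sum(w),
               tolerance = 1e-12)
})

test_that("EPT metrics and oligochaete-excluded variants are arithmetic", {
  tr <- data.frame(saprobic = 2, weight = 3L,
                   spear = c(FALSE, FALSE), ept = c(FALSE, FALSE),
                   oligochaete = c(FALSE, TRUE))
  m <- eptMetrics(c(12, 8), tr)
  expect_equal(m$ept_richness, 0)
  expect_equal(m$pct_ept, 0)
  expect_equal(m$total_abundance, 20)
  expect_equal(m$abundance_minus_oligo, 12)

  tr2 <- data.frame(saprobic = 2, weight = 3L, spear = FALSE,
                    ept = c(TRUE, FALSE, FALSE),
                    oligochaete = c(FALSE, TRUE, FALSE))
  m2 <- eptMetrics(c(10, 10, 0), tr2)
  expect_equal(m2$pct_ept, 50)
  expect_equal(m2$pct_ept_minus_oligo, 100)

  tr3 <- data.frame(saprobic = 2, weight = 3L, spear = FALSE,
                    ept = TRUE, oligochaete = FALSE)
  m3 <- eptMetrics(c(4, 6), rbind(tr3, tr3))
  expect_equal(m3$pct_ept, 100)
  expect_equal(m3$pct_ept_minus_oligo, 100)
})

test_that("descriptors are invariant to taxon order and count scaling", {
  set.seed(7)
  x <- c(rpois(10, 20), 0, 3)
  tr <- data.frame(saprobic = runif(12, 1, 4),
                   weight = sample(1:5, 12, TRUE),
                   spear = sample(c(TRUE, FALSE), 12, TRUE),
                   ept = sample(c(TRUE, FALSE), 12, TRUE),
                   oligochaete = sample(c(TRUE, FALSE), 12, TRUE))
  o <- sample(12)
  expect_equal(saprobicIndex(x[o], tr[o, ]), saprobicIndex(x, tr))
  expect_equal(spearIndex(x[o], tr[o, ]), spearIndex(x, tr))
  expect_equal(pielouEvenness(x[o]), pielouEvenness(x))
  expect_equal(bergerParker(x[o]), bergerParker(x))
  expect_equal(saprobicIndex(3 * x, tr), saprobicIndex(x, tr))
  expect_equal(pielouEvenness(3 * x), pielouEvenness(x))
  expect_equal(bergerParker(3 * x), bergerParker(x))
  # bounds
  s_present <- tr$saprobic[x > 0]
  si <- saprobicIndex(x, tr)
  expect_gte(si, min(s_present)); expect_lte(si, max(s_present))
  expect_gte(spearIndex(x, tr), 0); expect_lte(spearIndex(x, tr), 100)
})

test_that("descriptorMatrix assembles a complete, order-invariant table", {
  se <- simulateStreams(tinyParams())
  d <- descriptorMatrix(se)
  expect_equal(dim(d), c(12, 12))
  expect_false(anyNA(d))
  expect_true(all(d$evenness >= 0 & d$evenness <= 1))
  expect_true(all(d$saprobic >= 1 & d$saprobic <= 4))
  ab <- abundanceTable(se)
  o <- sample(ncol(ab))
  d2 <- descriptorMatrix(ab[, o], traits = traitTable(se)[o, ])
  expect_equal(d2, d)
  # identical locations have zero between-location variance
  ab3 <- ab[rep(1, 3), ]
  rownames(ab3) <- c("a", "b", "c")
  d3 <- descriptorMatrix(ab3, traits = traitTable(se))
  expect_true(all(apply(d3, 2, stats::sd) == 0))
})
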