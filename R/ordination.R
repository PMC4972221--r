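# Multivariate engine: Hellinger transform, PCA, NMDS, PERMANOVA, PCNM,
# partial RDA, variation partitioning, forward selection, collinearity
# pre-filter. Ordinations are delegated to vegan; selection and filtering
# are implemented here.

#' Hellinger transform
#'
#' Square root of within-location relative abundances,
#' `y_ij = sqrt(x_ij / sum_j x_ij)`. Euclidean distances on the transformed
#' matrix are appropriate for species-count data; every row has unit sum of
#' squares.
#'
#' @param x locations-by-taxa abundance matrix, or a [StreamExperiment].
#' @return matrix of the same shape.
#' @export
hellingerTransform <- function(x) {
  if (is(x, "StreamExperiment")) x <- abundanceTable(x)
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- rowSums(x)
  if (any(tot == 0)) {
    stop("zero-total location(s): ",
         paste(rownames(x)[tot == 0], collapse = ", "), call. = FALSE)
  }
  out <- vegan::decostand(x, method = "hellinger")
  stopifnot(max(abs(rowSums(out^2) - 1)) < 1e-8)
  out
}

#' Principal components analysis
#'
#' Thin wrapper around [stats::prcomp()] returning scores, loadings and
#' variance fractions in one list. With `scale = TRUE` the decomposition is
#' of the correlation matrix; constant columns are then an error.
#'
#' @param x numeric matrix, observations in rows.
#' @param center,scale passed to `prcomp`.
#' @return list with `scores`, `loadings`, `sdev`, `var_fraction`, `center`.
#' @export
runPCA <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two observations", call. = FALSE)
  if (anyNA(x)) stop("missing values in PCA input", call. = FALSE)
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) with scale = TRUE: ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  p <- stats::prcomp(x, center = center, scale. = scale)
  list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
       var_fraction = p$sdev^2 / sum(p$sdev^2),
       center = p$center, scale = p$scale)
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via [vegan::metaMDS()]/[vegan::monoMDS()] (monotone
#' regression with multiple random starts), on a distance matrix or on an
#' abundance matrix (then Hellinger-transformed Euclidean distances, the
#' configuration community ecologists pair with count data). The returned
#' configuration is centred and rotated to principal axes.
#'
#' @param x a `dist`, a symmetric distance matrix, or a locations-by-taxa
#'   abundance matrix.
#' @param k number of dimensions.
#' @param n_starts random starts; the best (lowest-stress) solution is kept.
#' @param max_iter maximum iterations per start.
#' @param tol stress convergence ratio tolerance.
#' @param seed RNG seed for the random starts.
#' @return list with `points` (n x k scores), `stress` (stress-1, 0-1
#'   scale), `converged`.
#' @export
runNMDS <- function(x, k = 2, n_starts = 20, max_iter = 200,
                    tol = 1e-7, seed = NULL) {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    x <- as.matrix(x)
    if (isSymmetric(unname(x)) && all(abs(diag(x)) < 1e-12)) {
      d <- stats::as.dist(x)
    } else {
      d <- stats::dist(hellingerTransform(x))
    }
  }
  n <- attr(d, "Size")
  fit <- withSeed(seed, {
    best <- NULL
    for (s in seq_len(max(1, n_starts))) {
      # first start from the metric (PCoA) configuration, then random
      init <- if (s == 1) {
        suppressWarnings(stats::cmdscale(d, k = k))
      } else {
        matrix(stats::runif(n * k, -1, 1), n, k)
      }
      m <- suppressWarnings(
        vegan::monoMDS(d, y = init, k = k, model = "global",
                       maxit = max_iter, smin = 1e-12, sfgrmin = 1e-12,
                       sratmax = 1 - tol))
      if (is.null(best) || m$stress < best$stress) best <- m
    }
    best
  })
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  rn <- rownames(fit$points)
  pts <- pts %*% svd(pts)$v  # principal-axis rotation
  dimnames(pts) <- list(rn, paste0("NMDS", seq_len(k)))
  # converged on the stress / stress-ratio / gradient criterion, or the
  # configuration is an (effectively) exact embedding; an iteration-limit
  # stop is flagged through the returned field rather than a condition
  conv <- isTRUE(fit$icause %in% 2:4) || fit$stress < 1e-8
  list(points = pts, stress = fit$stress, converged = conv,
       stress_type = "stress-1", engine = fit)
}

#' PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's pseudo-F), via [vegan::adonis2()]. The p-value uses the
#' `(1 + count) / (1 + n_perm)` estimator.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param groups factor of group labels, one per observation.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @param strata optional blocking factor: permutations are then restricted
#'   to within-stratum exchanges.
#' @param exact if `TRUE`, enumerate all distinct permutations (tiny
#'   designs only).
#' @return list with `F`, `R2`, `p`, `df`, `n_perm`.
#' @export
runPERMANOVA <- function(d, groups, n_perm = 999, seed = NULL,
                         strata = NULL, exact = FALSE) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least two members", call. = FALSE)
  }
  if (n_perm < 1 && !exact) stop("'n_perm' must be >= 1", call. = FALSE)
  ctrl <- if (exact) {
    permute::how(complete = TRUE, maxperm = 1e6, minperm = 2)
  } else if (!is.null(strata)) {
    permute::how(blocks = factor(strata), nperm = n_perm)
  } else {
    permute::how(nperm = n_perm)
  }
  dat <- data.frame(groups = groups)
  res <- withSeed(seed, vegan::adonis2(d ~ groups, data = dat,
                                       permutations = ctrl))
  out <- list(F = res$F[1], R2 = res$R2[1], p = res$`Pr(>F)`[1],
              df = c(res$Df[1], res$Df[2]),
              n_perm = if (exact) attr(res, "control")$nperm else n_perm)
  if (!is.finite(out$F)) {
    warning("pseudo-F undefined (degenerate distances)")
    out$p <- NA_real_
  }
  out
}

#' PCNM spatial eigenvectors
#'
#' Principal Coordinates of Neighbour Matrices: eigenvector decomposition
#' of the geographic distance matrix truncated at a threshold (default: the
#' longest edge of the minimum spanning tree), with beyond-threshold
#' distances replaced by four times the threshold. Eigenvectors with
#' positive eigenvalues provide orthogonal spatial predictors, ordered from
#' broad to fine scale. Backed by [vegan::pcnm()].
#'
#' @param coords two-column matrix of planar coordinates.
#' @param truncation optional truncation distance.
#' @return list with `vectors` (n x m), `values`, `threshold`.
#' @export
spatialEigenvectors <- function(coords, truncation = NULL) {
  coords <- as.matrix(coords)
  if (nrow(unique(coords)) < 3) {
    stop("need at least three distinct points", call. = FALSE)
  }
  d <- stats::dist(coords)
  if (all(d == 0)) stop("all points identical", call. = FALSE)
  p <- if (is.null(truncation)) vegan::pcnm(d) else
    vegan::pcnm(d, threshold = truncation)
  v <- as.matrix(vegan::scores(p))
  rownames(v) <- rownames(coords)
  list(vectors = v, values = p$values[p$values > 0], threshold = p$threshold)
}

#' Partial redundancy analysis
#'
#' Constrained ordination of `y` on predictors `x` after removing
#' (conditioning on) the variation explained by `z`, via [vegan::rda()].
#' Reports constrained-axis site scores, eigenvalues, the constrained
#' variance fraction, Ezekiel-adjusted R-squared ([vegan::RsquareAdj()])
#' and, when `n_perm > 0`, an overall permutation test (residual
#' permutation, [vegan::anova.cca()]).
#'
#' @param y response matrix (typically Hellinger-transformed abundances).
#' @param x predictor matrix or data.frame.
#' @param z optional conditioning matrix (e.g. PCNM spatial eigenvectors).
#' @param n_perm permutations for the overall test; 0 skips the test.
#' @param seed RNG seed for the test.
#' @return list with `site_scores`, `eigenvalues`, `constrained_fraction`,
#'   `r2`, `adj_r2`, `p`, and the underlying `model`.
#' @export
partialRDA <- function(y, x, z = NULL, n_perm = 999, seed = NULL) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  if (nrow(y) != nrow(x)) stop("rows of 'y' and 'x' differ", call. = FALSE)
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (nrow(z) != nrow(y)) stop("rows of 'y' and 'z' differ", call. = FALSE)
    xr <- stats::resid(stats::lm.fit(cbind(1, z), x))
  } else {
    xr <- scale(x, center = TRUE, scale = FALSE)
  }
  qr_x <- qr(xr)
  if (qr_x$rank < ncol(x)) {
    drop_cols <- setdiff(seq_len(ncol(x)), qr_x$pivot[seq_len(qr_x$rank)])
    stop("rank-deficient predictors after conditioning: ",
         paste(colnames(x)[drop_cols], collapse = ", "), call. = FALSE)
  }
  mod <- if (is.null(z)) vegan::rda(y, x) else vegan::rda(y, x, z)
  ev <- mod$CCA$eig
  n_ax <- length(ev)
  sc <- vegan::scores(mod, display = "sites",
                      choices = seq_len(n_ax))
  colnames(sc) <- paste0("RDA", seq_len(ncol(sc)))
  r2a <- vegan::RsquareAdj(mod)
  p <- NA_real_
  if (n_perm > 0) {
    an <- withSeed(seed, vegan::anova.cca(mod, permutations = n_perm))
    p <- an$`Pr(>F)`[1]
  }
  tot <- mod$tot.chi - if (!is.null(mod$pCCA)) mod$pCCA$tot.chi else 0
  list(site_scores = sc, eigenvalues = ev,
       constrained_fraction = sum(ev) / tot,
       r2 = r2a$r.squared, adj_r2 = r2a$adj.r.squared, p = p, model = mod)
}

#' Variation partitioning
#'
#' Partitions the adjusted explained variance of `y` among two or three
#' predictor blocks by inclusion-exclusion over RDAs of all block unions
#' ([vegan::varpart()]). Negative shared fractions are reported as
#' computed; a truncated (floored at zero) view is included for display.
#' Unique (testable) fractions are permutation-tested through partial RDA.
#'
#' @param y response matrix.
#' @param blocks named list of 2 or 3 predictor matrices/data.frames.
#' @param n_perm permutations for the unique-fraction tests; 0 skips them.
#' @param seed RNG seed.
#' @return list with `fractions` (data.frame: adjusted R2 per individual
#'   fraction), `fractions_truncated`, `tests` (per-block unique-fraction
#'   F and p), `varpart` (the vegan object).
#' @export
variationPartitioning <- function(y, blocks, n_perm = 999, seed = NULL) {
  if (!is.list(blocks) || length(blocks) < 2 || length(blocks) > 3) {
    stop("'blocks' must be a list of 2 or 3 predictor blocks",
         call. = FALSE)
  }
  if (is.null(names(blocks))) names(blocks) <- paste0("X", seq_along(blocks))
  blocks <- lapply(blocks, as.matrix)
  y <- as.matrix(y)
  # call with symbols so vegan can deparse its call cleanly
  ev <- new.env(parent = environment())
  assign(".Y", y, envir = ev)
  bsyms <- lapply(seq_along(blocks), function(i) {
    nm <- paste0(".X", i)
    assign(nm, blocks[[i]], envir = ev)
    as.name(nm)
  })
  vp <- eval(as.call(c(quote(vegan::varpart), as.name(".Y"), bsyms)), ev)
  ind <- vp$part$indfract
  fr <- data.frame(fraction = rownames(ind), adj_r2 = ind$Adj.R.square,
                   row.names = NULL)
  fr_tr <- fr
  fr_tr$adj_r2 <- pmax(fr_tr$adj_r2, 0)
  tests <- NULL
  if (n_perm > 0) {
    tests <- do.call(rbind, lapply(seq_along(blocks), function(i) {
      others <- do.call(cbind, blocks[-i])
      mod <- vegan::rda(y, blocks[[i]], others)
      an <- withSeed(if (is.null(seed)) NULL else seed + i,
                     vegan::anova.cca(mod, permutations = n_perm))
      data.frame(block = names(blocks)[i], F = an$F[1],
                 p = an$`Pr(>F)`[1], row.names = NULL)
    }))
  }
  list(fractions = fr, fractions_truncated = fr_tr, tests = tests,
       varpart = vp)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Forward selection of constraining variables
#'
#' Greedy forward selection for (multivariate) redundancy analysis: at each
#' step the candidate with the largest adjusted-R-squared gain is
#' considered, and its significance assessed by permutation of the
#' reduced-model residuals against the null distribution of the *best*
#' gain over all remaining candidates (a selection-aware test, which keeps
#' the procedure calibrated under a global null). Selection stops when the
#' best candidate's p-value exceeds `alpha`, or when the cumulative
#' adjusted R-squared exceeds `adj_r2_stop` (double-stopping).
#'
#' @param y response matrix or vector.
#' @param x candidate predictor matrix.
#' @param alpha significance threshold for entry.
#' @param n_perm permutations per step.
#' @param adj_r2_stop optional ceiling: stop once cumulative adjusted
#'   R-squared of the selected set exceeds it (typically the full model's).
#' @param seed RNG seed.
#' @return list with `selected` (column names in entry order), `trace`
#'   (data.frame: candidate, gain, cumulative adjusted R2, p per step).
#' @export
forwardSelect <- function(y, x, alpha = 0.05, n_perm = 1000,
                          adj_r2_stop = NULL, seed = NULL) {
  y <- as.matrix(y)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(y)
  if (nrow(x) != n) stop("rows of 'y' and 'x' differ", call. = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  tot_ss <- sum(yc^2)
  if (tot_ss == 0) stop("'y' has no variance", call. = FALSE)

  withSeed(seed, {
    selected <- integer(0)
    trace <- NULL
    qbasis <- matrix(0, n, 0) # orthonormal basis of selected predictors
    yres <- yc
    repeat {
      remaining <- setdiff(seq_len(ncol(x)), selected)
      if (!length(remaining)) break
      # orthonormalize candidates against the selected set
      xc <- scale(x[, remaining, drop = FALSE], center = TRUE, scale = FALSE)
      if (ncol(qbasis)) xc <- xc - qbasis %*% crossprod(qbasis, xc)
      norms <- sqrt(colSums(xc^2))
      usable <- norms > 1e-10 * sqrt(n)
      if (!any(usable)) break
      qcand <- sweep(xc[, usable, drop = FALSE], 2, norms[usable], "/")
      gains <- rowSums(crossprod(qcand, yres)^2) / tot_ss
      best <- which.max(gains)
      # null distribution of the best gain under permuted residuals
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        yp <- yres[sample.int(n), , drop = FALSE]
        if (max(rowSums(crossprod(qcand, yp)^2)) / tot_ss >= gains[best]) {
          exceed <- exceed + 1L
        }
      }
      p <- (1 + exceed) / (1 + n_perm)
      sel_col <- remaining[usable][best]
      r2_cum <- 1 - sum((yres - qcand[, best, drop = FALSE] %*%
                           crossprod(qcand[, best, drop = FALSE], yres))^2) /
        tot_ss
      adj_cum <- adjustedR2(r2_cum, n, length(selected) + 1L)
      step <- data.frame(candidate = colnames(x)[sel_col],
                         gain = gains[best], cum_adj_r2 = adj_cum, p = p,
                         row.names = NULL)
      if (p > alpha) {
        trace <- rbind(trace, transform(step, entered = FALSE))
        break
      }
      if (!is.null(adj_r2_stop) && !is.na(adj_cum) &&
          adj_cum > adj_r2_stop) {
        trace <- rbind(trace, transform(step, entered = FALSE))
        break
      }
      trace <- rbind(trace, transform(step, entered = TRUE))
      selected <- c(selected, sel_col)
      qnew <- qcand[, best, drop = FALSE]
      qbasis <- cbind(qbasis, qnew)
      yres <- yres - qnew %*% crossprod(qnew, yres)
    }
    list(selected = colnames(x)[selected], trace = trace)
  })
}

#' Collinearity pre-filter
#'
#' Greedy retention in the given priority order: a column is dropped when
#' its absolute Pearson correlation with an already-retained column reaches
#' `r_max`. Used to thin predictor sets before constrained ordination.
#'
#' @param x predictor matrix or data.frame.
#' @param r_max correlation threshold (columns with `|r| >= r_max` against
#'   a retained column are removed).
#' @return list with `retained` (column names), `dropped` (data.frame:
#'   column, against, r).
#' @export
collinearityFilter <- function(x, r_max = 0.6) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- integer(0)
  dropped <- NULL
  for (j in seq_len(ncol(x))) {
    if (!length(keep)) {
      keep <- j
      next
    }
    r <- suppressWarnings(stats::cor(x[, j], x[, keep, drop = FALSE]))
    r[is.na(r)] <- 0
    if (any(abs(r) >= r_max)) {
      k <- keep[which.max(abs(r))]
      dropped <- rbind(dropped, data.frame(
        column = colnames(x)[j], against = colnames(x)[k],
        r = r[which.max(abs(r))], row.names = NULL))
    } else {
      keep <- c(keep, j)
    }
  }
  list(retained = colnames(x)[keep], dropped = dropped)
}
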