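# Hypothesis-testing layer: hierarchical partitioning with randomization
# Z-scores, partial correlations, stream-blocked ANOVA with Tukey
# contrasts and variance components, and Cohen's d.

# Precompute everything reusable across responses/randomizations for
# all-subsets regression on a fixed predictor matrix: centred X, subset
# normal-equation inverses, and the increment bookkeeping of the
# Chevan-Sutherland averaging.
.hp_prepare <- function(X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k < 1) stop("need at least one predictor", call. = FALSE)
  if (k > 12) stop("more than 12 predictors (2^k model fits)", call. = FALSE)
  if (anyNA(X)) stop("missing values in predictors", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc)
  n_masks <- bitwShiftL(1L, k) - 1L
  idx_of <- vector("list", n_masks)
  Minv <- vector("list", n_masks)
  sizes <- integer(n_masks)
  for (m in seq_len(n_masks)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    idx_of[[m]] <- idx
    sizes[m] <- length(idx)
    Minv[[m]] <- tryCatch(solve(C[idx, idx, drop = FALSE]),
      error = function(e) {
        stop("singular subset fit for predictors: ",
             paste(colnames(X)[idx], collapse = ", "), call. = FALSE)
      })
  }
  # increment bookkeeping: for predictor j, pairs (S, S+j) with level
  # weights 1 / (k * choose(k-1, |S|))
  inc <- lapply(seq_len(k), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    wo <- (0:n_masks)[bitwAnd(0:n_masks, bit) == 0L]
    wi <- wo + bit
    lev <- integer(length(wo))
    lev[wo > 0L] <- sizes[wo[wo > 0L]]
    w <- 1 / (k * choose(k - 1, lev))
    list(wo = wo, wi = wi, w = w)
  })
  list(Xc = Xc, k = k, names = colnames(X), n = nrow(X),
       Minv = Minv, idx_of = idx_of, sizes = sizes, inc = inc)
}

# R^2 of every non-empty subset model, indexed by bitmask.
.hp_r2 <- function(prep, v, ssy) {
  vapply(seq_along(prep$Minv), function(m) {
    vs <- v[prep$idx_of[[m]]]
    sum(vs * (prep$Minv[[m]] %*% vs)) / ssy
  }, numeric(1))
}

# independent effects from the subset R^2 vector
.hp_indep <- function(prep, r2) {
  r2e <- c(0, r2) # prepend empty model, shift masks by one
  vapply(prep$inc, function(b) {
    sum(b$w * (r2e[b$wi + 1L] - r2e[b$wo + 1L]))
  }, numeric(1))
}

#' Hierarchical partitioning of regression variance
#'
#' Fits all `2^k` ordinary-least-squares subsets of the predictors and
#' averages the R-squared increments of each predictor over all hierarchy
#' levels (Chevan-Sutherland averaging), yielding its independent effect
#' `I`. The joint effect is `J = R2_univariate - I`. Two identities hold
#' to numerical precision and are asserted on every call:
#' `sum(I) = R2_full` and `I_j + J_j = R2_univariate_j`.
#'
#' @param y numeric response vector.
#' @param X predictor matrix or data.frame (at most 12 columns).
#' @return a \linkS4class{HierPartResult}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- X[, 1] + rnorm(20)
#' hierPart(y, X)
#' @export
hierPart <- function(y, X) {
  prep <- .hp_prepare(X)
  y <- as.numeric(y)
  if (length(y) != prep$n) stop("lengths of 'y' and 'X' differ",
                                call. = FALSE)
  if (anyNA(y)) stop("missing values in 'y'", call. = FALSE)
  if (prep$n <= prep$k + 1) stop("need n > k + 1 observations",
                                 call. = FALSE)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy == 0) stop("'y' has no variance", call. = FALSE)
  r2 <- .hp_r2(prep, crossprod(prep$Xc, yc), ssy)
  I <- .hp_indep(prep, r2)
  uni <- r2[bitwShiftL(1L, seq_len(prep$k) - 1L)]
  J <- uni - I
  r2_full <- r2[length(r2)]
  stopifnot(abs(sum(I) - r2_full) < 1e-10,
            all(abs(I + J - uni) < 1e-10))
  eff <- data.frame(I = I, J = J, total = uni,
                    pct_I = 100 * I / sum(I),
                    row.names = prep$names)
  new("HierPartResult", effects = eff, r2_full = r2_full,
      n_randomizations = 0L)
}

#' Hierarchical partitioning with randomization Z-scores
#'
#' As [hierPart()], plus a randomization test: the response is permuted
#' `n_rand` times and the independent effects recomputed; each predictor's
#' Z-score is `(I_obs - mean(I_rand)) / sd(I_rand)`, significant at the
#' upper 95% confidence limit (Z > 1.65). Permuting the response preserves
#' the predictor correlation structure, which is the relevant null.
#'
#' @param y numeric response vector.
#' @param X predictor matrix or data.frame.
#' @param n_rand number of randomizations.
#' @param seed RNG seed.
#' @return a \linkS4class{HierPartResult} with `Z` and `significant`
#'   columns.
#' @export
hierPartZ <- function(y, X, n_rand = 1000, seed = NULL) {
  obs <- hierPart(y, X)
  prep <- .hp_prepare(X)
  yc <- as.numeric(y) - mean(as.numeric(y))
  ssy <- sum(yc^2)
  Irand <- withSeed(seed, {
    t(vapply(seq_len(n_rand), function(r) {
      yp <- yc[sample.int(length(yc))]
      .hp_indep(prep, .hp_r2(prep, crossprod(prep$Xc, yp), ssy))
    }, numeric(prep$k)))
  })
  mu <- colMeans(Irand)
  sdv <- apply(Irand, 2, stats::sd)
  Z <- (obs@effects$I - mu) / sdv
  if (any(sdv == 0)) {
    warning("zero randomization spread: Z undefined for some predictors")
    Z[sdv == 0] <- NA_real_
  }
  eff <- obs@effects
  eff$Z <- Z
  eff$significant <- !is.na(Z) & Z > 1.65
  new("HierPartResult", effects = eff, r2_full = obs@r2_full,
      n_randomizations = as.integer(n_rand))
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `y` and `x` after ordinary
#' least squares on the control variables. With no controls this is the
#' plain correlation.
#'
#' @param y,x numeric vectors.
#' @param controls optional matrix/data.frame of control variables.
#' @return partial correlation coefficient.
#' @export
partialCorrelation <- function(y, x, controls = NULL) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (is.null(controls) || NCOL(controls) == 0) return(stats::cor(y, x))
  Z <- as.matrix(controls)
  if (nrow(Z) != length(y)) stop("'controls' do not align", call. = FALSE)
  if (length(y) <= ncol(Z) + 2) stop("need n > #controls + 2",
                                     call. = FALSE)
  M <- cbind(1, Z)
  if (qr(M)$rank < ncol(M)) stop("collinear controls", call. = FALSE)
  fit <- stats::lm.fit(M, cbind(y, x))
  ry <- fit$residuals[, 1]
  rx <- fit$residuals[, 2]
  # a variable fully explained by the controls has no residual variance
  if (stats::sd(rx) < 1e-10 * stats::sd(x) ||
      stats::sd(ry) < 1e-10 * stats::sd(y)) {
    return(0)
  }
  stats::cor(ry, rx)
}

#' Stream-blocked ANOVA of a community descriptor
#'
#' Tests the fixed effect of sampling location (U2/U1/D) on a descriptor
#' while blocking on stream, the balanced-design equivalent of a mixed
#' model with stream as random intercept: `F = MS_location / MS_error`.
#' Reports per-location means, Tukey HSD pairwise contrasts (studentized
#' range on the error degrees of freedom), the percentage of variance
#' explained by stream from the method-of-moments variance component
#' `(MS_stream - MS_error) / (MS_stream + (k - 1) MS_error)` (floored at
#' zero), and Cohen's d of the downstream location against the pooled
#' upstream references. Streams missing a location are excluded listwise
#' with a warning.
#'
#' @param values numeric descriptor values, one per location sample.
#' @param location factor/character of positions (`"U2"`, `"U1"`, `"D"`).
#' @param stream factor/character of stream ids.
#' @return list of class `"blockedAnova"`: `F`, `df`, `p`, `means`,
#'   `tukey`, `stream_var_pct`, `cohens_d`, `n_streams`, `excluded`.
#' @export
blockedAnova <- function(values, location, stream) {
  values <- as.numeric(values)
  location <- factor(as.character(location),
                     levels = intersect(.POSITIONS, unique(location)))
  stream <- factor(stream)
  ok_rows <- !is.na(values)
  complete <- tapply(ok_rows, stream, sum) == nlevels(location)
  excluded <- names(complete)[!complete | is.na(complete)]
  if (length(excluded)) {
    warning("excluding stream(s) with incomplete locations: ",
            paste(excluded, collapse = ", "))
  }
  keep <- ok_rows & !(as.character(stream) %in% excluded)
  values <- values[keep]
  location <- droplevels(location[keep])
  stream <- droplevels(stream[keep])
  if (nlevels(stream) < 2) stop("need at least two complete streams",
                                call. = FALSE)
  fit <- stats::aov(values ~ stream + location)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  ms_stream <- tab[rn == "stream", "Mean Sq"]
  ms_loc <- tab[rn == "location", "Mean Sq"]
  ms_err <- tab[rn == "Residuals", "Mean Sq"]
  df <- c(tab[rn == "location", "Df"], tab[rn == "Residuals", "Df"])
  k <- nlevels(location)
  if (ms_err < 1e-12 && ms_loc < 1e-12) {
    Fv <- 0
    p <- 1
    tukey <- data.frame(contrast = character(0), diff = numeric(0),
                        p_adj = numeric(0))
    lv <- levels(location)
    cmb <- utils::combn(lv, 2)
    tukey <- data.frame(contrast = paste(cmb[2, ], cmb[1, ], sep = "-"),
                        diff = 0, p_adj = 1)
  } else {
    Fv <- ms_loc / ms_err
    p <- stats::pf(Fv, df[1], df[2], lower.tail = FALSE)
    th <- stats::TukeyHSD(fit, which = "location")$location
    tukey <- data.frame(contrast = rownames(th), diff = th[, "diff"],
                        p_adj = th[, "p adj"], row.names = NULL)
  }
  denom <- ms_stream + (k - 1) * ms_err
  var_pct <- if (denom > 0) 100 * max(0, (ms_stream - ms_err) / denom) else 0
  d <- tryCatch(
    cohensD(values[location == "D"], values[location != "D"]),
    error = function(e) NA_real_)
  structure(list(F = Fv, df = df, p = p,
                 means = tapply(values, location, mean),
                 tukey = tukey,
                 stream_var_pct = var_pct,
                 cohens_d = d,
                 n_streams = nlevels(stream),
                 excluded = excluded),
            class = "blockedAnova")
}

#' @export
print.blockedAnova <- function(x, ...) {
  cat(sprintf("Location effect: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Location means:", paste(sprintf("%s = %.3f", names(x$means),
                                       x$means), collapse = ", "), "\n")
  cat(sprintf("Stream variance share: %.1f%%; Cohen's d (D vs U): %.2f\n",
              x$stream_var_pct, x$cohens_d))
  invisible(x)
}

#' Cohen's d
#'
#' Standardized mean difference `(mean_1 - mean_2) / s_pooled` with the
#' n-weighted pooled standard deviation.
#'
#' @param x1,x2 numeric vectors (>= 2 values each).
#' @return effect size d.
#' @export
cohensD <- function(x1, x2) {
  x1 <- as.numeric(x1)
  x2 <- as.numeric(x2)
  n1 <- length(x1)
  n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("need at least two values per group",
                             call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled standard deviation: d undefined",
                     call. = FALSE)
  (mean(x1) - mean(x2)) / sqrt(sp2)
}
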