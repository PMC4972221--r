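# Taxonomy- and trait-based community descriptors.
#
# All functions operate on a single abundance vector (counts per taxon) or,
# for descriptorMatrix(), on a whole survey. Trait-based indices take the
# trait table aligned to the abundance vector by taxon name or position.

#' Taxa richness
#'
#' Number of taxa with a positive count.
#'
#' @param counts non-negative numeric vector of per-taxon counts.
#' @return integer richness.
#' @export
taxaRichness <- function(counts) {
  counts <- as_count_vector(counts)
  if (sum(counts) == 0) {
    stop("all counts are zero: community undefined", call. = FALSE)
  }
  sum(counts > 0)
}

#' Hurlbert rarefied richness
#'
#' Expected number of taxa in a random subsample of `n` individuals,
#' computed from the exact hypergeometric expectation
#' \deqn{E[S_n] = \sum_i \left(1 - \binom{N - x_i}{n} / \binom{N}{n}\right)}
#' with no resampling.
#'
#' @param counts non-negative numeric vector of per-taxon counts.
#' @param n subsample size, `1 <= n <= sum(counts)`.
#' @return expected richness (numeric).
#' @export
rarefiedRichness <- function(counts, n) {
  counts <- as_count_vector(counts)
  N <- sum(counts)
  if (N == 0) stop("all counts are zero: community undefined", call. = FALSE)
  if (n < 1 || n > N) {
    stop(sprintf(
      "subsample size n = %s out of range; choose 1 <= n <= %d (the location total)",
      format(n), as.integer(N)), call. = FALSE)
  }
  x <- counts[counts > 0]
  # log-scale binomial ratios for numerical stability
  lr <- lchoose(N - x, n) - lchoose(N, n)
  lr[N - x < n] <- -Inf
  sum(1 - exp(lr))
}

#' Pielou's evenness
#'
#' `J = H' / ln S`, Shannon entropy (natural log) of relative abundances
#' over the log of richness. Undefined for single-taxon communities
#' (returned as `NA` with a warning).
#'
#' @param counts non-negative numeric vector of per-taxon counts.
#' @return evenness in `[0, 1]`, or `NA` when S < 2.
#' @export
pielouEvenness <- function(counts) {
  counts <- as_count_vector(counts)
  S <- sum(counts > 0)
  if (S < 2) {
    warning("evenness undefined for fewer than two taxa")
    return(NA_real_)
  }
  H <- vegan::diversity(counts, index = "shannon")
  unname(H / log(S))
}

#' Fisher's alpha
#'
#' The log-series diversity parameter: the unique `alpha > 0` solving
#' `S = alpha * ln(1 + N / alpha)`, found by root bisection to a residual
#' below 1e-10. Diverges when every individual is a singleton (`S == N`).
#'
#' @param S observed richness (or an abundance vector, from which S and N
#'   are taken).
#' @param N total count; omit when `S` is an abundance vector.
#' @return alpha (numeric).
#' @export
fisherAlpha <- function(S, N = NULL) {
  if (is.null(N)) {
    x <- as_count_vector(S)
    N <- sum(x)
    S <- sum(x > 0)
  }
  if (S < 1 || N < S) stop("need S >= 1 and N >= S", call. = FALSE)
  if (S == N) {
    stop("all individuals are singletons (S == N): Fisher's alpha diverges",
         call. = FALSE)
  }
  f <- function(a) a * log1p(N / a) - S
  # f is increasing in alpha; bracket then refine
  lo <- 1e-8
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-14)
  a <- r$root
  if (abs(f(a)) > 1e-10) {
    # polish with one more bisection pass at tighter tolerance
    r <- stats::uniroot(f, c(a * 0.5, a * 2), tol = .Machine$double.eps)
    a <- r$root
  }
  a
}

#' Berger-Parker dominance
#'
#' Relative abundance of the single most abundant taxon.
#'
#' @param counts non-negative numeric vector of per-taxon counts.
#' @return dominance in `(0, 1]`.
#' @export
bergerParker <- function(counts) {
  counts <- as_count_vector(counts)
  N <- sum(counts)
  if (N == 0) stop("all counts are zero: community undefined", call. = FALSE)
  max(counts) / N
}

#' Saprobic Index
#'
#' Abundance-weighted mean of taxon saprobic values,
#' \deqn{SI = \sum_i s_i g_i a_i / \sum_i g_i a_i,}
#' where `s_i` is the saprobic value (1 = clean to 4 = heavily polluted),
#' `g_i` the indicator weight and `a_i` the abundance term. The abundance
#' term defaults to the raw count; `abundance_class` accepts a transform
#' (e.g. an abundance-class coding) applied to the counts first. Taxa with
#' missing `saprobic` or `weight` are excluded from numerator and
#' denominator.
#'
#' @param counts non-negative numeric vector of per-taxon counts.
#' @param traits trait table with columns `saprobic` and `weight`, rows
#'   aligned to `counts` (by name when both are named).
#' @param abundance_class optional function transforming counts to the
#'   abundance term.
#' @return index in `[1, 4]`, or `NA` (with a warning) when no scored taxon
#'   is present.
#' @export
saprobicIndex <- function(counts, traits, abundance_class = NULL) {
  counts <- as_count_vector(counts)
  traits <- .align_traits(counts, traits)
  a <- if (is.null(abundance_class)) counts else abundance_class(counts)
  ok <- !is.na(traits$saprobic) & !is.na(traits$weight) & a > 0
  if (!any(ok)) {
    warning("no scored taxa present: Saprobic Index undefined")
    return(NA_real_)
  }
  s <- traits$saprobic[ok]
  g <- traits$weight[ok]
  a <- a[ok]
  sum(s * g * a) / sum(g * a)
}

#' SPEAR pesticides index
#'
#' Percentage of the community belonging to pesticide-sensitive (SPEAR)
#' taxa, abundance-weighted with the log-damped weight
#' `w(x) = log10(4x + 1)`:
#' \deqn{SPEAR = 100 \sum_{i \in SPEAR} w(x_i) / \sum_i w(x_i).}
#' Lower values indicate toxicant stress.
#'
#' @param counts non-negative numeric vector of per-taxon counts.
#' @param traits trait table with logical column `spear`, rows aligned to
#'   `counts`.
#' @return percentage in `[0, 100]`.
#' @export
spearIndex <- function(counts, traits) {
  counts <- as_count_vector(counts)
  traits <- .align_traits(counts, traits)
  if (sum(counts) == 0) {
    stop("all counts are zero: community undefined", call. = FALSE)
  }
  w <- log10(4 * counts + 1)
  100 * sum(w[traits$spear]) / sum(w)
}

#' EPT and abundance metrics
#'
#' Richness and relative abundance of EPT taxa (Ephemeroptera, Plecoptera,
#' Trichoptera), total abundance, and the oligochaete-excluded variants
#' used when wastewater-driven oligochaete blooms would otherwise swamp the
#' denominators.
#'
#' @param counts non-negative numeric vector of per-taxon counts.
#' @param traits trait table with logical columns `ept` and `oligochaete`.
#' @return named list: `ept_richness`, `pct_ept`, `pct_ept_minus_oligo`,
#'   `total_abundance`, `abundance_minus_oligo`.
#' @export
eptMetrics <- function(counts, traits) {
  counts <- as_count_vector(counts)
  traits <- .align_traits(counts, traits)
  N <- sum(counts)
  if (N == 0) stop("all counts are zero: community undefined", call. = FALSE)
  n_ept <- sum(counts[traits$ept])
  n_oli <- sum(counts[traits$oligochaete])
  denom <- N - n_oli
  list(ept_richness = sum(counts > 0 & traits$ept),
       pct_ept = 100 * n_ept / N,
       pct_ept_minus_oligo = if (denom > 0) 100 * n_ept / denom else {
         warning("denominator zero after excluding oligochaetes")
         NA_real_
       },
       total_abundance = N,
       abundance_minus_oligo = denom)
}

.align_traits <- function(counts, traits) {
  traits <- as.data.frame(traits)
  if (!is.null(names(counts)) && !is.null(rownames(traits)) &&
      all(names(counts) %in% rownames(traits))) {
    traits <- traits[names(counts), , drop = FALSE]
  } else if (nrow(traits) != length(counts)) {
    stop("trait table does not align with the abundance vector",
         call. = FALSE)
  }
  traits
}

#' Descriptor matrix for a whole survey
#'
#' Assembles all twelve community descriptors per sampling location:
#' taxa richness, rarefied richness, Pielou's evenness, Fisher's alpha,
#' Saprobic Index, SPEAR index, total abundance, abundance minus
#' oligochaetes, EPT richness, %EPT, %EPT minus oligochaetes and
#' Berger-Parker dominance. Per-location failures of individual
#' descriptors become `NA` values (with warnings); the batch never aborts.
#'
#' @param x a [StreamExperiment] or a locations-by-taxa abundance matrix.
#' @param traits trait table (ignored for a `StreamExperiment`).
#' @param rarefaction_n subsample size for rarefied richness; defaults to
#'   the smallest location total.
#' @param ... passed on between methods.
#' @return data.frame, one row per location, one column per descriptor.
#' @export
setGeneric("descriptorMatrix",
           function(x, ...) standardGeneric("descriptorMatrix"))

#' @rdname descriptorMatrix
#' @export
setMethod("descriptorMatrix", "StreamExperiment",
  function(x, rarefaction_n = NULL, ...) {
    .descriptor_matrix(abundanceTable(x), traitTable(x), rarefaction_n)
  })

#' @rdname descriptorMatrix
#' @export
setMethod("descriptorMatrix", "matrix",
  function(x, traits, rarefaction_n = NULL, ...) {
    .descriptor_matrix(x, traits, rarefaction_n)
  })

.descriptor_matrix <- function(abundance, traits, rarefaction_n = NULL) {
  abundance <- as.matrix(abundance)
  totals <- rowSums(abundance)
  if (any(totals == 0)) {
    stop("locations with zero total count: ",
         paste(rownames(abundance)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rarefaction_n)) rarefaction_n <- min(totals)
  one <- function(x) {
    ept <- eptMetrics(x, traits)
    S <- taxaRichness(x)
    data.frame(
      taxa_richness = S,
      rarefied_richness = rarefiedRichness(x, rarefaction_n),
      evenness = tryCatch(pielouEvenness(x), warning = function(w) NA_real_),
      fisher_alpha = tryCatch(fisherAlpha(x), error = function(e) NA_real_),
      saprobic = withCallingHandlers(
        saprobicIndex(x, traits),
        warning = function(w) invokeRestart("muffleWarning")),
      spear = spearIndex(x, traits),
      total_abundance = ept$total_abundance,
      abundance_minus_oligo = ept$abundance_minus_oligo,
      ept_richness = ept$ept_richness,
      pct_ept = ept$pct_ept,
      pct_ept_minus_oligo = ept$pct_ept_minus_oligo,
      berger_parker = bergerParker(x))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(abundance)), function(i) {
    row <- abundance[i, ]
    names(row) <- colnames(abundance)
    one(row)
  }))
  rownames(res) <- rownames(abundance)
  res
}
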