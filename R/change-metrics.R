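# Null-corrected upstream/downstream change statistics and the
# PCA-derived disturbance and habitat predictors.

#' Wastewater dilution factor
#'
#' `DF_ww = Q347 / Q_ww`: the low-flow discharge (reached or exceeded 347
#' days per year) over the mean wastewater discharge. Small values mean
#' weak dilution, i.e. strong disturbance.
#'
#' @param q347 low-flow discharge(s), positive.
#' @param q_ww mean wastewater discharge(s), positive.
#' @return dilution factor(s).
#' @examples
#' dilutionFactor(0.9, 0.3) # 3: wastewater is a third of baseflow
#' @export
dilutionFactor <- function(q347, q_ww) {
  if (any(!is.finite(q347)) || any(q347 <= 0) ||
      any(!is.finite(q_ww)) || any(q_ww <= 0)) {
    stop("discharges must be positive and finite", call. = FALSE)
  }
  q347 / q_ww
}

#' Null-corrected descriptor change
#'
#' The downstream-minus-upstream difference corrected for natural
#' longitudinal drift between the two upstream reference reaches:
#' `delta = (D - U1) - (U1 - U2)`. Zero whenever the downstream change
#' equals the drift between the references. Vectorized over streams;
#' missing inputs yield missing changes with a warning.
#'
#' @param d_D,d_U1,d_U2 descriptor values at the downstream location and
#'   the two upstream references (U1 nearer the outfall).
#' @return numeric change(s).
#' @export
descriptorChange <- function(d_D, d_U1, d_U2) {
  out <- (d_D - d_U1) - (d_U1 - d_U2)
  if (anyNA(out)) warning("missing descriptor values: change set to NA")
  out
}

#' Total Community Change
#'
#' Euclidean displacement in two-axis NMDS space from U1 to D (`Change`),
#' minus the U2-to-U1 displacement (`NullChange`):
#' `TCC = Change - NullChange`. All three locations must carry scores from
#' one joint ordination. Negative values (downstream shift smaller than
#' natural drift) are passed through as-is. The statistic is invariant
#' under rigid rotation and translation of the configuration.
#'
#' @param scores matrix of NMDS scores (>= 2 columns; the first two are
#'   used), rownames identifying locations.
#' @param stream,position vectors aligned to the rows of `scores`.
#' @return data.frame per stream: `change`, `null_change`, `tcc`.
#' @export
totalCommunityChange <- function(scores, stream, position) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need two ordination axes", call. = FALSE)
  if (length(stream) != nrow(scores) || length(position) != nrow(scores)) {
    stop("'stream'/'position' do not align with 'scores'", call. = FALSE)
  }
  streams <- unique(stream)
  res <- do.call(rbind, lapply(streams, function(s) {
    pick <- function(p) {
      i <- which(stream == s & position == p)
      if (length(i) != 1) return(c(NA_real_, NA_real_))
      scores[i, 1:2]
    }
    u2 <- pick("U2"); u1 <- pick("U1"); d <- pick("D")
    ch <- sqrt(sum((d - u1)^2))
    nc <- sqrt(sum((u1 - u2)^2))
    data.frame(stream = s, change = ch, null_change = nc, tcc = ch - nc,
               row.names = NULL)
  }))
  if (anyNA(res$tcc)) warning("streams with missing locations: TCC is NA")
  res
}

#' Wastewater composition index (PC1_ww)
#'
#' Correlation-scaled PCA of the downstream/effluent water-chemistry block;
#' the first-component site scores summarize wastewater composition into a
#' single index. PCA signs being arbitrary, the component is oriented to
#' correlate positively with total nitrogen (or the first available column
#' of `orient_var`), making the index reproducible.
#'
#' @param chemistry streams-by-variables chemistry matrix or data.frame.
#' @param orient_var column name(s) used to fix the sign, in order of
#'   preference.
#' @return list with `scores` (named per stream), `var_fraction` (variance
#'   explained by PC1), `dropped` (constant columns removed).
#' @export
wastewaterPC <- function(chemistry, orient_var = c("totn", "no3")) {
  chem <- as.matrix(chemistry)
  if (nrow(chem) < 2) stop("need at least two streams", call. = FALSE)
  sds <- apply(chem, 2, stats::sd)
  dropped <- colnames(chem)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant chemistry variable(s): ",
            paste(dropped, collapse = ", "))
    chem <- chem[, sds > 0, drop = FALSE]
  }
  p <- runPCA(chem, center = TRUE, scale = TRUE)
  pc1 <- p$scores[, 1]
  ov <- intersect(orient_var, colnames(chem))
  if (length(ov)) {
    r <- stats::cor(pc1, chem[, ov[1]])
    if (!is.na(r) && r < 0) pc1 <- -pc1
  }
  list(scores = pc1, var_fraction = p$var_fraction[1], dropped = dropped)
}

#' Habitat change index (PC_habitat)
#'
#' Two-stage summary of instream habitat change below the outfall.
#' Stage 1: correlation-scaled PCA of the habitat block across all
#' supplied locations. Stage 2: the per-stream differences (D minus U1) of
#' the first `n_axes` component scores are collapsed to one score by an
#' *uncentred* PCA, so streams with identical upstream and downstream
#' habitat score exactly zero. The sign is fixed so the index correlates
#' positively with the fine-sediment (mud) change where available.
#'
#' @param habitat locations-by-variables habitat matrix or data.frame.
#' @param stream,position vectors aligned to the rows of `habitat`.
#' @param n_axes number of stage-1 components whose changes are collapsed.
#' @param orient_var habitat variable used to fix the sign of the index.
#' @return list with `scores` (named per stream), `stage1_var_fraction`
#'   (variance explained by the first `n_axes` components),
#'   `var_fraction` (stage-2 share of the collapsed change variance).
#' @export
habitatChangePC <- function(habitat, stream, position, n_axes = 3,
                            orient_var = "mud") {
  hab <- as.matrix(habitat)
  if (length(stream) != nrow(hab) || length(position) != nrow(hab)) {
    stop("'stream'/'position' do not align with 'habitat'", call. = FALSE)
  }
  keep <- position %in% c("U1", "D")
  hab <- hab[keep, , drop = FALSE]
  stream <- stream[keep]
  position <- position[keep]
  sds <- apply(hab, 2, stats::sd)
  hab <- hab[, sds > 0, drop = FALSE]
  p1 <- runPCA(hab, center = TRUE, scale = TRUE)
  n_axes <- min(n_axes, ncol(p1$scores))
  streams <- unique(stream)
  diffs <- t(vapply(streams, function(s) {
    iu <- which(stream == s & position == "U1")
    id <- which(stream == s & position == "D")
    if (length(iu) != 1 || length(id) != 1) {
      return(rep(NA_real_, n_axes))
    }
    p1$scores[id, seq_len(n_axes)] - p1$scores[iu, seq_len(n_axes)]
  }, numeric(n_axes)))
  if (anyNA(diffs)) warning("streams with missing U1/D habitat rows")
  ok <- stats::complete.cases(diffs)
  sv <- svd(diffs[ok, , drop = FALSE])
  score <- rep(NA_real_, length(streams))
  score[ok] <- diffs[ok, , drop = FALSE] %*% sv$v[, 1]
  names(score) <- streams
  if (orient_var %in% colnames(hab)) {
    mudchange <- vapply(streams, function(s) {
      iu <- which(stream == s & position == "U1")
      id <- which(stream == s & position == "D")
      if (length(iu) != 1 || length(id) != 1) return(NA_real_)
      hab[id, orient_var] - hab[iu, orient_var]
    }, numeric(1))
    r <- suppressWarnings(stats::cor(score, mudchange,
                                     use = "complete.obs"))
    if (!is.na(r) && r < 0) score <- -score
  }
  list(scores = score,
       stage1_var_fraction = sum(p1$var_fraction[seq_len(n_axes)]),
       var_fraction = sv$d[1]^2 / sum(sv$d^2))
}
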