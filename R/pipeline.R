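# End-to-end orchestration: simulate/load -> descriptors -> ordinations ->
# null-corrected changes and predictors -> hierarchical partitioning and
# blocked ANOVA; plus validation and report rendering.

.ENV_PREDICTORS <- c("no3", "nh4", "srp", "conductivity", "doc", "tss",
                     "flow")
.MAIN_DESCRIPTORS <- c("taxa_richness", "rarefied_richness", "evenness",
                       "fisher_alpha", "saprobic", "spear")
.RESPONSES <- c("d_taxa", "d_rarefied", "d_evenness", "d_fisher",
                "d_community", "d_spear", "d_saprobic")

#' Pipeline configuration
#'
#' Collects all pipeline settings, with one root seed from which every
#' stochastic stage derives its own stream. Data come either from a
#' [simParams()] object (synthetic mode) or from a [StreamExperiment] /
#' CSV directory.
#'
#' @param params a [simParams()] object (synthetic mode), or `NULL`.
#' @param experiment a [StreamExperiment], or `NULL`.
#' @param data_dir directory of CSV tables for [readStreamTables()], or
#'   `NULL`.
#' @param exclude_streams stream ids dropped from the PERMANOVA and NMDS
#'   stage (e.g. a stream with an anomalous community); exclusions are
#'   logged, never silent.
#' @param rarefaction_n rarefaction subsample size (default: smallest
#'   location total).
#' @param nmds_starts random starts of the joint NMDS.
#' @param n_perm permutations for ordination tests and forward selection.
#' @param n_rand randomizations for hierarchical-partitioning Z-scores.
#' @param r_max collinearity threshold for the predictor pre-filter.
#' @param alpha entry threshold of forward selection.
#' @param responses change responses to model (subset of
#'   `d_taxa, d_rarefied, d_evenness, d_fisher, d_community, d_spear,
#'   d_saprobic`).
#' @param env_vars chemistry/hydraulic columns used as reach-scale
#'   predictors in the upstream partial RDA.
#' @param seed root seed.
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(params = NULL, experiment = NULL,
                           data_dir = NULL,
                           exclude_streams = character(0),
                           rarefaction_n = NULL,
                           nmds_starts = 20, n_perm = 999, n_rand = 1000,
                           r_max = 0.6, alpha = 0.05,
                           responses = .RESPONSES,
                           env_vars = .ENV_PREDICTORS,
                           seed = 1) {
  if (is.null(params) && is.null(experiment) && is.null(data_dir)) {
    params <- simParams(seed = seed)
  }
  stopifnot_scalar_pos(nmds_starts, "nmds_starts")
  stopifnot_scalar_pos(n_perm, "n_perm")
  stopifnot_scalar_pos(n_rand, "n_rand")
  responses <- match.arg(responses, .RESPONSES, several.ok = TRUE)
  structure(as.list(environment()), class = "pipelineConfig")
}

#' Validate the three survey tables
#'
#' Cross-checks taxon and location alignment, U2/U1/D completeness per
#' stream, count non-negativity and trait bounds. Hard errors (misaligned
#' identifiers, negative counts) are separated from warnings (incomplete
#' streams, which are merely excluded from change statistics).
#'
#' @param abundance locations-by-taxa count table.
#' @param traits per-taxon trait table.
#' @param sites per-location site table.
#' @return list with character vectors `errors` and `warnings`.
#' @export
validateStreamData <- function(abundance, traits, sites) {
  errors <- character(0)
  warnings <- character(0)
  ab <- as.matrix(abundance)
  tr <- as.data.frame(traits)
  st <- as.data.frame(sites)
  tax_ids <- if ("taxon" %in% colnames(tr)) tr$taxon else rownames(tr)
  loc_ids <- if ("location" %in% colnames(st)) st$location else rownames(st)
  unknown <- setdiff(colnames(ab), tax_ids)
  if (length(unknown)) {
    errors <- c(errors, paste0("abundance taxa without trait records: ",
                               paste(unknown, collapse = ", ")))
  }
  unknown <- setdiff(rownames(ab), loc_ids)
  if (length(unknown)) {
    errors <- c(errors, paste0("abundance locations without site records: ",
                               paste(unknown, collapse = ", ")))
  }
  if (any(ab < 0)) errors <- c(errors, "negative counts present")
  if (any(abs(ab - round(ab)) > 1e-8)) {
    errors <- c(errors, "non-integer counts present")
  }
  if (any(rowSums(ab) == 0)) {
    errors <- c(errors, paste0("zero-total locations: ",
                               paste(rownames(ab)[rowSums(ab) == 0],
                                     collapse = ", ")))
  }
  if ("saprobic" %in% colnames(tr)) {
    bad <- !is.na(tr$saprobic) & (tr$saprobic < 1 | tr$saprobic > 4)
    if (any(bad)) errors <- c(errors, "saprobic values outside [1, 4]")
  }
  if (all(c("stream", "position") %in% colnames(st))) {
    tab <- table(st$stream, factor(st$position, .POSITIONS))
    incomplete <- rownames(tab)[apply(tab, 1, function(r) any(r != 1))]
    if (length(incomplete)) {
      warnings <- c(warnings, paste0(
        "streams without a full U2/U1/D triplet (excluded from change ",
        "statistics): ", paste(incomplete, collapse = ", ")))
    }
  } else {
    errors <- c(errors, "site table lacks 'stream'/'position' columns")
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic or supplied),
#' validation, the descriptor matrix, the joint NMDS of all locations,
#' PERMANOVA of location groups, the upstream partial RDA (conditioned on
#' forward-selected PCNM spatial eigenvectors) yielding the upstream
#' community-composition axes RD1-3_invert, the null-corrected change
#' statistics and Total Community Change, the wastewater and habitat PCA
#' predictors, hierarchical partitioning with randomization Z-scores per
#' change response, and stream-blocked ANOVA per descriptor. Deterministic
#' given the configuration: all stage seeds derive from the root seed.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `"ReportBundle"`; see [renderReports()].
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (!inherits(config, "pipelineConfig")) {
    stop("'config' must come from pipelineConfig()", call. = FALSE)
  }
  seed <- config$seed
  log <- list(root_seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  se <- stage("data", {
    if (!is.null(config$experiment)) config$experiment
    else if (!is.null(config$data_dir)) readStreamTables(config$data_dir)
    else simulateStreams(config$params)
  })
  sites <- siteTable(se)
  traits <- traitTable(se)
  ab <- abundanceTable(se)

  stage("validate", {
    v <- validateStreamData(ab, traits, sites)
    if (length(v$errors)) stop(paste(v$errors, collapse = "; "))
    for (w in v$warnings) warning(w, call. = FALSE)
    log$validation <- v
  })

  descriptors <- stage("descriptors",
                       descriptorMatrix(se,
                                        rarefaction_n = config$rarefaction_n))

  hel <- stage("hellinger", hellingerTransform(ab))
  keep_ord <- !(sites$stream %in% config$exclude_streams)
  if (any(!keep_ord)) {
    log$excluded_from_ordination <- unique(sites$stream[!keep_ord])
  }

  nmds <- stage("nmds", runNMDS(stats::dist(hel), k = 2,
                                n_starts = config$nmds_starts,
                                seed = seed + 11L))

  permanova <- stage("permanova", {
    d <- stats::dist(hel[keep_ord, , drop = FALSE])
    runPERMANOVA(d, sites$position[keep_ord], n_perm = config$n_perm,
                 seed = seed + 12L)
  })

  upstream <- stage("upstream_prda", {
    up <- sites$position %in% c("U1", "U2")
    Yu <- hel[up, , drop = FALSE]
    coords <- as.matrix(sites[up, c("x", "y")])
    pcnm <- spatialEigenvectors(coords)
    fs <- forwardSelect(Yu, pcnm$vectors, alpha = config$alpha,
                        n_perm = config$n_perm, seed = seed + 13L)
    Z <- if (length(fs$selected)) {
      pcnm$vectors[, fs$selected, drop = FALSE]
    } else NULL
    env <- as.matrix(sites[up, c("arable", "pasture", config$env_vars)])
    cf <- collinearityFilter(env, r_max = config$r_max)
    X0 <- env[, cf$retained, drop = FALSE]
    # unimportant variables are dropped by forward selection (on Y with the
    # selected spatial structure removed); at least three constraints are
    # kept so that the three community-composition axes exist
    Yfs <- if (is.null(Z)) Yu else {
      stats::resid(stats::lm.fit(cbind(1, Z), Yu))
    }
    fse <- forwardSelect(Yfs, X0, alpha = config$alpha,
                         n_perm = config$n_perm, seed = seed + 15L)
    sel <- fse$selected
    if (length(sel) < 3) {
      extra <- setdiff(fse$trace$candidate, sel)
      gain_order <- unique(c(sel, extra, colnames(X0)))
      sel <- gain_order[seq_len(min(3, ncol(X0)))]
    }
    X <- X0[, sel, drop = FALSE]
    prda <- partialRDA(Yu, X, Z, n_perm = config$n_perm, seed = seed + 14L)
    list(prda = prda, pcnm_selected = fs, env_selected = fse,
         collinearity = cf, locations = rownames(Yu))
  })

  change_table <- stage("changes", {
    streams <- sort(unique(sites$stream))
    loc_of <- function(p) paste(streams, p, sep = "_")
    ids <- rownames(descriptors)
    at <- function(p, col) descriptors[match(loc_of(p), ids), col]
    ct <- data.frame(stream = streams)
    for (col in .MAIN_DESCRIPTORS) {
      resp <- paste0("d_", switch(col, taxa_richness = "taxa",
                                  rarefied_richness = "rarefied",
                                  evenness = "evenness",
                                  fisher_alpha = "fisher",
                                  saprobic = "saprobic", spear = "spear"))
      ct[[resp]] <- descriptorChange(at("D", col), at("U1", col),
                                     at("U2", col))
    }
    tcc <- totalCommunityChange(nmds$points, sites$stream, sites$position)
    ct$d_community <- tcc$tcc[match(streams, tcc$stream)]

    sc <- upstream$prda$site_scores
    u1 <- match(loc_of("U1"), rownames(sc))
    n_ax <- min(3, ncol(sc))
    for (a in seq_len(n_ax)) ct[[paste0("RD", a, "_invert")]] <- sc[u1, a]
    per_stream <- sites[match(loc_of("D"), rownames(sites)), ]
    ct$DF_ww <- dilutionFactor(per_stream$q347, per_stream$q_ww)
    pcww <- wastewaterPC(per_stream[, .CHEM_VARS])
    ct$PC1_ww <- unname(pcww$scores)
    hab <- habitatChangePC(sites[, .HABITAT_VARS], sites$stream,
                           sites$position)
    ct$PC_habitat <- unname(hab$scores[match(streams, names(hab$scores))])
    log$pc_ww_var_fraction <- pcww$var_fraction
    log$pc_habitat_var_fraction <- hab$stage1_var_fraction
    ct
  })

  predictors <- c(grep("^RD[0-9]+_invert$", colnames(change_table),
                       value = TRUE), "DF_ww", "PC1_ww", "PC_habitat")

  hierpart <- stage("hierpart", {
    out <- list()
    for (i in seq_along(config$responses)) {
      resp <- config$responses[i]
      y <- change_table[[resp]]
      X <- as.matrix(change_table[, predictors])
      ok <- stats::complete.cases(cbind(y, X))
      hp <- hierPartZ(y[ok], X[ok, , drop = FALSE],
                      n_rand = config$n_rand, seed = seed + 20L + i)
      top <- rownames(hp@effects)[which.max(hp@effects$I)]
      pr <- partialCorrelation(y[ok], X[ok, top],
                               X[ok, setdiff(predictors, top),
                                 drop = FALSE])
      attr(hp, "partial_r_top") <- stats::setNames(pr, top)
      out[[resp]] <- hp
    }
    out
  })

  anova_table <- stage("anova", {
    do.call(rbind, lapply(.MAIN_DESCRIPTORS, function(col) {
      ba <- suppressWarnings(
        blockedAnova(descriptors[[col]],
                     sites[rownames(descriptors), "position"],
                     sites[rownames(descriptors), "stream"]))
      m <- function(p) mean(descriptors[sites[rownames(descriptors),
                                              "position"] == p, col],
                            na.rm = TRUE)
      s <- function(p) stats::sd(descriptors[sites[rownames(descriptors),
                                                   "position"] == p, col],
                                 na.rm = TRUE)
      data.frame(indicator = col,
                 mean_U2 = m("U2"), sd_U2 = s("U2"),
                 mean_U1 = m("U1"), sd_U1 = s("U1"),
                 mean_D = m("D"), sd_D = s("D"),
                 cohens_d = ba$cohens_d, F = ba$F,
                 df1 = ba$df[1], df2 = ba$df[2], p = ba$p,
                 stream_var_pct = ba$stream_var_pct,
                 row.names = NULL)
    }))
  })

  structure(list(experiment = se, descriptors = descriptors, nmds = nmds,
                 permanova = permanova, upstream = upstream,
                 change_table = change_table, hierpart = hierpart,
                 anova_table = anova_table, log = log, config = config),
            class = "ReportBundle")
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle:", nrow(x$change_table), "streams,",
      nrow(x$descriptors), "locations\n")
  cat(sprintf("  NMDS stress %.4f | PERMANOVA F = %.2f, R2 = %.2f, p = %.4g\n",
              x$nmds$stress, x$permanova$F, x$permanova$R2, x$permanova$p))
  cat("  responses modelled:", paste(names(x$hierpart), collapse = ", "),
      "\n")
  invisible(x)
}

#' Flatten the hierarchical-partitioning results to a report table
#'
#' One row per response-by-predictor combination, ordered by the
#' independent contribution (%I) within response; the partial correlation
#' is reported for the top predictor of each response.
#'
#' @param bundle a `ReportBundle`.
#' @return data.frame.
#' @export
hierpartTable <- function(bundle) {
  do.call(rbind, lapply(names(bundle$hierpart), function(resp) {
    hp <- bundle$hierpart[[resp]]
    eff <- hp@effects
    eff <- eff[order(-eff$pct_I), , drop = FALSE]
    pr <- attr(hp, "partial_r_top")
    data.frame(response = resp, predictor = rownames(eff),
               I = eff$I, J = eff$J, total = eff$total, pct_I = eff$pct_I,
               Z = eff$Z, significant = eff$significant,
               partial_r = ifelse(rownames(eff) == names(pr), pr,
                                  NA_real_),
               row.names = NULL)
  }))
}

#' Render a ReportBundle to files
#'
#' Writes the descriptor matrix, the change table, the blocked-ANOVA
#' summary, the hierarchical-partitioning table, the NMDS scores and a
#' plain-text run log into `dir`. All CSVs round-trip losslessly.
#'
#' @param bundle a `ReportBundle` from [runPipeline()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
renderReports <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name, rn = FALSE) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = rn)
    p
  }
  paths <- c(
    w(cbind(location = rownames(bundle$descriptors), bundle$descriptors),
      "descriptors.csv"),
    w(bundle$change_table, "change_table.csv"),
    w(bundle$anova_table, "anova_table.csv"),
    w(hierpartTable(bundle), "hierpart_table.csv"),
    w(data.frame(location = rownames(bundle$nmds$points),
                 bundle$nmds$points), "nmds_scores.csv"))
  logp <- file.path(dir, "run_log.md")
  ln <- c("# Pipeline run log", "",
          sprintf("- root seed: %s", bundle$log$root_seed),
          sprintf("- NMDS stress: %.6f (converged: %s)",
                  bundle$nmds$stress, bundle$nmds$converged),
          sprintf("- PERMANOVA: F = %.4f, R2 = %.4f, p = %.4g (%d perms)",
                  bundle$permanova$F, bundle$permanova$R2,
                  bundle$permanova$p, bundle$permanova$n_perm),
          sprintf("- PC1_ww variance fraction: %.3f",
                  bundle$log$pc_ww_var_fraction),
          sprintf("- PC_habitat stage-1 variance fraction: %.3f",
                  bundle$log$pc_habitat_var_fraction),
          sprintf("- PCNM axes retained: %s",
                  if (length(bundle$upstream$pcnm_selected$selected))
                    paste(bundle$upstream$pcnm_selected$selected,
                          collapse = ", ") else "none"),
          sprintf("- collinearity-dropped predictors: %s",
                  if (is.null(bundle$upstream$collinearity$dropped)) "none"
                  else paste(bundle$upstream$collinearity$dropped$column,
                             collapse = ", ")),
          if (!is.null(bundle$log$excluded_from_ordination))
            sprintf("- streams excluded from ordination: %s",
                    paste(bundle$log$excluded_from_ordination,
                          collapse = ", ")))
  writeLines(ln, logp)
  invisible(c(paths, logp))
}

#' NMDS diagnostic plot
#'
#' Base-graphics ordination plot of the joint NMDS with standard-deviation
#' dispersion ellipses per sampling location group.
#'
#' @param bundle a `ReportBundle`.
#' @param ... passed to [plot()].
#' @return invisibly `NULL`.
#' @export
plotNMDS <- function(bundle, ...) {
  pts <- bundle$nmds$points
  pos <- factor(siteTable(bundle$experiment)$position, .POSITIONS)
  cols <- c(U2 = "#1b9e77", U1 = "#7570b3", D = "#d95f02")
  plot(pts, col = cols[as.character(pos)], pch = 19,
       xlab = "NMDS1", ylab = "NMDS2", ...)
  for (p in levels(pos)) {
    vegan::ordiellipse(pts, groups = pos, show.groups = p,
                       col = cols[[p]], draw = "lines")
  }
  graphics::legend("topright", legend = levels(pos), col = cols[levels(pos)],
                   pch = 19, bty = "n")
  invisible(NULL)
}
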