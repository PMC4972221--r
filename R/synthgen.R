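# Synthetic stream-network generator.
#
# Emulates a replicated wastewater point-source survey: n_streams streams,
# each with two upstream reference reaches (U2, U1) and one reach (D) below
# the treatment-plant outfall. Community structure is parameterized on the
# descriptor scale (Saprobic Index, SPEAR %, oligochaete share) and mapped
# to expected taxon compositions; counts are negative-binomial draws around
# those expectations.

.CHEM_VARS <- c("conductivity", "ph", "alkalinity", "hardness",
                "nh4", "no2", "tp", "srp", "no3", "totn", "sio4",
                "na", "k", "ca", "mg", "cl", "so4",
                "toc", "doc", "tss")
# variables that carry the effluent-quality latent factor at D
.CHEM_WW <- c("conductivity", "nh4", "no2", "tp", "srp", "no3", "totn",
              "na", "cl", "so4", "toc", "doc", "tss")

.HABITAT_VARS <- c("bedrock", "boulder", "cobble", "gravel", "sand", "mud",
                   "tss_total", "tss_inorganic", "oss_pct", "cpom", "algae",
                   "bryophytes", "submerged_macrophytes",
                   "emergent_macrophytes", "flow", "width", "depth")
# habitat variables most altered by wastewater-derived fine sediment and
# nutrient subsidies
.HABITAT_WW <- c("sand", "mud", "tss_total", "oss_pct",
                 "submerged_macrophytes", "algae")

#' Parameters of the synthetic stream-network generator
#'
#' Bundles and validates all knobs of the generator. Defaults reproduce the
#' study conditions of a twelve-stream wastewater survey: catchment agriculture
#' (arable + pasture) spanning 5--80% cover, downstream wastewater fractions
#' spanning 23--133% of the Q347 low-flow discharge, upstream Saprobic Index
#' rising with agriculture, upstream SPEAR falling with arable cover,
#' downstream oligochaete enrichment inversely related to upstream saprobity
#' (slopes 0.468 and -1.40 on the share-per-SI-unit scale), and a downstream
#' SPEAR depression proportional to the wastewater fraction.
#'
#' @param n_streams number of streams (each contributes locations U2, U1, D).
#' @param n_taxa number of taxa (>= 10).
#' @param agriculture_range fraction pair: catchment agriculture cover span.
#' @param ww_fraction_range fraction pair: Q_ww/Q347 span; the upper bound
#'   may exceed 1 (wastewater exceeding baseflow).
#' @param si_intercept,beta_si_agri upstream Saprobic Index as a linear
#'   function of agriculture cover.
#' @param spear_intercept,beta_spear_arable upstream SPEAR (%) as a linear
#'   function of arable cover (slope negative).
#' @param b_up_oligo,b_down_oligo slopes of upstream / downstream
#'   oligochaete share on upstream Saprobic Index (opposite signs).
#' @param oligo_up_base,oligo_down_base oligochaete share at the reference
#'   saprobity `si_ref`.
#' @param si_ref reference Saprobic Index about which oligochaete slopes
#'   pivot.
#' @param gamma_spear_df downstream SPEAR depression (percentage points) per
#'   unit wastewater fraction.
#' @param sigma_si,sigma_spear,sigma_spear_delta,sigma_oligo stream-level
#'   standard deviations of the descriptor targets.
#' @param dispersion negative-binomial size parameter of the count noise
#'   (`Inf` switches noise off: counts equal rounded expectations).
#' @param total_count expected total count per sampling location.
#' @param sigma_chem,sigma_habitat log-scale noise of the chemistry and
#'   habitat covariates.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `"simParams"`.
#' @examples
#' p <- simParams(n_streams = 3, n_taxa = 12, seed = 1)
#' @export
simParams <- function(n_streams = 12, n_taxa = 60,
                      agriculture_range = c(0.05, 0.80),
                      ww_fraction_range = c(0.23, 1.33),
                      si_intercept = 1.75, beta_si_agri = 0.45,
                      spear_intercept = 52, beta_spear_arable = -40,
                      b_up_oligo = 0.468, b_down_oligo = -1.40,
                      oligo_up_base = 0.10, oligo_down_base = 0.35,
                      si_ref = 1.94,
                      gamma_spear_df = 17,
                      sigma_si = 0.12, sigma_spear = 3.5,
                      sigma_spear_delta = 0.8, sigma_oligo = 0.03,
                      dispersion = 100, total_count = 2000,
                      sigma_chem = 0.6, sigma_habitat = 0.25,
                      seed = 1) {
  p <- as.list(environment())
  chk_range <- function(r, name, lo = 0, hi = Inf) {
    if (length(r) != 2 || anyNA(r) || r[1] > r[2]) {
      stop(sprintf("'%s' must be an ordered pair low <= high", name),
           call. = FALSE)
    }
    if (r[1] < lo || r[2] > hi) {
      stop(sprintf("'%s' out of admissible bounds", name), call. = FALSE)
    }
  }
  chk_range(p$agriculture_range, "agriculture_range", 0, 1)
  chk_range(p$ww_fraction_range, "ww_fraction_range", 0, Inf)
  if (!is.numeric(n_taxa) || n_taxa < 10) {
    stop("'n_taxa' must be at least 10", call. = FALSE)
  }
  if (!is.numeric(n_streams) || n_streams < 2) {
    stop("'n_streams' must be at least 2", call. = FALSE)
  }
  for (nm in c("sigma_si", "sigma_spear", "sigma_spear_delta", "sigma_oligo",
               "sigma_chem", "sigma_habitat")) {
    if (p[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  }
  stopifnot_scalar_pos(total_count, "total_count")
  if (!(is.numeric(dispersion) && length(dispersion) == 1 &&
        (is.infinite(dispersion) || dispersion > 0))) {
    stop("'dispersion' must be positive (Inf for noiseless counts)",
         call. = FALSE)
  }
  p$n_streams <- as.integer(n_streams)
  p$n_taxa <- as.integer(n_taxa)
  class(p) <- "simParams"
  p
}

#' @export
print.simParams <- function(x, ...) {
  cat("Synthetic stream-network parameters:\n")
  cat(sprintf("  %d streams x 3 locations, %d taxa, seed %s\n",
              x$n_streams, x$n_taxa, format(x$seed)))
  cat(sprintf("  agriculture %g-%g, ww fraction %g-%g, gamma_spear_df %g\n",
              x$agriculture_range[1], x$agriculture_range[2],
              x$ww_fraction_range[1], x$ww_fraction_range[2],
              x$gamma_spear_df))
  invisible(x)
}

.check_params <- function(params) {
  if (!inherits(params, "simParams")) {
    stop("'params' must be created by simParams()", call. = FALSE)
  }
  params
}

#' Generate the per-taxon trait table
#'
#' Taxa fall into four ecological roles: oligochaete worms (high saprobic
#' values near 3.5, thriving under organic enrichment), a block of
#' pesticide-sensitive SPEAR taxa that are also EPT insects (low saprobic
#' values), tolerant chironomid/gammarid-like taxa, and a background block
#' of intermediate taxa. Saprobic indicator weights are integers 1--5.
#'
#' @param params a [simParams()] object.
#' @return data.frame with columns `taxon`, `group`, `saprobic`, `weight`,
#'   `spear`, `ept`, `oligochaete`.
#' @export
simulateTraits <- function(params) {
  params <- .check_params(params)
  n <- params$n_taxa
  n_oli <- max(2L, round(0.05 * n))
  n_spe <- max(2L, round(0.35 * n))
  n_tol <- max(2L, round(0.20 * n))
  n_oth <- n - n_oli - n_spe - n_tol
  if (n_oth < 1L) stop("'n_taxa' too small for the four trait groups",
                       call. = FALSE)
  withSeed(params$seed, {
    group <- rep(c("oligochaete", "spear_ept", "tolerant", "other"),
                 c(n_oli, n_spe, n_tol, n_oth))
    saprobic <- c(runif(n_oli, 3.3, 3.7),
                  runif(n_spe, 1.2, 2.0),
                  runif(n_tol, 2.6, 3.2),
                  runif(n_oth, 1.7, 2.3))
    weight <- sample(1:5, n, replace = TRUE,
                     prob = c(0.10, 0.20, 0.30, 0.25, 0.15))
    ept <- group == "spear_ept"
    # a few EPT families that are not pesticide-sensitive
    idx_oth <- which(group == "other")
    ept[idx_oth[seq_len(max(1L, round(0.1 * n_oth)))]] <- TRUE
    data.frame(taxon = sprintf("t%03d", seq_len(n)),
               group = group,
               saprobic = round(saprobic, 3),
               weight = as.integer(weight),
               spear = group == "spear_ept",
               ept = ept,
               oligochaete = group == "oligochaete",
               stringsAsFactors = FALSE)
  })
}

#' Generate the per-location site table
#'
#' Lays `n_streams` streams on a coarse spatial grid (between-stream
#' distances of tens of kilometres; within-stream locations co-linear and
#' about 200 m apart), assigns the agriculture and wastewater-fraction
#' gradients as evenly spaced spans (endpoints exact, order randomized),
#' and simulates 20 water-chemistry and 17 habitat covariates. Chemistry at
#' the downstream location D increases with the wastewater fraction and
#' carries a stream-specific effluent-quality factor; habitat differs only
#' slightly and randomly between locations.
#'
#' @param params a [simParams()] object.
#' @return data.frame with one row per location: design columns (`location`,
#'   `stream`, `position`, `x`, `y`), land use (`agriculture`, `arable`,
#'   `pasture`), discharges (`q347`, `q_ww`), chemistry and habitat columns.
#' @export
simulateSites <- function(params) {
  params <- .check_params(params)
  ns <- params$n_streams
  withSeed(if (is.null(params$seed)) NULL else params$seed + 1L, {
    agri <- sample(seq(params$agriculture_range[1],
                       params$agriculture_range[2], length.out = ns))
    wwfrac <- sample(seq(params$ww_fraction_range[1],
                         params$ww_fraction_range[2], length.out = ns))
    arable_share <- runif(ns, 0.2, 0.8)
    arable <- agri * arable_share
    pasture <- agri - arable
    q347 <- exp(rnorm(ns, log(0.3), 0.4))
    q_ww <- wwfrac * q347

    # stream outlets on a coarse grid, reaches co-linear upstream of D
    gx <- ((seq_len(ns) - 1) %% 4) * 20000 + runif(ns, -3000, 3000)
    gy <- ((seq_len(ns) - 1) %/% 4) * 20000 + runif(ns, -3000, 3000)
    theta <- runif(ns, 0, 2 * pi)

    stream_ids <- sprintf("s%02d", seq_len(ns))
    des <- expand.grid(position = .POSITIONS, stream = stream_ids,
                       stringsAsFactors = FALSE)[, c("stream", "position")]
    des <- des[order(des$stream), ]
    s_idx <- match(des$stream, stream_ids)
    updist <- c(U2 = 400, U1 = 200, D = 0)[des$position]
    sites <- data.frame(
      location = paste(des$stream, des$position, sep = "_"),
      stream = des$stream,
      position = des$position,
      x = gx[s_idx] + updist * cos(theta[s_idx]),
      y = gy[s_idx] + updist * sin(theta[s_idx]),
      agriculture = agri[s_idx],
      arable = arable[s_idx],
      pasture = pasture[s_idx],
      q347 = q347[s_idx],
      q_ww = q_ww[s_idx],
      stringsAsFactors = FALSE)

    n_loc <- nrow(sites)
    is_d <- sites$position == "D"

    # chemistry: log-linear in agriculture; D adds dilution-scaled and
    # effluent-quality terms
    chem_base <- c(conductivity = 400, ph = 8, alkalinity = 3, hardness = 2.5,
                   nh4 = 20, no2 = 10, tp = 40, srp = 25, no3 = 2.5,
                   totn = 3.5, sio4 = 3, na = 8, k = 2, ca = 70, mg = 10,
                   cl = 12, so4 = 15, toc = 3, doc = 2.5, tss = 5)
    a_agri <- ifelse(.CHEM_VARS %in% c("nh4", "no2", "tp", "srp", "no3",
                                       "totn", "tss"), 1.5, 0.1)
    l_ww <- ifelse(.CHEM_VARS %in% .CHEM_WW, runif(20, 0.5, 0.9), 0)
    w_df <- ifelse(.CHEM_VARS %in% .CHEM_WW, runif(20, 0.2, 0.5), 0.05)
    effluent_q <- rnorm(ns)
    chem <- matrix(NA_real_, n_loc, 20, dimnames = list(NULL, .CHEM_VARS))
    for (v in seq_len(20)) {
      lg <- log(chem_base[v]) + a_agri[v] * sites$agriculture +
        is_d * (w_df[v] * (sites$q_ww / sites$q347) +
                  l_ww[v] * effluent_q[s_idx]) +
        rnorm(n_loc, 0, params$sigma_chem)
      chem[, v] <- exp(lg)
    }

    # habitat: stream-level baseline, small location noise, a random
    # wastewater-associated shift at D
    hab_base <- c(bedrock = 2, boulder = 10, cobble = 30, gravel = 30,
                  sand = 15, mud = 8, tss_total = 1.5, tss_inorganic = 1.0,
                  oss_pct = 30, cpom = 5, algae = 10, bryophytes = 5,
                  submerged_macrophytes = 8, emergent_macrophytes = 3,
                  flow = 0.4, width = 4, depth = 0.25)
    nh <- length(.HABITAT_VARS)
    m_ww <- ifelse(.HABITAT_VARS %in% .HABITAT_WW, runif(nh, 0.4, 1.0), 0.15)
    delta_hab <- rnorm(ns, 0, 1)
    stream_hab <- matrix(rnorm(ns * nh, 0, 0.3), ns, nh)
    hab <- matrix(NA_real_, n_loc, nh, dimnames = list(NULL, .HABITAT_VARS))
    for (v in seq_len(nh)) {
      lg <- log(hab_base[v]) + stream_hab[s_idx, v] +
        is_d * params$sigma_habitat * m_ww[v] * delta_hab[s_idx] +
        rnorm(n_loc, 0, 0.1)
      hab[, v] <- exp(lg)
    }
    cbind(sites, as.data.frame(chem), as.data.frame(hab))
  })
}

# Solve the four group shares so that the package's own index formulas,
# applied to the expected counts, hit the descriptor targets. The
# oligochaete share is fixed by the enrichment model; the SPEAR-taxon
# share `phi` is solved against the (log-damped) SPEAR index target and,
# upstream, the tolerant/other split `q` against the Saprobic Index
# target. Downstream reuses the upstream `q`, so the downstream saprobic
# shift emerges from oligochaete enrichment alone while the SPEAR index
# hits its own target independently of the crowding.
.solve_shares <- function(traits, prof, oligo_sh, spear_target,
                          si_target = NULL, q_fixed = NULL, total = 1000) {
  grp <- traits$group
  mk <- function(phi, q) {
    rest <- 1 - oligo_sh - phi
    sh <- c(oligochaete = oligo_sh, spear_ept = phi,
            tolerant = q * rest, other = (1 - q) * rest)
    sh[grp] * prof
  }
  phi_max <- 1 - oligo_sh - 0.02
  phi <- clamp(spear_target / 100, 0.005, phi_max)
  q <- if (is.null(q_fixed)) 0.5 else q_fixed
  for (it in 1:30) {
    if (is.null(q_fixed)) {
      f <- function(qq) {
        saprobicIndex(mk(phi, qq) * total, traits) - si_target
      }
      q <- if (f(0.01) >= 0) 0.01
      else if (f(0.99) <= 0) 0.99
      else stats::uniroot(f, c(0.01, 0.99), tol = 1e-9)$root
    }
    g <- function(pp) spearIndex(mk(pp, q) * total, traits) - spear_target
    phi_new <- if (g(0.005) >= 0) 0.005
    else if (g(phi_max) <= 0) phi_max
    else stats::uniroot(g, c(0.005, phi_max), tol = 1e-10)$root
    done <- abs(phi_new - phi) < 1e-9
    phi <- phi_new
    if (done) break
  }
  list(shares = mk(phi, q), q = q)
}

# Expected (noise-free unless stream-level noise supplied) taxon
# compositions for every location. Returns a locations x taxa matrix of
# expected counts. `noise` is a list of per-stream deviations on the
# descriptor scale; zeros give the generator's ground-truth expectations.
.expectedCounts <- function(sites, traits, params, noise = NULL) {
  ns <- length(unique(sites$stream))
  streams <- sort(unique(sites$stream))
  if (is.null(noise)) {
    z <- numeric(ns)
    noise <- list(e_si = z, e_spear = z, e_spear_d = z,
                  e_oligo_u = z, e_oligo_d = z)
  }
  if (nrow(traits) != params$n_taxa) {
    stop("trait table size does not match 'params$n_taxa'", call. = FALSE)
  }
  grp <- traits$group
  # fixed geometric rank-abundance profile within each group
  prof <- numeric(nrow(traits))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    w <- 0.5^(seq_along(idx) - 1)
    prof[idx] <- w / sum(w)
  }
  mu <- matrix(0, nrow(sites), nrow(traits),
               dimnames = list(sites$location, traits$taxon))
  q_up <- stats::setNames(rep(NA_real_, ns), streams)
  ord <- order(sites$position == "D") # solve upstream rows first
  for (i in seq_len(nrow(sites))[ord]) {
    si <- match(sites$stream[i], streams)
    agri <- sites$agriculture[i]
    arable <- sites$arable[i]
    wwfrac <- sites$q_ww[i] / sites$q347[i]
    at_d <- sites$position[i] == "D"

    si_t <- params$si_intercept + params$beta_si_agri * agri +
      noise$e_si[si]
    spear_u <- clamp(params$spear_intercept +
                       params$beta_spear_arable * arable +
                       noise$e_spear[si], 3, 95)
    spear_t <- if (at_d) {
      clamp(spear_u - params$gamma_spear_df * wwfrac +
              noise$e_spear_d[si], 3, 95)
    } else spear_u
    oligo_t <- if (at_d) {
      clamp(params$oligo_down_base +
              params$b_down_oligo * (si_t - params$si_ref) +
              noise$e_oligo_d[si], 0.01, 0.80)
    } else {
      clamp(params$oligo_up_base +
              params$b_up_oligo * (si_t - params$si_ref) +
              noise$e_oligo_u[si], 0.01, 0.80)
    }
    sol <- .solve_shares(traits, prof, oligo_t, spear_t,
                         si_target = if (at_d) NULL else si_t,
                         q_fixed = if (at_d) q_up[[si]] else NULL,
                         total = params$total_count)
    if (!at_d) q_up[[si]] <- sol$q
    mu[i, ] <- sol$shares * params$total_count
  }
  mu
}

#' Generate the abundance table
#'
#' Draws negative-binomial counts around expected compositions built from
#' the descriptor-scale gradients: upstream communities tilt toward
#' saprobic-tolerant taxa with agriculture and away from SPEAR taxa with
#' arable cover; at the downstream location the oligochaete share rises
#' (more where upstream saprobity is low) and the SPEAR share drops in
#' proportion to the wastewater fraction.
#'
#' @param sites site table from [simulateSites()].
#' @param traits trait table from [simulateTraits()].
#' @param params a [simParams()] object.
#' @return locations-by-taxa integer matrix with dimnames.
#' @export
simulateAbundances <- function(sites, traits, params) {
  params <- .check_params(params)
  if (!all(c("stream", "position", "agriculture", "arable",
             "q347", "q_ww") %in% colnames(sites))) {
    stop("'sites' is missing required columns", call. = FALSE)
  }
  ns <- length(unique(sites$stream))
  withSeed(if (is.null(params$seed)) NULL else params$seed + 2L, {
    noise <- list(
      e_si = rnorm(ns, 0, params$sigma_si),
      e_spear = rnorm(ns, 0, params$sigma_spear),
      e_spear_d = rnorm(ns, 0, params$sigma_spear_delta),
      e_oligo_u = rnorm(ns, 0, params$sigma_oligo),
      e_oligo_d = rnorm(ns, 0, params$sigma_oligo))
    mu <- .expectedCounts(sites, traits, params, noise)
    counts <- mu
    if (is.finite(params$dispersion)) {
      counts[] <- stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = params$dispersion)
    } else {
      counts[] <- round(mu)
    }
    storage.mode(counts) <- "integer"
    counts
  })
}

#' Ground truth of the generator
#'
#' Returns the noiseless expectations behind [simulateAbundances()]:
#' per-stream expected upstream Saprobic Index and SPEAR values, expected
#' null-corrected changes (the two upstream locations share one
#' expectation, so the expected null change is zero), and the labels of the
#' predictors that truly drive each change response.
#'
#' Descriptor expectations are computed by applying the package's own index
#' formulas to the expected compositions, so on noise-free data the
#' pipeline recovers them exactly.
#'
#' @param params a [simParams()] object.
#' @return list with `streams` (data.frame of per-stream expectations) and
#'   `dominant_predictor` (named character vector for `d_spear`,
#'   `d_saprobic`).
#' @export
groundTruth <- function(params) {
  params <- .check_params(params)
  traits <- simulateTraits(params)
  sites <- simulateSites(params)
  mu <- .expectedCounts(sites, traits, params)
  si <- apply(mu, 1, saprobicIndex, traits = traits)
  sp <- apply(mu, 1, spearIndex, traits = traits)
  streams <- sort(unique(sites$stream))
  pos <- function(p) match(paste(streams, p, sep = "_"), rownames(mu))
  u1 <- pos("U1"); u2 <- pos("U2"); d <- pos("D")
  df <- data.frame(
    stream = streams,
    ww_fraction = (sites$q_ww / sites$q347)[match(streams, sites$stream)],
    si_upstream = si[u1],
    spear_upstream = sp[u1],
    d_saprobic = (si[d] - si[u1]) - (si[u1] - si[u2]),
    d_spear = (sp[d] - sp[u1]) - (sp[u1] - sp[u2]),
    row.names = NULL)
  dominant <- c(
    d_spear = if (params$gamma_spear_df != 0) "DF_ww" else "none",
    d_saprobic = if (params$b_down_oligo != params$b_up_oligo)
      "upstream_composition" else "none")
  list(streams = df, dominant_predictor = dominant)
}

#' Simulate a complete survey
#'
#' Convenience wrapper producing a validated [StreamExperiment] with the
#' ground truth and generator parameters attached as metadata.
#'
#' @param params a [simParams()] object.
#' @return a \linkS4class{StreamExperiment}.
#' @examples
#' se <- simulateStreams(simParams(n_streams = 4, n_taxa = 20, seed = 3))
#' se
#' @export
simulateStreams <- function(params) {
  params <- .check_params(params)
  traits <- simulateTraits(params)
  sites <- simulateSites(params)
  counts <- simulateAbundances(sites, traits, params)
  se <- StreamExperiment(counts, traits, sites)
  S4Vectors::metadata(se)$params <- params
  S4Vectors::metadata(se)$ground_truth <- groundTruth(params)
  se
}
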