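# Flat-file interchange: the three survey tables as CSV, plus config
# snapshots.

#' Write a survey to CSV tables
#'
#' Writes `abundance.csv` (locations x taxa, wide), `traits.csv` (one row
#' per taxon) and `sites.csv` (one row per location) into `dir`. When the
#' experiment carries generator metadata, the ground truth and a parameter
#' snapshot are written as well (`ground_truth.csv`, `params.yaml` when the
#' yaml package is installed, else `params.json`-style `dput`).
#'
#' @param se a [StreamExperiment].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeStreamTables <- function(se, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ab <- as.data.frame(abundanceTable(se))
  ab <- cbind(location = rownames(ab), ab)
  tr <- traitTable(se)
  if (!"taxon" %in% colnames(tr)) tr <- cbind(taxon = rownames(tr), tr)
  st <- siteTable(se)
  if (!"location" %in% colnames(st)) st <- cbind(location = rownames(st), st)
  paths <- file.path(dir, c("abundance.csv", "traits.csv", "sites.csv"))
  utils::write.csv(ab, paths[1], row.names = FALSE)
  utils::write.csv(tr, paths[2], row.names = FALSE)
  utils::write.csv(st, paths[3], row.names = FALSE)
  md <- S4Vectors::metadata(se)
  if (!is.null(md$ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.csv")
    utils::write.csv(md$ground_truth$streams, gt_path, row.names = FALSE)
    paths <- c(paths, gt_path)
  }
  if (!is.null(md$params)) {
    p <- md$params
    if (requireNamespace("yaml", quietly = TRUE)) {
      pp <- file.path(dir, "params.yaml")
      yaml::write_yaml(unclass(p), pp)
    } else {
      pp <- file.path(dir, "params.R")
      dput(unclass(p), pp)
    }
    paths <- c(paths, pp)
  }
  invisible(paths)
}

#' Read a survey from CSV tables
#'
#' Counterpart of [writeStreamTables()]: reads the three tables from `dir`
#' (or from explicitly named files) and assembles a validated
#' [StreamExperiment].
#'
#' @param dir directory holding `abundance.csv`, `traits.csv`, `sites.csv`.
#' @param abundance,traits,sites optional explicit file paths overriding
#'   `dir`.
#' @return a [StreamExperiment].
#' @export
readStreamTables <- function(dir = NULL, abundance = NULL, traits = NULL,
                             sites = NULL) {
  if (!is.null(dir)) {
    abundance <- abundance %||% file.path(dir, "abundance.csv")
    traits <- traits %||% file.path(dir, "traits.csv")
    sites <- sites %||% file.path(dir, "sites.csv")
  }
  for (f in c(abundance, traits, sites)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  ab <- utils::read.csv(abundance, check.names = FALSE)
  rownames(ab) <- ab$location
  ab$location <- NULL
  tr <- utils::read.csv(traits)
  st <- utils::read.csv(sites, check.names = FALSE)
  StreamExperiment(as.matrix(ab), tr, st)
}
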