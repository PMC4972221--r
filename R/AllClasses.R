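#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' StreamExperiment: community counts with traits and site design
#'
#' An S4 container for a replicated upstream/downstream stream survey:
#' a taxa-by-location count matrix (assay \code{"counts"}), per-taxon trait
#' attributes in \code{rowData} and per-location design, spatial,
#' hydrological and environment variables in \code{colData}. Extends
#' \linkS4class{SummarizedExperiment}, so all its accessors and subsetting
#' semantics apply.
#'
#' Required \code{rowData} columns: \code{saprobic} (saprobic value in
#' \[1, 4\], or \code{NA} for unscored taxa), \code{weight} (saprobic
#' indicator weight, integer 1-5), and logical flags \code{spear},
#' \code{ept}, \code{oligochaete}. Required \code{colData} columns:
#' \code{stream} and \code{position} (one of \code{"U2"}, \code{"U1"},
#' \code{"D"}: two upstream reference reaches and one reach below the
#' wastewater outfall).
#'
#' @aliases StreamExperiment-class
#' @exportClass StreamExperiment
setClass("StreamExperiment", contains = "SummarizedExperiment")

.POSITIONS <- c("U2", "U1", "D")

setValidity("StreamExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cts)) msg <- c(msg, "counts contain missing values")
    else {
      if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(abs(cts - round(cts)) > 1e-8)) {
        msg <- c(msg, "counts must be integers")
      }
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  need_rd <- c("saprobic", "weight", "spear", "ept", "oligochaete")
  miss <- setdiff(need_rd, colnames(rd))
  if (length(miss)) {
    msg <- c(msg, paste0("missing rowData columns: ",
                         paste(miss, collapse = ", ")))
  } else {
    s <- rd$saprobic
    if (any(!is.na(s) & (s < 1 | s > 4))) {
      msg <- c(msg, "saprobic values must lie in [1, 4]")
    }
    g <- rd$weight
    if (any(!is.na(g) & (g < 1 | abs(g - round(g)) > 1e-8))) {
      msg <- c(msg, "saprobic weights must be integers >= 1")
    }
    for (fl in c("spear", "ept", "oligochaete")) {
      if (!is.logical(rd[[fl]])) msg <- c(msg, paste0("'", fl, "' must be logical"))
    }
  }
  cd <- SummarizedExperiment::colData(object)
  need_cd <- c("stream", "position")
  miss <- setdiff(need_cd, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("missing colData columns: ",
                         paste(miss, collapse = ", ")))
  } else if (!all(cd$position %in% .POSITIONS)) {
    msg <- c(msg, "position must be one of 'U2', 'U1', 'D'")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "taxa must have unique identifiers (rownames)")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "locations must have unique identifiers (colnames)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StreamExperiment
#'
#' Assembles the three flat survey tables into a validated
#' \linkS4class{StreamExperiment}. The abundance table is location-by-taxon
#' (the orientation community ecologists exchange as CSV); it is stored
#' transposed, taxa-by-location, following SummarizedExperiment convention.
#'
#' @param abundance numeric matrix or data frame of non-negative integer
#'   counts, locations in rows, taxa in columns; row and column names are
#'   required and must match `sites` and `traits`.
#' @param traits data frame keyed by taxon (rownames or a `taxon` column)
#'   with columns `saprobic`, `weight`, `spear`, `ept`, `oligochaete`.
#' @param sites data frame keyed by location (rownames or a `location`
#'   column) with at least `stream` and `position` columns.
#' @return A \linkS4class{StreamExperiment}.
#' @examples
#' p <- simParams(n_streams = 3, n_taxa = 12, seed = 1)
#' se <- simulateStreams(p)
#' se
#' @export
StreamExperiment <- function(abundance, traits, sites) {
  abundance <- as.matrix(abundance)
  traits <- as.data.frame(traits)
  sites <- as.data.frame(sites)
  if ("taxon" %in% colnames(traits) && is.null(rownames(traits))) {
    rownames(traits) <- traits$taxon
  }
  if (!is.null(traits$taxon)) rownames(traits) <- traits$taxon
  if (!is.null(sites$location)) rownames(sites) <- sites$location
  if (is.null(colnames(abundance)) || is.null(rownames(abundance))) {
    stop("abundance table needs location rownames and taxon colnames",
         call. = FALSE)
  }
  unknown <- setdiff(colnames(abundance), rownames(traits))
  if (length(unknown)) {
    stop("abundance columns without trait records: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(rownames(abundance), rownames(sites))
  if (length(unknown)) {
    stop("abundance rows without site records: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  traits <- traits[colnames(abundance), , drop = FALSE]
  sites <- sites[rownames(abundance), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(abundance)),
    rowData = S4Vectors::DataFrame(traits),
    colData = S4Vectors::DataFrame(sites)
  )
  new("StreamExperiment", se)
}

#' @rdname StreamExperiment
#' @param object,x a \code{StreamExperiment}.
#' @export
setGeneric("abundanceTable", function(x) standardGeneric("abundanceTable"))

#' @describeIn StreamExperiment location-by-taxon count matrix.
#' @export
setMethod("abundanceTable", "StreamExperiment", function(x) {
  t(SummarizedExperiment::assay(x, "counts"))
})

#' @rdname StreamExperiment
#' @export
setGeneric("traitTable", function(x) standardGeneric("traitTable"))

#' @describeIn StreamExperiment per-taxon trait data frame.
#' @export
setMethod("traitTable", "StreamExperiment", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname StreamExperiment
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @describeIn StreamExperiment per-location site data frame.
#' @export
setMethod("siteTable", "StreamExperiment", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @describeIn StreamExperiment compact summary.
#' @export
setMethod("show", "StreamExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("StreamExperiment:", nrow(object), "taxa x", ncol(object),
      "sampling locations\n")
  cat("  streams:", length(unique(cd$stream)),
      " positions:", paste(levels(factor(cd$position, .POSITIONS)),
                           collapse = "/"), "\n")
  rd <- SummarizedExperiment::rowData(object)
  cat("  SPEAR taxa:", sum(rd$spear), " EPT taxa:", sum(rd$ept),
      " oligochaetes:", sum(rd$oligochaete), "\n")
  invisible(NULL)
})

#' HierPartResult: hierarchical partitioning of regression variance
#'
#' Holds per-predictor independent (\code{I}) and joint (\code{J})
#' contributions to explained variance from all-subsets regression,
#' their percentage contributions, and (when randomization was run)
#' Z-scores with significance at the upper 95% confidence limit
#' (Z > 1.65).
#'
#' @slot effects data.frame with columns \code{I}, \code{J}, \code{total},
#'   \code{pct_I}, and optionally \code{Z}, \code{significant}.
#' @slot r2_full full-model R-squared.
#' @slot n_randomizations number of randomizations (0 if none).
#' @aliases HierPartResult-class
#' @exportClass HierPartResult
setClass("HierPartResult",
  representation(effects = "data.frame",
                 r2_full = "numeric",
                 n_randomizations = "integer"))

#' @describeIn HierPartResult Table-style summary ordered by independent
#'   contribution.
#' @param object a \code{HierPartResult}.
#' @export
setMethod("show", "HierPartResult", function(object) {
  cat("Hierarchical partitioning (", nrow(object@effects),
      " predictors, full-model R2 = ", sprintf("%.3f", object@r2_full),
      ")\n", sep = "")
  eff <- object@effects[order(-object@effects$pct_I), , drop = FALSE]
  print(round(as.data.frame(eff), 3))
  if (object@n_randomizations > 0L) {
    cat("Z-scores from", object@n_randomizations,
        "randomizations; significant at Z > 1.65\n")
  }
  invisible(NULL)
})

#' @describeIn HierPartResult extract the effects table.
#' @param x a \code{HierPartResult}.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "HierPartResult", function(x, ...) x@effects)
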