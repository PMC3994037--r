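#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels Seqinfo seqinfo
#'   seqlevelsInUse keepSeqlevels genome
#' @importFrom stats ppois rpois runif setNames wilcox.test
#' @importFrom utils read.table write.table
NULL

#' Co-binding class labels
#'
#' The four combinatorial co-occupancy categories of a Rest binding site:
#' `R+/S+/L+` (Sin3A and Lsd1 both co-bound), `R+/S+/L-` (Sin3A only),
#' `R+/S-/L+` (Lsd1 only) and `R+/S-/L-` (Rest alone).
#'
#' @return Character vector of the four class labels, in canonical order.
#' @export
#' @examples
#' cobindClasses()
cobindClasses <- function() {
  c("R+/S+/L+", "R+/S+/L-", "R+/S-/L+", "R+/S-/L-")
}

## ---- ClassifiedSites --------------------------------------------------------

#' Rest binding sites annotated with co-binding class
#'
#' A [GenomicRanges::GRanges] subclass holding Rest peaks from one cell state,
#' each annotated with its Sin3A/Lsd1 co-binding class, partner-peak counts
#' and (after [compareCells()]) its cross-cell specificity. Metadata columns:
#' `cobind` (one of [cobindClasses()]), `nSin3a`, `nLsd1` (number of
#' overlapping partner peaks), `specificity` (`"unique"`, `"common"` or `NA`
#' before comparison), plus any columns carried over from the peak calls
#' (`pvalue`, `summit`).
#'
#' @slot cell Single string naming the cell state the sites were called in
#'   (e.g. `"ES"` or `"EpiS"`).
#'
#' @seealso [classifyCobinding()], [dropRestOnly()], [compareCells()]
#' @export
setClass("ClassifiedSites",
  contains = "GRanges",
  representation(cell = "character"),
  prototype(cell = NA_character_)
)

setValidity("ClassifiedSites", function(object) {
  msg <- character()
  if (length(object@cell) != 1L)
    msg <- c(msg, "'cell' must be a single string")
  mc <- S4Vectors::mcols(object)
  need <- c("cobind", "nSin3a", "nLsd1", "specificity")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    msg <- c(msg, paste0("missing metadata columns: ",
                         paste(miss, collapse = ", ")))
  if (!length(miss) && length(object)) {
    if (!all(mc$cobind %in% cobindClasses()))
      msg <- c(msg, "'cobind' values must be one of cobindClasses()")
    sPlus <- mc$nSin3a > 0L
    lPlus <- mc$nLsd1 > 0L
    expect <- paste0("R+/S", ifelse(sPlus, "+", "-"),
                     "/L", ifelse(lPlus, "+", "-"))
    if (!all(mc$cobind == expect))
      msg <- c(msg, "'cobind' inconsistent with partner-peak counts")
    bad <- !(is.na(mc$specificity) | mc$specificity %in% c("unique", "common"))
    if (any(bad))
      msg <- c(msg, "'specificity' must be 'unique', 'common' or NA")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ClassifiedSites-class Cell state the sites belong to.
#' @param x A `ClassifiedSites` object.
#' @export
cellState <- function(x) {
  stopifnot(is(x, "ClassifiedSites"))
  x@cell
}

#' @describeIn ClassifiedSites-class Co-binding class label per site.
#' @export
cobindClass <- function(x) {
  stopifnot(is(x, "ClassifiedSites"))
  S4Vectors::mcols(x)$cobind
}

#' @describeIn ClassifiedSites-class Cross-cell specificity per site
#'   (`"unique"`/`"common"`, `NA` before [compareCells()]).
#' @export
siteSpecificity <- function(x) {
  stopifnot(is(x, "ClassifiedSites"))
  S4Vectors::mcols(x)$specificity
}

setMethod("show", "ClassifiedSites", function(object) {
  cat("ClassifiedSites with", length(object), "sites in cell",
      sQuote(object@cell), "\n")
  if (length(object)) {
    tab <- table(factor(cobindClass(object), levels = cobindClasses()))
    cat("  classes:",
        paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
    sp <- siteSpecificity(object)
    if (!all(is.na(sp))) {
      st <- table(sp, useNA = "ifany")
      cat("  specificity:",
          paste(names(st), st, sep = "=", collapse = "  "), "\n")
    }
  }
  invisible(callNextMethod())
})

## ---- TssClusters ------------------------------------------------------------

#' Clusters of TSS-seq tags in fixed 500-base bins
#'
#' A [GenomicRanges::GRanges] subclass in which each range is one non-empty
#' fixed genomic bin on one strand, with metadata columns `tagCount` (tags in
#' the bin), `ppm` (tags per million library tags), `gene` (associated gene id
#' or `NA`) and `novelLnc` (intergenic cluster above the ppm cutoff with no
#' gene association).
#'
#' @slot librarySize Total number of TSS tags in the library that the `ppm`
#'   values were computed against.
#'
#' @seealso [clusterTssTags()], [identifyNovelLncTscs()]
#' @export
setClass("TssClusters",
  contains = "GRanges",
  representation(librarySize = "numeric"),
  prototype(librarySize = NA_real_)
)

setValidity("TssClusters", function(object) {
  msg <- character()
  if (length(object@librarySize) != 1L || is.na(object@librarySize) ||
      object@librarySize <= 0)
    msg <- c(msg, "'librarySize' must be a single positive number")
  mc <- S4Vectors::mcols(object)
  need <- c("tagCount", "ppm", "gene", "novelLnc")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    msg <- c(msg, paste0("missing metadata columns: ",
                         paste(miss, collapse = ", ")))
  if (!length(miss) && length(object)) {
    if (any(mc$tagCount < 1L))
      msg <- c(msg, "every cluster must contain at least one tag")
    expect <- 1e6 * mc$tagCount / object@librarySize
    if (any(abs(mc$ppm - expect) > 1e-8 * pmax(expect, 1)))
      msg <- c(msg, "'ppm' inconsistent with tagCount/librarySize")
    if (any(mc$novelLnc & !is.na(mc$gene)))
      msg <- c(msg, "novel lncRNA clusters cannot carry a gene association")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TssClusters-class TSS library size used for ppm.
#' @param x A `TssClusters` object.
#' @export
librarySize <- function(x) {
  stopifnot(is(x, "TssClusters"))
  x@librarySize
}

#' @describeIn TssClusters-class Tag count per cluster.
#' @export
tagCount <- function(x) {
  stopifnot(is(x, "TssClusters"))
  S4Vectors::mcols(x)$tagCount
}

#' @describeIn TssClusters-class Tags per million per cluster.
#' @export
tagPpm <- function(x) {
  stopifnot(is(x, "TssClusters"))
  S4Vectors::mcols(x)$ppm
}

setMethod("show", "TssClusters", function(object) {
  cat("TssClusters with", length(object), "clusters",
      sprintf("(library size %g)\n", object@librarySize))
  if (length(object)) {
    cat(sprintf("  tags: total %d; novel lncRNA clusters: %d\n",
                sum(tagCount(object)),
                sum(S4Vectors::mcols(object)$novelLnc)))
  }
  invisible(callNextMethod())
})

## ---- SignalProfile ----------------------------------------------------------

#' Per-site chromatin signal matrix around site anchors
#'
#' Holds an input-normalized signal matrix: one row per site, one column per
#' base offset from the site anchor (summit when available, interval midpoint
#' otherwise), spanning `-halfWidth ... +halfWidth`.
#'
#' @slot values Numeric matrix, rows = sites (ordered by the sort key used at
#'   construction, by default descending site intensity), columns = offsets.
#' @slot offsets Integer vector of column offsets relative to the anchor.
#' @slot factorLabel Single string naming the profiled factor/mark.
#' @slot siteIds Character vector of row identifiers.
#' @slot padded Logical per row: `TRUE` where the window ran over a chromosome
#'   boundary and was zero-padded.
#'
#' @seealso [profileMatrix()], [thresholdMask()], [verticalSection()]
#' @export
setClass("SignalProfile",
  representation(
    values = "matrix",
    offsets = "integer",
    factorLabel = "character",
    siteIds = "character",
    padded = "logical"
  )
)

setValidity("SignalProfile", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@offsets))
    msg <- c(msg, "column count must equal number of offsets")
  if (nrow(object@values) != length(object@siteIds))
    msg <- c(msg, "row count must equal number of site ids")
  if (nrow(object@values) != length(object@padded))
    msg <- c(msg, "'padded' must have one entry per row")
  if (length(object@factorLabel) != 1L)
    msg <- c(msg, "'factorLabel' must be a single string")
  if (length(object@values) && any(object@values < 0))
    msg <- c(msg, "signal values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn SignalProfile-class The profile matrix (rows = sites, columns
#'   named by offset).
#' @param x A `SignalProfile` object.
#' @param ... Ignored.
#' @export
setMethod("as.matrix", "SignalProfile", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@siteIds, x@offsets)
  m
})

#' @describeIn SignalProfile-class Offsets of the matrix columns.
#' @export
profileOffsets <- function(x) {
  stopifnot(is(x, "SignalProfile"))
  x@offsets
}

setMethod("show", "SignalProfile", function(object) {
  cat(sprintf("SignalProfile for %s: %d sites x %d positions (%d..%+d)\n",
              sQuote(object@factorLabel), nrow(object@values),
              ncol(object@values), min(object@offsets), max(object@offsets)))
  invisible(NULL)
})

## ---- OverlapIndex -----------------------------------------------------------

#' Overlap-query index over a fixed set of genomic intervals
#'
#' Thin wrapper around a preprocessed [GenomicRanges::GNCList] that returns,
#' for a query interval, all stored intervals sharing at least one base with
#' it (strand ignored). Results are identical to a linear scan with
#' [intervalsOverlap()].
#'
#' @slot subject The indexed intervals.
#' @slot nclist Preprocessed nested containment list.
#'
#' @seealso [overlapIndex()], [queryOverlaps()]
#' @export
setClass("OverlapIndex",
  representation(subject = "GRanges", nclist = "ANY")
)

setMethod("show", "OverlapIndex", function(object) {
  cat("OverlapIndex over", length(object@subject), "intervals\n")
  invisible(NULL)
})

## ---- SummaryReport ----------------------------------------------------------

#' Pipeline summary report
#'
#' The end product of [runPipeline()]: the four analysis summary tables
#' (per-factor site/gene association counts; co-binding class composition;
#' cross-cell overlap; knock-down target rates), the per-stage intermediate
#' objects, and a provenance block (seed, parameter hash, package version).
#'
#' @slot tables Named list of data frames: `table1`, `table2`, `table3`,
#'   `table4`.
#' @slot details Named list of per-stage objects (classified sites, TSS
#'   clusters, target calls, ...), kept so downstream checks can drill in.
#' @slot provenance Named list: `seed`, `paramHash`, `packageVersion`.
#'
#' @seealso [runPipeline()], [emitTables()]
#' @export
setClass("SummaryReport",
  representation(tables = "list", details = "list", provenance = "list")
)

#' @describeIn SummaryReport-class Access one of the report tables.
#' @param x A `SummaryReport`.
#' @param name Table name (`"table1"` ... `"table4"`).
#' @export
reportTable <- function(x, name) {
  stopifnot(is(x, "SummaryReport"))
  if (!name %in% names(x@tables))
    stop("no such table: ", name)
  x@tables[[name]]
}

setMethod("show", "SummaryReport", function(object) {
  cat("SummaryReport\n")
  for (nm in names(object@tables)) {
    tb <- object@tables[[nm]]
    cat(sprintf("  %s: %d rows x %d cols\n", nm, nrow(tb), ncol(tb)))
  }
  cat("  seed:", object@provenance$seed,
      " param hash:", object@provenance$paramHash, "\n")
  invisible(NULL)
})
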