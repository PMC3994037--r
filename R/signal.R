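## Binding-intensity quantification, input-normalized signal profiles around
## site anchors, threshold masks, columnwise aggregation, paired signal
## comparison and conservation scoring.

## internal: anchor of a site = summit when present, interval midpoint
## otherwise
siteAnchor <- function(sites) {
  summit <- S4Vectors::mcols(sites)$summit
  mid <- as.integer((start(sites) + end(sites)) %/% 2)
  if (is.null(summit)) mid else ifelse(is.na(summit), mid, summit)
}

#' Input-normalized binding intensity of sites
#'
#' The ratio of ChIP to input tag counts inside each site, the input count
#' scaled by the library-size ratio, with a pseudocount on both numerator and
#' denominator to avoid division by zero at tag-sparse sites:
#' `(chip + c) / (input * nChip/nInput + c)`.
#'
#' @param chip,input Tag [GenomicRanges::GRanges].
#' @param sites [GenomicRanges::GRanges] (or [ClassifiedSites-class]).
#' @param pseudocount Pseudocount `c` (default 1).
#' @return Non-negative numeric vector, one intensity per site.
#' @export
siteIntensity <- function(chip, input, sites, pseudocount = 1) {
  stopifnot(is(sites, "GRanges"))
  if (!length(input)) stop("unusable sample: empty input tag set")
  cc <- GenomicRanges::countOverlaps(sites, chip, ignore.strand = TRUE)
  ic <- GenomicRanges::countOverlaps(sites, input, ignore.strand = TRUE)
  ratio <- length(chip) / length(input)
  (cc + pseudocount) / (ic * ratio + pseudocount)
}

#' Signal profile matrix around site anchors
#'
#' One row per site, spanning `-halfWidth ... +halfWidth` around the site
#' anchor (peak summit when available, interval midpoint otherwise). Each
#' position holds the extended-tag pileup, normalized per position by the
#' input pileup when input tags are given:
#' `(chip + c) / (input * nChip/nInput + c)`. Rows are ordered by decreasing
#' `sortBy` (by default the sites' own input-normalized intensity, so that
#' Rest-site profiles sort by descending Rest intensity). Windows running
#' over a chromosome boundary are zero-padded and flagged.
#'
#' @param sites [ClassifiedSites-class] or [GenomicRanges::GRanges].
#' @param chip Tag [GenomicRanges::GRanges] for the profiled factor.
#' @param input Optional input tag [GenomicRanges::GRanges]; when `NULL` the
#'   raw pileup is returned.
#' @param halfWidth Half window width in bases (default 500, giving 1001
#'   columns).
#' @param extension Fragment extension in bases (default 200).
#' @param pseudocount Pseudocount for the per-position normalization
#'   (default 1).
#' @param factorLabel Label stored on the profile (default `"chip"`).
#' @param sortBy Numeric sort key per site (descending); defaults to
#'   [siteIntensity()] of the provided tags at the sites when input is given,
#'   else the raw ChIP count.
#' @return A [SignalProfile-class] object.
#' @export
profileMatrix <- function(sites, chip, input = NULL, halfWidth = 500L,
                          extension = 200L, pseudocount = 1,
                          factorLabel = "chip", sortBy = NULL) {
  stopifnot(is(sites, "GRanges"))
  offsets <- seq.int(-halfWidth, halfWidth)
  n <- length(sites)
  ids <- if (!is.null(names(sites)) && all(nzchar(names(sites))))
    names(sites) else sprintf("site_%d", seq_len(n))
  if (is.null(sortBy)) {
    sortBy <- if (is.null(input))
      GenomicRanges::countOverlaps(sites, chip, ignore.strand = TRUE)
    else siteIntensity(chip, input, sites, pseudocount)
  }
  stopifnot(length(sortBy) == n)
  anchors <- siteAnchor(sites)
  chrlens <- GenomeInfoDb::seqlengths(sites)
  ratio <- if (!is.null(input)) length(chip) / length(input) else NA_real_

  oneRow <- function(i) {
    chr <- as.character(GenomeInfoDb::seqnames(sites))[i]
    ws <- anchors[i] - halfWidth
    we <- anchors[i] + halfWidth
    len <- chrlens[chr]
    clipS <- max(ws, 1L)
    clipE <- if (!is.na(len)) min(we, len) else we
    padded <- clipS > ws || clipE < we
    if (clipE < clipS) {
      return(list(row = numeric(length(offsets)), padded = TRUE))
    }
    win <- GenomicRanges::GRanges(chr, IRanges::IRanges(clipS, clipE))
    cp <- coveragePileup(chip, win, extension)
    if (!is.null(input)) {
      ip <- coveragePileup(input, win, extension)
      vals <- (cp + pseudocount) / (ip * ratio + pseudocount)
    } else {
      vals <- as.numeric(cp)
    }
    row <- numeric(length(offsets))
    row[(clipS - ws + 1L):(clipS - ws + length(vals))] <- vals
    list(row = row, padded = padded)
  }

  rows <- lapply(seq_len(n), oneRow)
  m <- do.call(rbind, c(lapply(rows, `[[`, "row"),
                        list(matrix(numeric(0), 0, length(offsets)))))
  pad <- vapply(rows, `[[`, logical(1), "padded")
  if (n) {
    ord <- order(-sortBy, seq_len(n))
    m <- m[ord, , drop = FALSE]
    ids <- ids[ord]
    pad <- pad[ord]
  } else {
    pad <- logical(0)
  }
  new("SignalProfile", values = m, offsets = as.integer(offsets),
      factorLabel = factorLabel, siteIds = ids, padded = pad)
}

#' Threshold mask of a signal profile
#'
#' Marks the matrix cells whose input-normalized intensity strictly exceeds
#' the fold threshold (the colored positions of the profile heatmaps).
#'
#' @param profile A [SignalProfile-class].
#' @param fold Fold threshold (default 25; strict `>`).
#' @return Logical matrix with the profile's dimensions.
#' @export
thresholdMask <- function(profile, fold = 25) {
  stopifnot(is(profile, "SignalProfile"))
  as.matrix(profile) > fold
}

#' Columnwise mean signal curve
#'
#' The per-position mean over sites ("vertical section" through the profile
#' heatmap), one curve per factor.
#'
#' @param profiles A single [SignalProfile-class] or a list of them sharing
#'   the same column layout.
#' @return For one profile, a named numeric vector (names = offsets). For a
#'   list, a data frame with columns `offset`, `factor`, `mean`.
#' @export
verticalSection <- function(profiles) {
  one <- function(p) {
    stopifnot(is(p, "SignalProfile"))
    if (!nrow(p@values)) stop("empty profile: no sites to average over")
    stats::setNames(colMeans(p@values), p@offsets)
  }
  if (is(profiles, "SignalProfile")) return(one(profiles))
  stopifnot(is.list(profiles), length(profiles) > 0)
  offs <- profileOffsets(profiles[[1]])
  for (p in profiles)
    if (!identical(profileOffsets(p), offs))
      stop("profiles must share the same column layout")
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(offset = offs, factor = p@factorLabel,
               mean = unname(one(p)))
  }))
}

#' Paired Wilcoxon signed-rank comparison of site-level signals
#'
#' Two-sided Wilcoxon signed-rank test on paired per-site scores. Zero
#' differences are dropped; when all differences are zero the p-value is 1
#' with a warning. The exact distribution is used for n <= 25 without ties,
#' the normal approximation with continuity correction otherwise.
#'
#' @param values_a,values_b Numeric vectors of equal length, paired by site.
#' @return The two-sided p-value.
#' @export
pairedSignalTest <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b))
  d <- values_a - values_b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(stats::wilcox.test(
    d, alternative = "two.sided", exact = exact, correct = TRUE))
  unname(res$p.value)
}

## ---- Conservation -----------------------------------------------------------

#' Read a per-base conservation track
#'
#' Reads a bedGraph (or fixed-step wiggle) of per-base conservation
#' probabilities, e.g. phastCons scores in `[0, 1]`.
#'
#' @param path Path to the bedGraph/wig file.
#' @param format `"bedGraph"` (default) or `"wig"`.
#' @return [GenomicRanges::GRanges] with a `score` column.
#' @export
readConservation <- function(path, format = "bedGraph") {
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) && (min(gr$score) < 0 || max(gr$score) > 1))
    stop("conservation scores must lie in [0, 1]")
  gr
}

#' Mean conservation in a window around site anchors
#'
#' Arithmetic mean of the per-base conservation score over
#' `[anchor - half, anchor + half]` (2*half + 1 positions; anchor = summit
#' when available, midpoint otherwise). Bases missing from the track score 0
#' (the phastCons convention for unalignable regions) and stay in the
#' denominator.
#'
#' @param sites [ClassifiedSites-class] or [GenomicRanges::GRanges].
#' @param track Conservation [GenomicRanges::GRanges] with a `score` column
#'   (see [readConservation()]).
#' @param half Half window width in bases (default 50).
#' @return Numeric vector of mean scores, one per site.
#' @export
meanConservation <- function(sites, track, half = 50L) {
  stopifnot(is(sites, "GRanges"), is(track, "GRanges"))
  anchors <- siteAnchor(sites)
  covl <- GenomicRanges::coverage(track, weight = "score")
  chrs <- as.character(GenomeInfoDb::seqnames(sites))
  vapply(seq_along(sites), function(i) {
    ws <- anchors[i] - half
    we <- anchors[i] + half
    npos <- 2L * half + 1L
    if (!chrs[i] %in% names(covl)) return(0)
    rle <- covl[[chrs[i]]]
    lo <- max(ws, 1L)
    hi <- min(we, length(rle))
    if (hi < lo) return(0)
    sum(as.numeric(S4Vectors::window(rle, lo, hi))) / npos
  }, numeric(1))
}
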