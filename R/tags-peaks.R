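## Tag-level preprocessing and peak handling. A "tag" is the 5'-most mapped
## base of a sequencing read, held as a width-1 stranded GRanges with an
## optional `sample_id` metadata column.

#' Construct tag ranges from positions
#'
#' @param chrom Character vector of chromosome names.
#' @param pos5 Integer vector of 5'-most mapped positions (1-based).
#' @param strand Character vector in `{"+", "-"}`.
#' @param sample_id Optional sample label (recycled).
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo].
#' @return Width-1 [GenomicRanges::GRanges].
#' @export
tagRanges <- function(chrom, pos5, strand, sample_id = NA_character_,
                      seqinfo = NULL) {
  stopifnot(all(strand %in% c("+", "-")), all(pos5 >= 1))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos5, width = 1L),
                               strand = strand)
  S4Vectors::mcols(gr)$sample_id <- rep_len(sample_id, length(gr))
  if (!is.null(seqinfo)) GenomeInfoDb::seqinfo(gr) <-
      seqinfo[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Read tags from a BED6 file
#'
#' One tag per line; the 5' position is the BED start on the plus strand and
#' `end - 1` on the minus strand (so width-1 records read back unchanged on
#' both strands). The BED name column, when present, is kept as `sample_id`.
#'
#' @param path Path to the BED file.
#' @return Width-1 [GenomicRanges::GRanges] anchored at the 5' position.
#' @export
readTags <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("tag records must be stranded (+/-)")
  pos5 <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::IRanges(pos5, width = 1L),
                                strand = strand(gr),
                                seqinfo = GenomeInfoDb::seqinfo(gr))
  sid <- if (!is.null(gr$name)) gr$name else NA_character_
  S4Vectors::mcols(out)$sample_id <- rep_len(sid, length(out))
  out
}

#' Write tags as BED6
#'
#' Width-1 records, score 0, `sample_id` in the name column.
#'
#' @param tags Width-1 tag [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTags <- function(tags, path) {
  stopifnot(all(width(tags) == 1L))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(tags)),
    start = start(tags) - 1L,
    end = end(tags),
    name = if (!is.null(tags$sample_id)) as.character(tags$sample_id)
           else ".",
    score = 0L,
    strand = as.character(strand(tags))
  )
  df$name[is.na(df$name)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove duplicate tags
#'
#' Keeps at most one tag per (chromosome, 5' position, strand, sample)
#' combination. Idempotent and order-independent: the retained set does not
#' depend on input order (the first occurrence is kept, and all occurrences
#' of a key are identical).
#'
#' @param tags Width-1 tag [GenomicRanges::GRanges].
#' @return De-duplicated tags.
#' @export
filterDuplicates <- function(tags) {
  stopifnot(is(tags, "GRanges"))
  if (!length(tags)) return(tags)
  sid <- if (!is.null(tags$sample_id)) as.character(tags$sample_id)
         else rep(NA_character_, length(tags))
  key <- paste(as.character(GenomeInfoDb::seqnames(tags)), start(tags),
               as.character(strand(tags)), sid, sep = "\r")
  tags[!duplicated(key)]
}

#' Match ChIP and input sequencing depths
#'
#' Randomly subsamples (without replacement) the larger of the two tag sets so
#' that the relative depth difference `|n1 - n2| / max(n1, n2)` is at most
#' `tolerance`; the smaller set is returned unchanged. The target size is the
#' largest `s` satisfying the tolerance, `floor(smaller / (1 - tolerance))`,
#' capped at the larger library's size. The same seed always yields the same
#' subsample.
#'
#' @param chip,input Tag [GenomicRanges::GRanges]; duplicates should already
#'   be filtered.
#' @param tolerance Maximum allowed relative depth difference (default 0.10).
#' @param seed Integer seed for the subsampling RNG.
#' @return List with elements `chip` and `input`.
#' @export
matchDepth <- function(chip, input, tolerance = 0.10, seed = 1L) {
  if (!length(chip) || !length(input))
    stop("unusable sample: empty tag set passed to matchDepth")
  stopifnot(tolerance > 0, tolerance < 1)
  n1 <- length(chip); n2 <- length(input)
  if (abs(n1 - n2) / max(n1, n2) <= tolerance)
    return(list(chip = chip, input = input))
  small <- min(n1, n2)
  target <- min(max(n1, n2), floor(small / (1 - tolerance) + 1e-9))
  keep <- withSeed(seed, sort(sample.int(max(n1, n2), target)))
  if (n1 > n2) list(chip = chip[keep], input = input)
  else list(chip = chip, input = input[keep])
}

#' Filter peak calls by p-value
#'
#' Retains exactly the peaks with `pvalue` strictly below the threshold,
#' preserving input order.
#'
#' @param peaks [GenomicRanges::GRanges] with a `pvalue` metadata column.
#' @param threshold Significance cutoff (default `1e-10`).
#' @return The surviving peaks.
#' @export
filterPeaksByPvalue <- function(peaks, threshold = 1e-10) {
  stopifnot(is(peaks, "GRanges"))
  pv <- S4Vectors::mcols(peaks)$pvalue
  if (is.null(pv) || (length(peaks) && anyNA(pv)))
    stop("every peak must carry a p-value")
  peaks[which(pv < threshold)]
}

## internal: extend width-1 tags to fragments of `extension` bases, directed
## by strand: [pos5, pos5+ext-1] on +, [pos5-ext+1, pos5] on -
extendTags <- function(tags, extension) {
  stopifnot(extension >= 1)
  minus <- as.character(strand(tags)) == "-"
  s <- ifelse(minus, start(tags) - extension + 1L, start(tags))
  e <- s + extension - 1L
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(tags),
                         IRanges::IRanges(pmax(s, 1L), e),
                         strand = strand(tags))
}

#' Per-position tag coverage over a window
#'
#' Each tag is extended to a fragment of `extension` bases in its strand
#' direction; the returned vector counts, for every position of the window,
#' how many extended fragments cover it.
#'
#' @param tags Width-1 tag [GenomicRanges::GRanges].
#' @param window A single [GenomicRanges::GRanges] interval.
#' @param extension Fragment length in bases (default 200).
#' @return Integer vector of length `width(window)`.
#' @export
coveragePileup <- function(tags, window, extension = 200L) {
  stopifnot(is(window, "GRanges"), length(window) == 1L, extension >= 1)
  w <- width(window)
  chr <- as.character(GenomeInfoDb::seqnames(window))
  tags <- tags[GenomeInfoDb::seqnames(tags) == chr]
  if (!length(tags)) return(integer(w))
  fr <- extendTags(tags, extension)
  ir <- IRanges::shift(ranges(fr), -(start(window) - 1L))
  ir <- IRanges::restrict(ir, start = 1L, end = w)
  ir <- ir[width(ir) > 0]
  if (!length(ir)) return(integer(w))
  as.integer(IRanges::coverage(ir, width = w))
}

#' Score candidate peaks with a sliding-window local-Poisson model
#'
#' A minimal stand-in peak scorer used to exercise the pipeline on synthetic
#' data (it is deliberately not a reimplementation of a production caller).
#' Fixed-width windows are slid along each chromosome; each window's ChIP tag
#' count is tested against a Poisson expectation
#' `lambda = max(local input count scaled by the library-size ratio,
#' genome-wide ChIP rate)` with an upper-tail p-value. Overlapping significant
#' windows are merged; the merged peak's p-value is the minimum over its
#' windows and its summit is the position of maximum ChIP pileup.
#'
#' @param chip,input Depth-matched tag [GenomicRanges::GRanges].
#' @param genome A [GenomeInfoDb::Seqinfo] giving chromosome lengths.
#' @param windowSize Window width in bases (default 300).
#' @param step Window step in bases (default 100).
#' @param pThreshold Upper-tail p-value cutoff (default `1e-10`).
#' @param extension Fragment extension used for summit pileups (default 200).
#' @return [GenomicRanges::GRanges] of merged peaks with metadata columns
#'   `pvalue` and `summit` (absolute position).
#' @export
scoreCandidatePeaks <- function(chip, input, genome, windowSize = 300L,
                                step = 100L, pThreshold = 1e-10,
                                extension = 200L) {
  stopifnot(is(genome, "Seqinfo"))
  glen <- sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
  if (!isTRUE(glen > 0)) stop("zero-length genome")
  if (!length(input)) stop("unusable sample: empty input tag set")
  nChip <- length(chip); nInput <- length(input)
  libRatio <- nChip / nInput
  lambdaGlobal <- nChip * windowSize / glen

  windowsOf <- function(chr, len) {
    starts <- seq.int(1L, max(1L, len), by = step)
    GenomicRanges::GRanges(chr, IRanges::IRanges(
      starts, end = pmin(starts + windowSize - 1L, len)), seqinfo = genome)
  }
  win <- do.call(c, lapply(GenomeInfoDb::seqnames(genome), function(chr)
    windowsOf(chr, GenomeInfoDb::seqlengths(genome)[[chr]])))

  cnt <- GenomicRanges::countOverlaps(win, chip, ignore.strand = TRUE)
  bg <- GenomicRanges::countOverlaps(win, input, ignore.strand = TRUE)
  lambda <- pmax(bg * libRatio, lambdaGlobal)
  pv <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE)
  sig <- which(pv < pThreshold)
  if (!length(sig)) {
    out <- GenomicRanges::GRanges(seqinfo = genome)
    S4Vectors::mcols(out)$pvalue <- numeric(0)
    S4Vectors::mcols(out)$summit <- integer(0)
    return(out)
  }
  merged <- GenomicRanges::reduce(win[sig], ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(merged, win[sig], ignore.strand = TRUE)
  minP <- vapply(split(pv[sig][S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits)), min, numeric(1))
  summit <- vapply(seq_along(merged), function(i) {
    pile <- coveragePileup(chip, merged[i], extension = extension)
    start(merged)[i] + which.max(pile) - 1L
  }, integer(1))
  S4Vectors::mcols(merged)$pvalue <- pmax(unname(minP), 1e-300)
  S4Vectors::mcols(merged)$summit <- summit
  merged
}

## ---- narrowPeak I/O ---------------------------------------------------------

#' Read a narrowPeak file
#'
#' Ten-column BED-derived peak format; the stored `-log10(p)` column is
#' converted back to a p-value, and the summit offset (column 10) to an
#' absolute position (`NA` when recorded as -1).
#'
#' @param path Path to the narrowPeak file.
#' @return [GenomicRanges::GRanges] with `pvalue` and `summit` columns.
#' @export
readNarrowPeak <- function(path) {
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  S4Vectors::mcols(gr)$pvalue <- 10^(-gr$pValue)
  S4Vectors::mcols(gr)$summit <- ifelse(gr$peak < 0, NA_integer_,
                                        start(gr) + gr$peak)
  gr
}

#' Write peaks as narrowPeak
#'
#' @param peaks [GenomicRanges::GRanges] with `pvalue` (and optionally
#'   `summit`) metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
  pv <- S4Vectors::mcols(peaks)$pvalue
  if (is.null(pv)) stop("peaks must carry a p-value")
  summit <- S4Vectors::mcols(peaks)$summit
  peakCol <- if (is.null(summit)) rep(-1L, length(peaks))
             else ifelse(is.na(summit), -1L, summit - start(peaks))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = sprintf("peak_%d", seq_along(peaks)),
    score = 0L,
    strand = ".",
    signalValue = 0,
    pValue = -log10(pmax(pv, 1e-300)),
    qValue = -1,
    peak = peakCol
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
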