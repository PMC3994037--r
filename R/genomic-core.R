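## Interval arithmetic and overlap indexing. All in-memory coordinates follow
## the GRanges convention (1-based, closed); BED and bedGraph files are
## converted at the I/O boundary by rtracklayer, so half-open BED semantics
## hold on disk (abutting BED intervals do not overlap).

#' Do two interval vectors overlap element-wise?
#'
#' Strand is ignored: two intervals overlap iff they lie on the same
#' chromosome and share at least one base.
#'
#' @param a,b [GenomicRanges::GRanges] of equal length (or either of length
#'   one, recycled).
#' @return Logical vector.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
#' intervalsOverlap(a, b)  # abutting: FALSE
intervalsOverlap <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  n <- max(length(a), length(b))
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, n)
    if (length(b) == 1L) b <- rep(b, n)
  }
  stopifnot(length(a) == length(b))
  as.character(GenomeInfoDb::seqnames(a)) ==
    as.character(GenomeInfoDb::seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

#' Distance from an interval to a genomic point
#'
#' Zero when the point lies inside the interval; otherwise the distance in
#' bases to the nearest interval base, i.e. `min(|pos - start|, |pos - end|)`.
#' The caller is responsible for restricting to same-chromosome queries.
#'
#' @param iv [GenomicRanges::GRanges].
#' @param pos Integer vector of positions (1-based), recycled against `iv`.
#' @return Non-negative integer vector.
#' @export
pointDistance <- function(iv, pos) {
  stopifnot(is(iv, "GRanges"))
  n <- max(length(iv), length(pos))
  s <- rep_len(start(iv), n)
  e <- rep_len(end(iv), n)
  p <- rep_len(as.integer(pos), n)
  inside <- p >= s & p <= e
  ifelse(inside, 0L, pmin(abs(p - s), abs(p - e)))
}

#' Build an overlap-query index
#'
#' Preprocesses a set of intervals for fast repeated overlap queries with
#' [queryOverlaps()]. Query results are identical to a linear scan with
#' [intervalsOverlap()].
#'
#' @param intervals [GenomicRanges::GRanges] (may be empty).
#' @return An [OverlapIndex-class] object.
#' @export
overlapIndex <- function(intervals) {
  stopifnot(is(intervals, "GRanges"))
  new("OverlapIndex", subject = intervals,
      nclist = GenomicRanges::GNCList(intervals))
}

#' Query an overlap index
#'
#' @param index An [OverlapIndex-class] from [overlapIndex()].
#' @param query A [GenomicRanges::GRanges] of length one (or more; results are
#'   the union over queries when `query` is longer).
#' @return The stored intervals overlapping the query (strand ignored), in
#'   their original order.
#' @export
queryOverlaps <- function(index, query) {
  stopifnot(is(index, "OverlapIndex"), is(query, "GRanges"))
  hits <- GenomicRanges::findOverlaps(query, index@nclist,
                                      ignore.strand = TRUE)
  index@subject[sort(unique(S4Vectors::subjectHits(hits)))]
}

## ---- I/O --------------------------------------------------------------------

#' Read a BED3/BED6 file
#'
#' @param path Path to a tab-separated BED file (0-based half-open on disk).
#' @return A [GenomicRanges::GRanges] (1-based closed in memory).
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write intervals as BED
#'
#' @param gr [GenomicRanges::GRanges].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Tab-separated file: chromosome name, length in bases.
#' @return A [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = df$chrom, seqlengths = df$length)
}

#' Write a chromosome-sizes file
#'
#' @param seqinfo A [GenomeInfoDb::Seqinfo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(seqinfo, path) {
  df <- data.frame(chrom = GenomeInfoDb::seqnames(seqinfo),
                   length = GenomeInfoDb::seqlengths(seqinfo))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## internal: give two GRanges a shared seqlevel universe so findOverlaps
## does not warn when they live on disjoint chromosomes
unifySeqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

## internal: deterministic 32-bit FNV-1a hash of a character scalar,
## used for labeled RNG substreams and config fingerprints
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## XOR the low byte of h with b (h is kept as a double below 2^32)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    ## 32-bit multiply by 16777619 without overflow (split into 16-bit halves)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

## internal: derive a substream seed below 2^31 from a base seed and a label
subSeed <- function(seed, label) {
  as.integer((as.numeric(seed) + fnv1a32(label)) %% 2147483647)
}

## internal: evaluate `expr` under a temporary seeded RNG, restoring the
## caller's RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
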