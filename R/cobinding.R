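## Co-occupancy classification of Rest peaks by Sin3A/Lsd1 overlap, and the
## ES-vs-EpiS cross-cell comparison.

#' Classify Rest peaks by Sin3A/Lsd1 co-binding
#'
#' Each Rest peak becomes one classified site. A site is `S+` iff it overlaps
#' at least one Sin3A peak and `L+` iff it overlaps at least one Lsd1 peak
#' (one shared base suffices; strand ignored), giving the four classes of
#' [cobindClasses()]. The partition is exhaustive and exclusive: a Rest peak
#' overlapping several partner peaks still yields a single site.
#'
#' @param rest,sin3a,lsd1 Peak [GenomicRanges::GRanges] (already p-value
#'   filtered). `pvalue` and `summit` columns on `rest` are carried over.
#' @param cell Cell-state label stored on the result (default `"ES"`).
#' @return A [ClassifiedSites-class] object, one entry per Rest peak.
#' @export
classifyCobinding <- function(rest, sin3a, lsd1, cell = "ES") {
  stopifnot(is(rest, "GRanges"), is(sin3a, "GRanges"), is(lsd1, "GRanges"))
  uS <- unifySeqlevels(rest, sin3a)
  uL <- unifySeqlevels(rest, lsd1)
  nS <- GenomicRanges::countOverlaps(uS$a, uS$b, ignore.strand = TRUE)
  nL <- GenomicRanges::countOverlaps(uL$a, uL$b, ignore.strand = TRUE)
  gr <- GenomicRanges::granges(rest)
  mc <- S4Vectors::mcols(rest)
  S4Vectors::mcols(gr)$pvalue <-
    if ("pvalue" %in% colnames(mc)) mc$pvalue else NA_real_
  S4Vectors::mcols(gr)$summit <-
    if ("summit" %in% colnames(mc)) mc$summit else NA_integer_
  S4Vectors::mcols(gr)$cobind <- paste0("R+/S", ifelse(nS > 0L, "+", "-"),
                                        "/L", ifelse(nL > 0L, "+", "-"))
  S4Vectors::mcols(gr)$nSin3a <- as.integer(nS)
  S4Vectors::mcols(gr)$nLsd1 <- as.integer(nL)
  S4Vectors::mcols(gr)$specificity <- rep(NA_character_, length(gr))
  new("ClassifiedSites", gr, cell = cell)
}

#' Drop Rest-only sites
#'
#' Removes `R+/S-/L-` sites (Rest peaks co-bound by neither Sin3A nor Lsd1),
#' which are excluded from downstream comparisons; order is preserved.
#'
#' @param sites A [ClassifiedSites-class] object.
#' @return The sites with `cobind != "R+/S-/L-"`.
#' @export
dropRestOnly <- function(sites) {
  stopifnot(is(sites, "ClassifiedSites"))
  sites[cobindClass(sites) != "R+/S-/L-"]
}

#' Compare Rest site sets between two cell states
#'
#' A site of one cell is `common` iff its Rest peak overlaps at least one Rest
#' peak of the other cell (one shared base; strand ignored), else `unique`.
#' Counts are reported per reference cell, so `common_a` and `common_b` can
#' differ when one peak overlaps several peaks of the other set.
#'
#' @param sites_a,sites_b [ClassifiedSites-class] from the two cell states,
#'   both already passed through [dropRestOnly()].
#' @return List with the specificity-annotated inputs (`a`, `b`) and an
#'   integer vector `counts` with elements `a_unique`, `common_a`, `common_b`,
#'   `b_unique`.
#' @export
compareCells <- function(sites_a, sites_b) {
  stopifnot(is(sites_a, "ClassifiedSites"), is(sites_b, "ClassifiedSites"))
  hitA <- GenomicRanges::countOverlaps(sites_a, sites_b,
                                       ignore.strand = TRUE) > 0L
  hitB <- GenomicRanges::countOverlaps(sites_b, sites_a,
                                       ignore.strand = TRUE) > 0L
  S4Vectors::mcols(sites_a)$specificity <- ifelse(hitA, "common", "unique")
  S4Vectors::mcols(sites_b)$specificity <- ifelse(hitB, "common", "unique")
  list(
    a = sites_a, b = sites_b,
    counts = c(a_unique = sum(!hitA), common_a = sum(hitA),
               common_b = sum(hitB), b_unique = sum(!hitB))
  )
}

## internal: integer percentages by the largest-remainder method, summing to
## 100 (matches the printed class compositions, which nearest-integer
## rounding does not); ties broken by position
largestRemainderPercent <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(rep(0L, length(counts)))
  p <- 100 * counts / total
  fl <- floor(p)
  k <- 100L - as.integer(sum(fl))
  if (k > 0) {
    ord <- order(-(p - fl), seq_along(p))
    fl[ord[seq_len(k)]] <- fl[ord[seq_len(k)]] + 1
  }
  as.integer(fl)
}

## internal: round-half-up to integer
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

#' Co-binding class composition
#'
#' Counts sites per co-binding class (over the three non-Rest-only classes)
#' and expresses them as integer percentages of the total. Percentages use
#' largest-remainder apportionment so they always sum to 100.
#'
#' @param x Either a [ClassifiedSites-class] object already filtered with
#'   [dropRestOnly()], or a named integer vector of class counts.
#' @return Data frame with columns `cobind`, `count`, `percent`.
#' @export
#' @examples
#' compositionPercentages(c("R+/S+/L+" = 628, "R+/S+/L-" = 402,
#'                          "R+/S-/L+" = 284))
compositionPercentages <- function(x) {
  classes <- setdiff(cobindClasses(), "R+/S-/L-")
  if (is(x, "ClassifiedSites")) {
    if (any(cobindClass(x) == "R+/S-/L-"))
      stop("drop R+/S-/L- sites (dropRestOnly) before computing composition")
    counts <- as.integer(table(factor(cobindClass(x), levels = classes)))
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)), all(names(x) %in% classes))
    counts <- as.integer(x[match(classes, names(x))])
    counts[is.na(counts)] <- 0L
  }
  if (sum(counts) == 0L)
    warning("no sites: percentages reported as zero")
  data.frame(cobind = classes, count = counts,
             percent = largestRemainderPercent(counts))
}
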