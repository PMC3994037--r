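# Shared helpers: terse constructors, brute-force oracles, and memoized
# synthetic fixtures so the expensive simulations run once per test session.

gr <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand)
}

randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 1e5,
                            maxLen = 500) {
  s <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(maxLen, n, replace = TRUE)
  gr(sample(chroms, n, replace = TRUE), s, s + w - 1L)
}

# linear-scan overlap oracle (same chromosome, >= 1 shared base)
overlapOracle <- function(a, b) {
  as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b)) &
    GenomicRanges::start(a) <= GenomicRanges::end(b) &
    GenomicRanges::start(b) <= GenomicRanges::end(a)
}

# brute-force point-to-interval distance: min over all interval bases
pointDistanceOracle <- function(s, e, pos) {
  min(abs(pos - (s:e)))
}

# exact two-sided signed-rank p-value by full 2^n sign enumeration
wilcoxEnumOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w0 <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w0 <= w), mean(w0 >= w)))
}

# memoized fixtures (shared across test files)
.fixtureCache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 7L) {
  spec <- expand.grid(cobind = cobindClasses(),
                      occupancy = c("both", "ES-only", "EpiS-only"),
                      stringsAsFactors = FALSE)
  spec$enrichment <- 20
  spec$induced <- rep(c(TRUE, FALSE), length.out = nrow(spec))
  spec$inductionFold <- 4
  syntheticConfig(
    seed = seed,
    genome = c(chr1 = 1200000L, chr2 = 300000L),
    nCodingGenes = 34L, nNoncodingGenes = 6L,
    nIntergenicPromoters = 4L,
    siteSpec = spec,
    depths = list(chip = 150000L, input = 150000L,
                  tss = 50000L, mrna = 200000L)
  )
}

smallFixture <- function() {
  if (is.null(.fixtureCache$small))
    .fixtureCache$small <- generateFixture(smallConfig())
  .fixtureCache$small
}

smallReport <- function() {
  if (is.null(.fixtureCache$smallReport))
    .fixtureCache$smallReport <- {
      fx <- smallFixture()
      runPipeline(fx$tags, fx$genes, fx$seqinfo,
                  conservation = fx$conservation,
                  params = pipelineParams(seed = 7L))
    }
  .fixtureCache$smallReport
}

standardFixture <- function() {
  if (is.null(.fixtureCache$standard))
    .fixtureCache$standard <- generateFixture(syntheticConfig(seed = 42L))
  .fixtureCache$standard
}

standardReport <- function() {
  if (is.null(.fixtureCache$standardReport))
    .fixtureCache$standardReport <- {
      fx <- standardFixture()
      runPipeline(fx$tags, fx$genes, fx$seqinfo,
                  conservation = fx$conservation,
                  params = pipelineParams(seed = 42L))
    }
  .fixtureCache$standardReport
}
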