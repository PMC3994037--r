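test_that("duplicate filtering keeps one tag per position/strand/sample", {
  t3 <- tagRanges(rep("chr1", 3), rep(101, 3), rep("+", 3))
  expect_length(filterDuplicates(t3), 1)

  both <- tagRanges(c("chr1", "chr1"), c(101, 101), c("+", "-"))
  expect_length(filterDuplicates(both), 2)

  # random multiset vs set-based oracle
  set.seed(5)
  n <- 10000
  tg <- tagRanges(sample(c("chr1", "chr2"), n, TRUE),
                  sample.int(2000, n, TRUE),
                  sample(c("+", "-"), n, TRUE))
  key <- paste(GenomicRanges::seqnames(tg), GenomicRanges::start(tg),
               GenomicRanges::strand(tg))
  expect_length(filterDuplicates(tg), length(unique(key)))

  # idempotent
  once <- filterDuplicates(tg)
  expect_identical(filterDuplicates(once), once)
})

test_that("depth matching satisfies the tolerance inequality", {
  mk <- function(n) tagRanges(rep("chr1", n), seq_len(n), rep("+", n))
  eq <- matchDepth(mk(100), mk(100), seed = 1)
  expect_length(eq$chip, 100)
  expect_length(eq$input, 100)

  md <- matchDepth(mk(200), mk(100), seed = 1)
  s <- length(md$chip)
  expect_length(md$input, 100)
  expect_lte((s - 100) / s, 0.10)
  expect_equal(s, 111)  # largest size satisfying the 10% rule

  # determinism
  md2 <- matchDepth(mk(200), mk(100), seed = 1)
  expect_identical(GenomicRanges::start(md2$chip),
                   GenomicRanges::start(md$chip))

  # property: never increases either count; inequality always holds
  set.seed(9)
  for (i in 1:25) {
    n1 <- sample(50:4000, 1); n2 <- sample(50:4000, 1)
    r <- matchDepth(mk(n1), mk(n2), seed = i)
    m1 <- length(r$chip); m2 <- length(r$input)
    expect_lte(m1, n1); expect_lte(m2, n2)
    expect_lte(abs(m1 - m2) / max(m1, m2), 0.10)
  }

  expect_error(matchDepth(mk(0), mk(10)), "unusable")
})

test_that("p-value filtering is strict and order-preserving", {
  pk <- gr("chr1", c(1, 100, 200), c(50, 150, 250))
  pk$pvalue <- c(1e-12, 1e-10, 1e-9)
  kept <- filterPeaksByPvalue(pk)
  expect_length(kept, 1)
  expect_equal(kept$pvalue, 1e-12)

  expect_length(filterPeaksByPvalue(pk[0]), 0)

  set.seed(13)
  pr <- gr("chr1", 1:1000, 1:1000 + 10)
  pr$pvalue <- 10^(-runif(1000, 0, 20))
  expect_length(filterPeaksByPvalue(pr), sum(pr$pvalue < 1e-10))

  bad <- gr("chr1", 1, 10)
  expect_error(filterPeaksByPvalue(bad), "p-value")
})

test_that("coverage pileup counts extended fragments per position", {
  win <- gr("chr1", 101, 120)
  one <- tagRanges("chr1", 101, "+")
  expect_equal(coveragePileup(one, win, extension = 5),
               c(rep(1L, 5), rep(0L, 15)))

  expect_equal(coveragePileup(one[0], win), integer(20))

  # minus-strand tag covers (pos5-ext, pos5]
  minus <- tagRanges("chr1", 110, "-")
  v <- coveragePileup(minus, win, extension = 5)
  expect_equal(which(v == 1L), 6:10)

  # brute-force oracle on 500 random tags
  set.seed(17)
  tg <- tagRanges(rep("chr1", 500), sample.int(3000, 500, TRUE),
                  sample(c("+", "-"), 500, TRUE))
  win2 <- gr("chr1", 1001, 1400)
  ext <- 50L
  got <- coveragePileup(tg, win2, extension = ext)
  st <- GenomicRanges::start(tg)
  mi <- as.character(GenomicRanges::strand(tg)) == "-"
  fs <- ifelse(mi, st - ext + 1L, st)
  fe <- fs + ext - 1L
  want <- vapply(1001:1400, function(p) sum(fs <= p & p <= fe), integer(1))
  expect_equal(got, want)
})

test_that("the stand-in caller finds planted enrichment and nothing else", {
  set.seed(23)
  genome <- GenomeInfoDb::Seqinfo(seqnames = "chr1", seqlengths = 1000000L)
  n <- 10000
  unif <- function() tagRanges(rep("chr1", n),
                               sample.int(1000000L, n, TRUE),
                               sample(c("+", "-"), n, TRUE))
  chipNull <- unif(); inputNull <- unif()
  nullPeaks <- scoreCandidatePeaks(chipNull, inputNull, genome)
  expect_lte(length(nullPeaks), 1)

  # plant a 50x site at 500000-500199
  center <- 500100L
  extra <- 98L
  sitePos <- sample(500000:500199, extra, TRUE)
  strands <- sample(c("+", "-"), extra, TRUE)
  pos5 <- ifelse(strands == "+", sitePos - 100L, sitePos + 100L)
  chip <- c(unif(), tagRanges(rep("chr1", extra), pos5, strands))
  input <- unif()
  pk <- scoreCandidatePeaks(chip, input, genome)
  expect_equal(length(pk), 1)
  expect_true(GenomicRanges::start(pk) <= center & center <=
                GenomicRanges::end(pk))
  expect_true(pk$pvalue < 1e-10)
  expect_true(abs(pk$summit - center) <= 300)

  # enrichment is directional: swapped labels find nothing at the site
  swapped <- scoreCandidatePeaks(input, chip, genome)
  if (length(swapped))
    expect_false(any(overlapOracle(swapped, rep(gr("chr1", 500000, 500199),
                                                length(swapped)))))

  # extreme enrichment: all chip tags at one position, sparse input
  spike <- tagRanges(rep("chr1", 200), rep(600000L, 200), rep("+", 200))
  sparse <- tagRanges(rep("chr1", 50), sample.int(1000000L, 50),
                      rep("+", 50))
  pk2 <- scoreCandidatePeaks(spike, sparse, genome)
  expect_true(any(GenomicRanges::start(pk2) <= 600000 &
                    600000 <= GenomicRanges::end(pk2)))

  expect_error(scoreCandidatePeaks(chip, input,
                                   GenomeInfoDb::Seqinfo()), "genome")
})

test_that("narrowPeak files round-trip peak calls", {
  pk <- gr("chr1", c(1001, 5001), c(1300, 5300))
  pk$pvalue <- c(1e-15, 1e-30)
  pk$summit <- c(1101L, NA_integer_)
  f <- tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(pk, f)
  back <- readNarrowPeak(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk))
  expect_equal(back$pvalue, pk$pvalue, tolerance = 1e-6)
  expect_equal(back$summit, pk$summit)
})

test_that("tag BED round-trip preserves 5' positions on both strands", {
  tg <- tagRanges(c("chr1", "chr1", "chr2"), c(101, 205, 33),
                  c("+", "-", "-"), sample_id = "s1")
  f <- tempfile(fileext = ".bed")
  writeTags(tg, f)
  back <- readTags(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(tg))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(tg)))
  expect_equal(unique(back$sample_id), "s1")
})
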