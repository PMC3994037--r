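test_that("site intensity is the pseudocounted chip/input ratio", {
  site <- gr("chr1", 1001, 1200)
  mkT <- function(n, lo = 1001, hi = 1200)
    tagRanges(rep("chr1", n), sample(lo:hi, n, TRUE),
              sample(c("+", "-"), n, TRUE))
  set.seed(59)
  # equal counts, equal depths -> exactly 1
  chip <- mkT(50); input <- chip
  expect_equal(siteIntensity(chip, input, site), 1.0)

  # chip 2x input at equal depth, counts >> pseudocount -> ~2
  chip2 <- c(mkT(400), mkT(600, 5001, 9000))
  input2 <- c(mkT(200), mkT(800, 5001, 9000))
  expect_equal(siteIntensity(chip2, input2, site), 2.0, tolerance = 0.02)

  expect_true(all(siteIntensity(mkT(10), mkT(10), site) >= 0))
})

test_that("planted sites score higher than background sites", {
  fx <- smallFixture()
  sites <- gr(fx$truth$sites$chrom, fx$truth$sites$start,
              fx$truth$sites$end)
  occ <- fx$truth$sites$occupancy %in% c("both", "ES-only")
  chip <- fx$tags$Rest_ES
  input <- fx$tags$input_ES
  set.seed(61)
  bgStart <- sample(100000:1100000, 50)
  bg <- gr("chr1", bgStart, bgStart + 199)
  planted <- siteIntensity(chip, input, sites[occ])
  background <- siteIntensity(chip, input, bg)
  p <- stats::wilcox.test(planted, background,
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("profile matrices are anchored, normalized and sorted", {
  site <- gr("chr1", 10001, 10200)
  site$summit <- 10100L
  empty <- profileMatrix(site, GenomicRanges::GRanges(), halfWidth = 100)
  expect_s4_class(empty, "SignalProfile")
  expect_equal(dim(as.matrix(empty)), c(1L, 201L))
  expect_true(all(as.matrix(empty) == 0))
  expect_equal(profileOffsets(empty), -100:100)

  # symmetric planted enrichment: row maximum within +/-50 of the anchor
  set.seed(67)
  center <- 10100L
  pos <- center + sample(-80:80, 400, TRUE)
  strand <- sample(c("+", "-"), 400, TRUE)
  pos5 <- ifelse(strand == "+", pos - 100L, pos + 100L)
  chip <- tagRanges(rep("chr1", 400), pos5, strand)
  prof <- profileMatrix(site, chip, halfWidth = 500)
  row <- as.matrix(prof)[1, ]
  peakOffset <- profileOffsets(prof)[which.max(row)]
  expect_lte(abs(peakOffset), 50)

  # rows sort by descending intensity
  s2 <- gr("chr1", c(10001, 20001), c(10200, 20200))
  s2$summit <- c(10100L, 20100L)
  names(s2) <- c("hot", "cold")
  prof2 <- profileMatrix(s2, chip, halfWidth = 200)
  expect_equal(prof2@siteIds, c("hot", "cold"))

  # window over the chromosome edge is zero-padded and flagged
  edge <- gr("chr1", 1, 200)
  GenomeInfoDb::seqlengths(edge) <- 50000
  profE <- profileMatrix(edge, chip, halfWidth = 500)
  expect_true(profE@padded[1])
})

test_that("threshold mask is a strict elementwise comparison", {
  site <- gr("chr1", 1001, 1200)
  prof <- profileMatrix(site, GenomicRanges::GRanges(), halfWidth = 50)
  expect_false(any(thresholdMask(prof)))

  vals <- matrix(c(24.9, 25, 25.1, 0), nrow = 1)
  p <- new("SignalProfile", values = vals, offsets = 1:4 * 1L,
           factorLabel = "x", siteIds = "s", padded = FALSE)
  expect_equal(as.vector(thresholdMask(p, fold = 25)),
               c(FALSE, FALSE, TRUE, FALSE))

  set.seed(71)
  rv <- matrix(runif(200, 0, 50), nrow = 10)
  pr <- new("SignalProfile", values = rv, offsets = seq_len(20),
            factorLabel = "x", siteIds = sprintf("s%d", 1:10),
            padded = rep(FALSE, 10))
  expect_equal(unname(thresholdMask(pr, 25)), rv > 25)
})

test_that("vertical sections are columnwise means", {
  mkP <- function(m, lab = "f") new("SignalProfile", values = m,
                                    offsets = seq_len(ncol(m)),
                                    factorLabel = lab,
                                    siteIds = sprintf("s%d", seq_len(nrow(m))),
                                    padded = rep(FALSE, nrow(m)))
  one <- matrix(1:5, nrow = 1)
  expect_equal(unname(verticalSection(mkP(one))), as.numeric(1:5))

  two <- rbind(1:5, 1:5)
  expect_equal(unname(verticalSection(mkP(two))), as.numeric(1:5))

  set.seed(73)
  m <- matrix(runif(60), nrow = 6)
  expect_equal(unname(verticalSection(mkP(m))), unname(colMeans(m)))

  df <- verticalSection(list(mkP(m, "a"), mkP(m * 2, "b")))
  expect_equal(unique(df$factor), c("a", "b"))
  expect_equal(df$mean[df$factor == "b"], 2 * df$mean[df$factor == "a"])

  expect_error(verticalSection(mkP(matrix(numeric(0), 0, 5))), "empty")
})

test_that("paired signal test matches exact sign-flip enumeration", {
  expect_warning(p1 <- pairedSignalTest(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(p1, 1)

  # n = 6, all differences positive: exact p = 2/64
  a <- c(5, 6, 7, 8, 9, 10); b <- a - (1:6) / 10
  expect_equal(pairedSignalTest(a, b), 0.03125)

  set.seed(79)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pairedSignalTest(x, y), wilcoxEnumOracle(x - y),
                 tolerance = 1e-12)
  }

  # p decreases with shift magnitude for large samples
  set.seed(83)
  base <- rnorm(200)
  ps <- vapply(c(0.1, 0.3, 0.6), function(s)
    pairedSignalTest(base + s + rnorm(200, sd = 0.2), base), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("mean conservation averages the +/-50 b window with missing = 0", {
  site <- gr("chr1", 1001, 1201)
  site$summit <- 1101L
  constant <- gr("chr1", 1, 5000); constant$score <- 1.0
  expect_equal(meanConservation(site, constant), 1.0)

  zero <- gr("chr1", 1, 5000); zero$score <- 0.0
  expect_equal(meanConservation(site, zero), 0.0)

  # step track: 1.0 left of the anchor, 0.0 right -> 51/101 (anchor included)
  left <- gr("chr1", 1, 1101); left$score <- 1.0
  expect_equal(meanConservation(site, left), 51 / 101)

  # track absent over part of the window counts as zero
  partial <- gr("chr1", 1051, 1101); partial$score <- 1.0
  expect_equal(meanConservation(site, partial), 51 / 101)

  # brute-force window-average oracle on a random track
  set.seed(89)
  segStart <- seq(1, 2001, by = 100)
  track <- gr("chr1", segStart, segStart + 99)
  track$score <- runif(length(segStart))
  perBase <- rep(0, 5000)
  for (i in seq_along(track))
    perBase[GenomicRanges::start(track)[i]:GenomicRanges::end(track)[i]] <-
      track$score[i]
  s2 <- gr("chr1", 901, 1101); s2$summit <- 1001L
  expect_equal(meanConservation(s2, track),
               mean(perBase[(1001 - 50):(1001 + 50)]))
})

test_that("planted common sites are more conserved than the baseline", {
  fx <- smallFixture()
  tr <- fx$truth$sites
  sites <- gr(tr$chrom, tr$start, tr$end)
  mc <- meanConservation(sites, fx$conservation)
  expect_gt(min(mc[tr$occupancy == "both"]),
            max(mc[tr$occupancy != "both"]))
})
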