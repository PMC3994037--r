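test_that("annotation generation places non-overlapping genes", {
  cfg0 <- syntheticConfig(seed = 1L, nCodingGenes = 0L,
                          nNoncodingGenes = 0L)
  ann0 <- generateAnnotation(cfg0)
  expect_length(ann0$genes, 0)
  expect_equal(GenomeInfoDb::seqlengths(ann0$seqinfo)[["chr1"]], 4000000L)

  cfg <- smallConfig()
  ann <- generateAnnotation(cfg)
  expect_length(ann$genes, 40)
  # all-pairs overlap check
  g <- ann$genes
  for (i in seq_len(length(g) - 1))
    expect_false(any(overlapOracle(rep(g[i], length(g) - i),
                                   g[(i + 1):length(g)])))
  # determinism
  ann2 <- generateAnnotation(cfg)
  expect_identical(GenomicRanges::start(ann2$genes),
                   GenomicRanges::start(ann$genes))
  expect_identical(ann2$genes$gene_id, ann$genes$gene_id)

  # impossible placement errors out
  tiny <- syntheticConfig(seed = 1L, genome = c(chr1 = 30000L,
                                                chr2 = 100000L),
                          nCodingGenes = 100L, nNoncodingGenes = 0L,
                          nIntergenicPromoters = 0L)
  expect_error(generateAnnotation(tiny), "cannot place")
})

test_that("planted sites honor their configuration and the 50 kb rule", {
  cfg <- smallConfig()
  ann <- generateAnnotation(cfg)
  truth <- plantSites(cfg, ann)
  st <- truth$sites
  expect_equal(nrow(st), 12)
  expect_setequal(unique(st$cobind), cobindClasses())
  expect_setequal(unique(st$occupancy), c("both", "ES-only", "EpiS-only"))

  # every site is within 50 kb of its designated gene's 5' end (brute force)
  tss <- GenomicRanges::start(geneTss(ann$genes))
  names(tss) <- ann$genes$gene_id
  for (i in seq_len(nrow(st))) {
    d <- pointDistance(gr(st$chrom[i], st$start[i], st$end[i]),
                       tss[[st$gene_id[i]]])
    expect_lte(d, 50000)
  }

  # site intervals do not overlap each other
  sgr <- gr(st$chrom, st$start, st$end)
  expect_equal(length(GenomicRanges::reduce(sgr)), length(sgr))

  # induced flags propagate to gene-level truth
  expect_setequal(truth$genes$gene_id[truth$genes$kdFold > 1],
                  st$gene_id[st$induced])
})

test_that("simulated depths, enrichment structure and determinism hold", {
  fx <- smallFixture()
  cfg <- smallConfig()

  # total tag counts within 2*sqrt(N) of the configured depths
  for (nm in c("Rest_ES", "input_ES", "Lsd1_EpiS")) {
    n <- length(fx$tags[[nm]])
    expect_lt(abs(n - 150000), 2 * sqrt(150000) + 1)
  }
  expect_lt(abs(length(fx$tags$TSS_ES) - 50000), 2 * sqrt(50000) + 1)
  expect_lt(abs(length(fx$tags$mRNA_ctrl) - 200000),
            2 * sqrt(200000) + 1)

  # factor tags are enriched only where that factor is planted in that cell
  st <- fx$truth$sites
  sgr <- gr(st$chrom, st$start, st$end)
  cnt <- function(sample) GenomicRanges::countOverlaps(
    sgr + 100, fx$tags[[sample]], ignore.strand = TRUE)
  sin3aES <- cnt("Sin3A_ES")
  occupied <- grepl("S\\+", st$cobind) & st$occupancy %in% c("both",
                                                             "ES-only")
  # expected background in a 400 b window is ~40; enriched sites carry ~20x
  expect_true(all(sin3aES[occupied] > 150))
  expect_true(all(sin3aES[!occupied] < 150))

  # same seed -> identical tags
  fx2 <- generateFixture(cfg)
  expect_identical(GenomicRanges::start(fx2$tags$Rest_ES),
                   GenomicRanges::start(fx$tags$Rest_ES))

  # different seed -> different tags
  fx3 <- generateFixture(syntheticConfig(seed = 8L,
                                         genome = cfg$genome,
                                         nCodingGenes = cfg$nCodingGenes,
                                         nNoncodingGenes = cfg$nNoncodingGenes,
                                         nIntergenicPromoters = 2L,
                                         siteSpec = cfg$siteSpec,
                                         depths = cfg$depths))
  expect_false(identical(GenomicRanges::start(fx3$tags$Rest_ES),
                         GenomicRanges::start(fx$tags$Rest_ES)))
})

test_that("knock-down induction concentrates near the configured fold", {
  fx <- smallFixture()
  genes <- fx$genes
  lamCnt <- function(sample) GenomicRanges::countOverlaps(
    genes, fx$tags[[sample]], ignore.strand = TRUE)
  ctrl <- lamCnt("mRNA_ctrl"); kd <- lamCnt("mRNA_kd")
  induced <- genes$gene_id %in%
    fx$truth$genes$gene_id[fx$truth$genes$kdFold > 1]
  ratio <- kd[induced] / pmax(ctrl[induced], 1)
  expect_true(all(ctrl[induced] >= 50))
  expect_true(all(ratio >= 3 & ratio <= 5.3))
})

test_that("fixtures round-trip through disk byte-identically", {
  fx <- smallFixture()
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  writeFixture(fx, d1)
  writeFixture(generateFixture(smallConfig()), d2)

  # identical config + seed -> byte-identical files
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # round-trip reproduces the in-memory objects
  back <- readFixture(d1)
  expect_equal(GenomeInfoDb::seqlengths(back$seqinfo),
               GenomeInfoDb::seqlengths(fx$seqinfo))
  expect_equal(back$genes$gene_id, fx$genes$gene_id)
  expect_identical(GenomicRanges::start(back$tags$Rest_ES),
                   GenomicRanges::start(fx$tags$Rest_ES))
  expect_equal(back$truth$sites, fx$truth$sites)
  expect_equal(back$truth$genes, fx$truth$genes, tolerance = 1e-6)

  # manifest hash changes iff the config changes
  m1 <- readLines(file.path(d1, "manifest.yaml"))
  d3 <- file.path(tempdir(), "fx3")
  cfgB <- smallConfig(seed = 8L)
  writeFixture(generateFixture(cfgB), d3)
  m3 <- readLines(file.path(d3, "manifest.yaml"))
  expect_false(identical(m1[2], m3[2]))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("flat enrichment makes chip indistinguishable from input", {
  cfg <- smallConfig()
  spec <- cfg$siteSpec
  spec$enrichment <- 1.0000001  # effectively flat
  cfgFlat <- syntheticConfig(seed = 7L, genome = cfg$genome,
                             nCodingGenes = cfg$nCodingGenes,
                             nNoncodingGenes = cfg$nNoncodingGenes,
                             nIntergenicPromoters = 2L,
                             siteSpec = spec, depths = cfg$depths)
  ann <- generateAnnotation(cfgFlat)
  truth <- plantSites(cfgFlat, ann)
  sim <- simulateTags(truth, cfgFlat, ann)
  chipPos <- GenomicRanges::start(sim$tags$Rest_ES)
  inputPos <- GenomicRanges::start(sim$tags$input_ES)
  ks <- suppressWarnings(stats::ks.test(chipPos, inputPos))
  expect_gt(ks$p.value, 0.01)
})
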