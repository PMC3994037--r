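test_that("rpkm follows the tags-per-kilobase-per-million formula", {
  expect_equal(computeRpkm(1000, 1000, 1e6), 1000)
  expect_equal(computeRpkm(0, 2000, 1e7), 0)
  expect_equal(computeRpkm(250, 2500, 1e7), 10)  # 250 / (2.5 * 10)

  # linear in count, inverse-linear in length and library
  expect_equal(computeRpkm(500, 1000, 1e6), computeRpkm(1000, 1000, 1e6) / 2)
  expect_equal(computeRpkm(1000, 2000, 1e6), computeRpkm(1000, 1000, 1e6) / 2)
  expect_equal(computeRpkm(1000, 1000, 2e6), computeRpkm(1000, 1000, 1e6) / 2)

  expect_error(computeRpkm(10, 0, 1e6), "geneLength")
  expect_error(computeRpkm(10, 1000, 0), "librarySize")
})

test_that("fold change applies the pseudocount symmetrically", {
  expect_equal(foldChange(7, 7), 1)
  expect_equal(foldChange(0, 0), 1)
  expect_equal(foldChange(9, 4), 2)          # (9+1)/(4+1)
  expect_equal(foldChange(3, 7, 2), 0.5556, tolerance = 1e-3)
  expect_error(foldChange(1, 1, pseudocount = 0))
})

test_that("target selection applies the strict 2-fold rule on rpkm scale", {
  cg <- data.frame(gene_id = c("gA", "gB", "gC"),
                   specificity = "common", cobind = "R+/S+/L+")
  ctrl <- data.frame(gene_id = c("gA", "gB", "gC"),
                     tag_count = c(100, 4, 40))
  kd <- data.frame(gene_id = c("gA", "gB", "gC"),
                   tag_count = c(252, 9, 40))
  calls <- selectTargets(cg, ctrl, kd, ctrlLibSize = 1e6, kdLibSize = 1e6)
  # gA: (252+1)/(100+1) = 2.50 -> target
  expect_true(calls$is_target[calls$gene_id == "gA"])
  # gB: (9+1)/(4+1) = 2 exactly -> NOT a target (strict >)
  expect_equal(calls$kd_fold[calls$gene_id == "gB"], 2)
  expect_false(calls$is_target[calls$gene_id == "gB"])
  expect_false(calls$is_target[calls$gene_id == "gC"])

  # library-size scaling enters the fold
  calls2 <- selectTargets(cg, ctrl, kd, ctrlLibSize = 1e6, kdLibSize = 2e6)
  expect_equal(calls2$kd_fold, calls$kd_fold / 2)

  # missing gene excluded with a warning
  expect_warning(
    part <- selectTargets(cg, ctrl[1:2, ], kd, ctrlLibSize = 1e6,
                          kdLibSize = 1e6),
    "missing")
  expect_equal(nrow(part), 2)

  # monotone: raising the threshold never adds targets
  set.seed(97)
  cgR <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    specificity = sample(c("unique", "common"), 200, TRUE),
                    cobind = sample(setdiff(cobindClasses(), "R+/S-/L-"),
                                    200, TRUE))
  ctrlR <- data.frame(gene_id = cgR$gene_id,
                      tag_count = rpois(200, 50))
  kdR <- data.frame(gene_id = cgR$gene_id,
                    tag_count = rpois(200, 80))
  lo <- selectTargets(cgR, ctrlR, kdR, 1e6, 1e6, threshold = 1.5)
  hi <- selectTargets(cgR, ctrlR, kdR, 1e6, 1e6, threshold = 2.5)
  expect_true(all(hi$is_target <= lo$is_target))
})

test_that("target rate table reproduces the printed induction percentages", {
  mkCalls <- function(spec, cobind, total, induced) {
    data.frame(gene_id = sprintf("%s_%s_%d", spec, cobind, seq_len(total)),
               specificity = spec, cobind = cobind,
               kd_fold = c(rep(3, induced), rep(1, total - induced)),
               is_target = c(rep(TRUE, induced),
                             rep(FALSE, total - induced)))
  }
  # coding-gene panel of the knock-down target table
  calls <- rbind(
    mkCalls("common", "R+/S+/L+", 624, 117),
    mkCalls("common", "R+/S+/L-", 255, 27),
    mkCalls("common", "R+/S-/L+", 125, 10),
    mkCalls("unique", "R+/S+/L+", 393, 23),
    mkCalls("unique", "R+/S+/L-", 435, 29),
    mkCalls("unique", "R+/S-/L+", 350, 10)
  )
  tab <- targetRateTable(calls)
  pick <- function(spec, cb) tab$percent[tab$specificity == spec &
                                           tab$cobind == cb]
  expect_equal(pick("common", "R+/S+/L+"), 19L)
  expect_equal(pick("common", "R+/S+/L-"), 11L)
  expect_equal(pick("common", "R+/S-/L+"), 8L)
  expect_equal(pick("unique", "R+/S+/L+"), 6L)
  expect_equal(pick("unique", "R+/S+/L-"), 7L)
  expect_equal(pick("unique", "R+/S-/L+"), 3L)

  # zero induced and empty categories
  none <- mkCalls("common", "R+/S+/L+", 100, 0)
  t0 <- targetRateTable(none)
  expect_equal(t0$percent[t0$specificity == "common" &
                            t0$cobind == "R+/S+/L+"], 0L)
  expect_true(all(t0$empty[t0$total == 0]))
  expect_equal(t0$percent[t0$empty], rep(0L, sum(t0$empty)))
})

test_that("TSS-based gene expression sums associated cluster counts", {
  genes <- gr("chr1", c(100001, 300001), c(110000, 310000), c("+", "+"))
  S4Vectors::mcols(genes)$gene_id <- c("gA", "gB")
  S4Vectors::mcols(genes)$coding <- TRUE
  tg <- tagRanges(rep("chr1", 30),
                  c(rep(100010, 10), rep(100900, 5), rep(300010, 15)),
                  "+")
  cl <- associateClusterToGene(clusterTssTags(tg, librarySize = 30), genes)
  ex <- geneTssExpression(cl)
  expect_equal(ex$tag_count[ex$gene_id == "gA"], 15L)
  expect_equal(ex$tag_count[ex$gene_id == "gB"], 15L)
  expect_equal(sum(ex$tag_count), 30L)
})

test_that("non-induced genes concentrate near fold 1 in synthetic data", {
  fx <- smallFixture()
  genes <- fx$genes
  cnt <- function(sample) GenomicRanges::countOverlaps(
    genes, fx$tags[[sample]], ignore.strand = TRUE)
  ctrl <- data.frame(gene_id = genes$gene_id, tag_count = cnt("mRNA_ctrl"))
  kd <- data.frame(gene_id = genes$gene_id, tag_count = cnt("mRNA_kd"))
  cg <- data.frame(gene_id = genes$gene_id, specificity = "common",
                   cobind = "R+/S+/L+")
  calls <- selectTargets(cg, ctrl, kd,
                         ctrlLibSize = length(fx$tags$mRNA_ctrl),
                         kdLibSize = length(fx$tags$mRNA_kd))
  induced <- fx$truth$genes$gene_id[fx$truth$genes$kdFold > 1]
  nonInduced <- calls$kd_fold[!calls$gene_id %in% induced]
  expect_gte(median(nonInduced), 0.8)
  expect_lte(median(nonInduced), 1.25)
  # every planted induced gene clears the strict 2-fold rule
  expect_true(all(calls$is_target[calls$gene_id %in% induced]))
})
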