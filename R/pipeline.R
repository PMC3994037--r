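## End-to-end orchestration: preprocess -> classify -> compare -> associate
## -> express -> targets -> report, plus the summary tables, persistence and
## truth-recovery evaluation.

#' Pipeline parameters
#'
#' All tunable constants of the analysis in one place; the defaults are the
#' study's operating values (peak p-value cutoff 1e-10, 50 kb gene flank,
#' 500-base TSS bins, 5 ppm novel-lncRNA cutoff, 2-fold knock-down rule,
#' +/-500 b profiles with the 25-fold mask, +/-50 b conservation windows).
#'
#' @param pThreshold Peak p-value cutoff (strict `<`).
#' @param flank Site/cluster-to-gene 5'-end distance in bases.
#' @param tssBin TSS clustering bin width in bases.
#' @param ppmCutoff Strict ppm cutoff for novel lncRNA TSS clusters.
#' @param kdFoldThreshold Strict knock-down fold-change cutoff.
#' @param profileHalfWidth Profile half window in bases.
#' @param maskFold Profile mask fold threshold.
#' @param conservationHalf Conservation half window in bases.
#' @param pseudocount Pseudocount for intensities and fold changes.
#' @param extension ChIP fragment extension in bases.
#' @param windowSize,step Sliding-window size/step of the stand-in peak
#'   scorer.
#' @param depthTolerance Depth-matching tolerance.
#' @param seed Seed for the depth-matching subsampling.
#' @return Named list of parameters.
#' @export
pipelineParams <- function(pThreshold = 1e-10, flank = 50000L,
                           tssBin = 500L, ppmCutoff = 5,
                           kdFoldThreshold = 2, profileHalfWidth = 500L,
                           maskFold = 25, conservationHalf = 50L,
                           pseudocount = 1, extension = 200L,
                           windowSize = 300L, step = 100L,
                           depthTolerance = 0.10, seed = 1L) {
  p <- list(pThreshold = pThreshold, flank = flank, tssBin = tssBin,
            ppmCutoff = ppmCutoff, kdFoldThreshold = kdFoldThreshold,
            profileHalfWidth = profileHalfWidth, maskFold = maskFold,
            conservationHalf = conservationHalf, pseudocount = pseudocount,
            extension = extension, windowSize = windowSize, step = step,
            depthTolerance = depthTolerance, seed = as.integer(seed))
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))))
  p
}

## internal: novel TSS clusters recast as gene models so they can join the
## annotated non-coding genes as one association universe
tscAsGenes <- function(novel) {
  gr <- GenomicRanges::granges(novel)
  S4Vectors::mcols(gr)$gene_id <- sprintf(
    "TSC_%s_%d_%s", as.character(GenomeInfoDb::seqnames(gr)), start(gr),
    as.character(strand(gr)))
  S4Vectors::mcols(gr)$coding <- rep(FALSE, length(gr))
  gr
}

## internal: site count and distinct associated gene count for one site set
## against one gene universe
associationCounts <- function(sites, genes, flank) {
  assoc <- associateSiteToGenes(sites, genes, flank)
  hasGene <- lengths(assoc) > 0L
  list(nSites = sum(hasGene),
       nGenes = length(unique(unlist(assoc[hasGene]))),
       assoc = assoc)
}

## internal: per-class association rows for table 2/3 style panels
classAssociationRows <- function(sites, assoc, classes) {
  hasGene <- lengths(assoc) > 0L
  cl <- cobindClass(sites)
  do.call(rbind, lapply(classes, function(k) {
    sel <- cl == k & hasGene
    data.frame(cobind = k, sites = sum(sel),
               genes = length(unique(unlist(assoc[sel]))))
  }))
}

#' Run the full analysis pipeline
#'
#' Executes the stage order preprocess (duplicate filtering, depth matching,
#' peak scoring, p-value filtering) -> co-binding classification -> cross-cell
#' comparison -> gene/lncRNA association (with TSS clustering and novel-TSC
#' discovery) -> expression quantification -> knock-down target selection ->
#' report. Deterministic given the inputs and `params$seed`.
#'
#' @param tags Named list of width-1 tag [GenomicRanges::GRanges]. Required
#'   names: `Rest_ES`, `Sin3A_ES`, `Lsd1_ES`, `input_ES`, `Rest_EpiS`,
#'   `Sin3A_EpiS`, `Lsd1_EpiS`, `input_EpiS`, `TSS_ES`, `TSS_EpiS`,
#'   `mRNA_ctrl`, `mRNA_kd`. Alternatively pre-called peaks can be supplied
#'   via `peaks`.
#' @param genes Gene model [GenomicRanges::GRanges] (`gene_id`, `coding`).
#' @param seqinfo [GenomeInfoDb::Seqinfo] of the genome.
#' @param conservation Optional conservation track (`score` column).
#' @param peaks Optional named list of pre-called peak [GenomicRanges::GRanges]
#'   (`Rest_ES`, ..., `Lsd1_EpiS`) that bypasses the stand-in peak scorer.
#' @param params [pipelineParams()].
#' @param outDir Optional directory; when given, per-stage artifacts (peaks as
#'   narrowPeak, classified sites, target calls) and the summary tables are
#'   persisted there.
#' @return A [SummaryReport-class].
#' @export
runPipeline <- function(tags, genes, seqinfo, conservation = NULL,
                        peaks = NULL, params = pipelineParams(),
                        outDir = NULL) {
  cells <- c("ES", "EpiS")
  factors <- c("Rest", "Sin3A", "Lsd1")
  needTags <- c(outer(c(factors, "input"), cells, paste, sep = "_"),
                paste("TSS", cells, sep = "_"), "mRNA_ctrl", "mRNA_kd")
  for (nm in needTags)
    if (is.null(tags[[nm]]))
      stop("missing sample: ", sub("_", "/", nm))

  ## stage 1: preprocess and call peaks (unless pre-called peaks supplied)
  calledPeaks <- list()
  for (cell in cells) {
    inputDedup <- filterDuplicates(tags[[paste0("input_", cell)]])
    for (fac in factors) {
      key <- paste(fac, cell, sep = "_")
      if (!is.null(peaks[[key]])) {
        calledPeaks[[key]] <- filterPeaksByPvalue(peaks[[key]],
                                                  params$pThreshold)
        next
      }
      chip <- filterDuplicates(tags[[key]])
      md <- matchDepth(chip, inputDedup, tolerance = params$depthTolerance,
                       seed = subSeed(params$seed, paste("depth", key)))
      pk <- scoreCandidatePeaks(md$chip, md$input, seqinfo,
                                windowSize = params$windowSize,
                                step = params$step,
                                pThreshold = params$pThreshold,
                                extension = params$extension)
      calledPeaks[[key]] <- filterPeaksByPvalue(pk, params$pThreshold)
    }
  }

  ## stage 2: co-binding classification per cell
  classified <- list(
    ES = classifyCobinding(calledPeaks$Rest_ES, calledPeaks$Sin3A_ES,
                           calledPeaks$Lsd1_ES, cell = "ES"),
    EpiS = classifyCobinding(calledPeaks$Rest_EpiS, calledPeaks$Sin3A_EpiS,
                             calledPeaks$Lsd1_EpiS, cell = "EpiS")
  )

  ## stage 3: drop Rest-only sites, compare cells
  kept <- lapply(classified, dropRestOnly)
  cmp <- compareCells(kept$ES, kept$EpiS)
  compared <- list(ES = cmp$a, EpiS = cmp$b)

  ## stage 4: TSS clustering, novel lncRNA TSCs, gene universes per cell
  clusters <- list(); novel <- list(); universes <- list()
  codingGenes <- genes[genes$coding]
  ncGenes <- genes[!genes$coding]
  for (cell in cells) {
    cl <- clusterTssTags(tags[[paste0("TSS_", cell)]], bin = params$tssBin)
    cl <- associateClusterToGene(cl, genes, flank = params$flank)
    nv <- identifyNovelLncTscs(cl, ppmCutoff = params$ppmCutoff)
    clusters[[cell]] <- cl
    novel[[cell]] <- nv
    universes[[cell]] <- list(coding = codingGenes,
                              noncoding = c(ncGenes, tscAsGenes(nv)))
  }

  ## table 1: per factor x cell, associated site/gene counts per universe
  table1 <- do.call(rbind, lapply(cells, function(cell) {
    do.call(rbind, lapply(factors, function(fac) {
      pk <- calledPeaks[[paste(fac, cell, sep = "_")]]
      co <- associationCounts(pk, universes[[cell]]$coding, params$flank)
      nc <- associationCounts(pk, universes[[cell]]$noncoding, params$flank)
      data.frame(cell = cell, factor = fac,
                 coding_sites = co$nSites, coding_genes = co$nGenes,
                 noncoding_sites = nc$nSites, noncoding_genes = nc$nGenes)
    }))
  }))

  ## table 2: co-binding class composition per cell and gene universe
  table2 <- do.call(rbind, lapply(cells, function(cell) {
    s <- classified[[cell]]
    aco <- associateSiteToGenes(s, universes[[cell]]$coding, params$flank)
    anc <- associateSiteToGenes(s, universes[[cell]]$noncoding, params$flank)
    co <- classAssociationRows(s, aco, cobindClasses())
    nc <- classAssociationRows(s, anc, cobindClasses())
    data.frame(cell = cell, cobind = co$cobind,
               coding_sites = co$sites, coding_genes = co$genes,
               noncoding_sites = nc$sites, noncoding_genes = nc$genes)
  }))

  ## table 3: cross-cell overlap per category, class and gene universe
  catOf <- list(
    `ES-unique` = list(cell = "ES", spec = "unique"),
    `Common (ES)` = list(cell = "ES", spec = "common"),
    `Common (EpiS)` = list(cell = "EpiS", spec = "common"),
    `EpiS-unique` = list(cell = "EpiS", spec = "unique")
  )
  classes3 <- setdiff(cobindClasses(), "R+/S-/L-")
  table3 <- do.call(rbind, lapply(names(catOf), function(cat) {
    cell <- catOf[[cat]]$cell
    s <- compared[[cell]]
    sel <- siteSpecificity(s) == catOf[[cat]]$spec
    sub <- s[sel]
    aco <- associateSiteToGenes(sub, universes[[cell]]$coding, params$flank)
    anc <- associateSiteToGenes(sub, universes[[cell]]$noncoding,
                                params$flank)
    co <- classAssociationRows(sub, aco, classes3)
    nc <- classAssociationRows(sub, anc, classes3)
    totRow <- data.frame(cobind = "Total",
                         sites = sum(lengths(aco) > 0L),
                         genes = length(unique(unlist(aco))))
    totRowNc <- data.frame(cobind = "Total",
                           sites = sum(lengths(anc) > 0L),
                           genes = length(unique(unlist(anc))))
    data.frame(category = cat,
               cobind = c(totRow$cobind, co$cobind),
               coding_sites = c(totRow$sites, co$sites),
               coding_genes = c(totRow$genes, co$genes),
               noncoding_sites = c(totRowNc$sites, nc$sites),
               noncoding_genes = c(totRowNc$genes, nc$genes))
  }))

  ## stage 5: chromatin-signal profiles over the ES site set (one per
  ## factor, rows shared and sorted by descending Rest intensity), plus
  ## per-site conservation when a track is supplied
  profiles <- NULL
  conservationMeans <- NULL
  if (length(compared$ES)) {
    restKey <- siteIntensity(tags$Rest_ES, tags$input_ES, compared$ES,
                             pseudocount = params$pseudocount)
    profiles <- lapply(factors, function(fac) {
      profileMatrix(compared$ES, tags[[paste0(fac, "_ES")]],
                    input = tags$input_ES,
                    halfWidth = params$profileHalfWidth,
                    extension = params$extension,
                    pseudocount = params$pseudocount,
                    factorLabel = fac, sortBy = restKey)
    })
    names(profiles) <- factors
    if (!is.null(conservation))
      conservationMeans <- meanConservation(compared$ES, conservation,
                                            half = params$conservationHalf)
  }

  ## stage 6: expression quantification
  mrnaUniverse <- c(GenomicRanges::granges(genes),
                    GenomicRanges::granges(tscAsGenes(novel$ES)))
  mrnaIds <- c(genes$gene_id, tscAsGenes(novel$ES)$gene_id)
  exprOf <- function(sample) {
    cnt <- GenomicRanges::countOverlaps(mrnaUniverse, tags[[sample]],
                                        ignore.strand = TRUE)
    data.frame(gene_id = mrnaIds, tag_count = cnt,
               gene_length = width(mrnaUniverse),
               rpkm = computeRpkm(cnt, width(mrnaUniverse),
                                  max(length(tags[[sample]]), 1L)))
  }
  exprCtrl <- exprOf("mRNA_ctrl")
  exprKd <- exprOf("mRNA_kd")
  tssExpr <- lapply(clusters, geneTssExpression)

  ## stage 7: knock-down target selection on the ES comparison
  esSites <- compared$ES
  assocCo <- associateSiteToGenes(esSites, universes$ES$coding, params$flank)
  assocNc <- associateSiteToGenes(esSites, universes$ES$noncoding,
                                  params$flank)
  geneRows <- function(assoc) {
    idx <- rep(seq_along(assoc), lengths(assoc))
    if (!length(idx))
      return(data.frame(gene_id = character(0), specificity = character(0),
                        cobind = character(0)))
    unique(data.frame(gene_id = unlist(assoc),
                      specificity = siteSpecificity(esSites)[idx],
                      cobind = cobindClass(esSites)[idx]))
  }
  targetCalls <- list(
    coding = selectTargets(geneRows(assocCo), exprCtrl, exprKd,
                           ctrlLibSize = length(tags$mRNA_ctrl),
                           kdLibSize = length(tags$mRNA_kd),
                           threshold = params$kdFoldThreshold,
                           pseudocount = params$pseudocount),
    noncoding = selectTargets(geneRows(assocNc), exprCtrl, exprKd,
                              ctrlLibSize = length(tags$mRNA_ctrl),
                              kdLibSize = length(tags$mRNA_kd),
                              threshold = params$kdFoldThreshold,
                              pseudocount = params$pseudocount)
  )
  rateCo <- targetRateTable(targetCalls$coding)
  rateNc <- targetRateTable(targetCalls$noncoding)
  table4 <- rbind(cbind(panel = "coding", rateCo),
                  cbind(panel = "noncoding", rateNc))

  report <- new("SummaryReport",
    tables = list(table1 = table1, table2 = table2, table3 = table3,
                  table4 = table4),
    details = list(peaks = calledPeaks, classified = classified,
                   compared = compared, compareCounts = cmp$counts,
                   clusters = clusters, novelTscs = novel,
                   profiles = profiles,
                   conservationMeans = conservationMeans,
                   exprCtrl = exprCtrl, exprKd = exprKd,
                   tssExpr = tssExpr, targetCalls = targetCalls,
                   mrnaLibSizes = c(ctrl = length(tags$mRNA_ctrl),
                                    kd = length(tags$mRNA_kd)),
                   params = params),
    provenance = list(seed = params$seed,
                      paramHash = sprintf("%010.0f", fnv1a32(
                        paste(deparse(params), collapse = "\n"))),
                      packageVersion = as.character(
                        utils::packageVersion("restcobind")))
  )
  checkReportConsistency(report)
  if (!is.null(outDir)) persistPipeline(report, outDir)
  report
}

#' Run the pipeline on an on-disk fixture
#'
#' @param dir Fixture directory (see [writeFixture()]).
#' @param params [pipelineParams()].
#' @param outDir Optional artifact directory, passed to [runPipeline()].
#' @return A [SummaryReport-class].
#' @export
runPipelineOnFixture <- function(dir, params = pipelineParams(),
                                 outDir = NULL) {
  fx <- readFixture(dir)
  runPipeline(fx$tags, fx$genes, fx$seqinfo,
              conservation = fx$conservation, params = params,
              outDir = outDir)
}

## internal: cross-table consistency assertions
checkReportConsistency <- function(report) {
  t1 <- report@tables$table1
  t2 <- report@tables$table2
  t3 <- report@tables$table3
  for (cell in unique(t1$cell)) {
    restCo <- t1$coding_sites[t1$cell == cell & t1$factor == "Rest"]
    sumCo <- sum(t2$coding_sites[t2$cell == cell])
    if (restCo != sumCo)
      stop("inconsistent report: table2 coding class counts for ", cell,
           " sum to ", sumCo, " but table1 Rest count is ", restCo)
  }
  cnt <- report@details$compareCounts
  nES <- length(report@details$compared$ES)
  nEpiS <- length(report@details$compared$EpiS)
  if (cnt[["a_unique"]] + cnt[["common_a"]] != nES ||
      cnt[["b_unique"]] + cnt[["common_b"]] != nEpiS)
    stop("inconsistent report: cross-cell counts do not partition the sites")
  invisible(TRUE)
}

## internal: persist per-stage artifacts
persistPipeline <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report@details$peaks))
    writeNarrowPeak(report@details$peaks[[nm]],
                    file.path(outDir, paste0("peaks_", nm, ".narrowPeak")))
  for (cell in names(report@details$compared))
    writeClassifiedSites(report@details$compared[[cell]],
                         file.path(outDir,
                                   paste0("sites_", cell, ".bed")))
  for (panel in names(report@details$targetCalls))
    utils::write.table(report@details$targetCalls[[panel]],
                       file.path(outDir,
                                 paste0("targets_", panel, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  emitTables(report, outDir)
  invisible(outDir)
}

#' Write the summary tables as TSV
#'
#' One TSV per table, counts and gene counts as separate integer columns (no
#' literal parentheses), percentages as integer columns.
#'
#' @param report A [SummaryReport-class].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
emitTables <- function(report, dir) {
  stopifnot(is(report, "SummaryReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report@tables))
    utils::write.table(report@tables[[nm]],
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read emitted summary tables back
#'
#' @param dir Directory written by [emitTables()].
#' @return Named list of data frames (`table1` ... `table4`).
#' @export
loadTables <- function(dir) {
  files <- list.files(dir, pattern = "^table[0-9]+\\.tsv$",
                      full.names = TRUE)
  out <- lapply(files, utils::read.table, sep = "\t", header = TRUE,
                check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Write classified sites as extended BED
#'
#' BED6 plus columns: co-binding class, specificity, Sin3A and Lsd1 partner
#' counts.
#'
#' @param sites A [ClassifiedSites-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeClassifiedSites <- function(sites, path) {
  stopifnot(is(sites, "ClassifiedSites"))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sites)),
    start = start(sites) - 1L,
    end = end(sites),
    name = sprintf("site_%d", seq_along(sites)),
    score = 0L,
    strand = ".",
    cobind = cobindClass(sites),
    specificity = ifelse(is.na(siteSpecificity(sites)), ".",
                         siteSpecificity(sites)),
    nSin3a = S4Vectors::mcols(sites)$nSin3a,
    nLsd1 = S4Vectors::mcols(sites)$nLsd1
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- truth recovery ---------------------------------------------------------

#' Evaluate pipeline recovery of planted truth
#'
#' For every planted (site, occupied cell) instance: was a Rest peak detected
#' overlapping the planted interval, with the planted co-binding class, and
#' (for sites that survive the Rest-only filter) the planted cross-cell
#' specificity? Also checks the knock-down rule against the planted induced
#' genes.
#'
#' @param report A [SummaryReport-class] from [runPipeline()].
#' @param truth A `SyntheticTruth` from [plantSites()].
#' @return List: `siteInstances` (data frame, one row per planted site x
#'   occupied cell with logicals `detected`, `classOk`, `specOk`, `correct`),
#'   `siteRecovery` (fraction correct), `inducedRecovery` (fraction of
#'   planted induced genes called targets), `falseTargets` (non-induced genes
#'   called targets).
#' @export
compareToTruth <- function(report, truth) {
  stopifnot(is(report, "SummaryReport"), inherits(truth, "SyntheticTruth"))
  rows <- list()
  for (cell in c("ES", "EpiS")) {
    occ <- truth$sites$occupancy %in% c("both", paste0(cell, "-only"))
    st <- truth$sites[occ, , drop = FALSE]
    if (!nrow(st)) next
    gr <- GenomicRanges::GRanges(st$chrom,
                                 IRanges::IRanges(st$start, st$end))
    cls <- report@details$classified[[cell]]
    hit <- GenomicRanges::findOverlaps(gr, cls, ignore.strand = TRUE)
    detected <- logical(nrow(st)); classOk <- logical(nrow(st))
    if (length(hit)) {
      qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
      detected[unique(qh)] <- TRUE
      okIdx <- qh[cobindClass(cls)[sh] == st$cobind[qh]]
      classOk[unique(okIdx)] <- TRUE
    }
    needSpec <- st$cobind != "R+/S-/L-"
    expSpec <- ifelse(st$occupancy == "both", "common", "unique")
    cmp <- report@details$compared[[cell]]
    specOk <- !needSpec  # sites dropped before comparison are vacuously ok
    hit2 <- GenomicRanges::findOverlaps(gr, cmp, ignore.strand = TRUE)
    if (length(hit2)) {
      qh <- S4Vectors::queryHits(hit2); sh <- S4Vectors::subjectHits(hit2)
      okIdx <- qh[siteSpecificity(cmp)[sh] == expSpec[qh] & needSpec[qh]]
      specOk[unique(okIdx)] <- TRUE
    }
    rows[[cell]] <- data.frame(
      site_id = st$site_id, cell = cell, cobind = st$cobind,
      occupancy = st$occupancy, detected = detected, classOk = classOk,
      specOk = specOk, correct = detected & classOk & specOk)
  }
  inst <- do.call(rbind, rows)
  ## apply the knock-down fold rule over every annotated gene
  p <- report@details$params
  libs <- report@details$mrnaLibSizes
  allGenes <- data.frame(gene_id = truth$genes$gene_id,
                         specificity = "common", cobind = "R+/S+/L+")
  calls <- selectTargets(allGenes, report@details$exprCtrl,
                         report@details$exprKd,
                         ctrlLibSize = libs[["ctrl"]],
                         kdLibSize = libs[["kd"]],
                         threshold = p$kdFoldThreshold,
                         pseudocount = p$pseudocount)
  inducedGenes <- truth$genes$gene_id[truth$genes$kdFold > 1]
  called <- calls$gene_id[calls$is_target]
  list(
    siteInstances = inst,
    siteRecovery = mean(inst$correct),
    inducedRecovery = if (length(inducedGenes))
      mean(inducedGenes %in% called) else NA_real_,
    inducedEvaluated = length(inducedGenes),
    falseTargets = setdiff(called, inducedGenes)
  )
}
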