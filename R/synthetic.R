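## Seeded synthetic-data generator: a toy two-chromosome genome, non-
## overlapping gene models, planted Rest/Sin3A/Lsd1 sites with known
## co-binding class, cell occupancy and knock-down induction structure, and
## Poisson-simulated ChIP/input/TSS/mRNA tags plus a conservation track.
## All randomness flows from one seed through labeled substreams, so adding a
## sample does not perturb the others and identical configs give
## byte-identical fixtures.

#' Synthetic study configuration
#'
#' Defines the simulated study: genome layout, gene counts, the planted-site
#' specification (co-binding class, cell occupancy, ChIP enrichment,
#' knock-down induction), sequencing depths and the fragment model. The
#' defaults describe the standard fixture used throughout the test suite: a
#' 5 Mb genome (4 Mb genic + 1 Mb intergenic), 300 genes, 60 planted sites
#' covering every class x occupancy category at 20-fold enrichment, 30
#' induced genes at 4-fold induction, and 5e5 tags per ChIP/input/TSS sample
#' (1e6 for mRNA).
#'
#' @param seed Integer master seed.
#' @param genome Named integer vector of chromosome lengths.
#' @param genicChrom Chromosome that carries the gene models; the remaining
#'   chromosomes stay gene-free so intergenic TSS clusters exist.
#' @param nCodingGenes,nNoncodingGenes Gene counts.
#' @param nIntergenicPromoters Planted intergenic (novel lncRNA) promoters.
#' @param siteSpec Data frame with columns `cobind`, `occupancy`
#'   (`"both"`, `"ES-only"`, `"EpiS-only"`), `enrichment`, `induced`,
#'   `inductionFold`; one row per planted site. Default: 5 sites in each of
#'   the 12 class x occupancy categories, enrichment 20, alternating induced
#'   flag (30 induced), induction fold 4.
#' @param siteWidth Planted site width in bases (default 200).
#' @param depths Named list of per-sample tag totals: `chip`, `input`, `tss`,
#'   `mrna` (the mRNA depth applies to the control library; the knock-down
#'   total follows from the induction folds).
#' @param fragmentExtension ChIP fragment length in bases (default 200).
#' @param promoterTags Expected TSS tags at each intergenic promoter
#'   (default 100).
#' @return A list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(seed = 42L,
                            genome = c(chr1 = 4000000L, chr2 = 1000000L),
                            genicChrom = "chr1",
                            nCodingGenes = 250L,
                            nNoncodingGenes = 50L,
                            nIntergenicPromoters = 10L,
                            siteSpec = NULL,
                            siteWidth = 200L,
                            depths = list(chip = 500000L, input = 500000L,
                                          tss = 500000L, mrna = 1000000L),
                            fragmentExtension = 200L,
                            promoterTags = 100L) {
  if (is.null(siteSpec)) {
    grid <- expand.grid(cobind = cobindClasses(),
                        occupancy = c("both", "ES-only", "EpiS-only"),
                        rep = seq_len(5),
                        stringsAsFactors = FALSE)
    siteSpec <- data.frame(
      cobind = grid$cobind,
      occupancy = grid$occupancy,
      enrichment = 20,
      induced = rep(c(TRUE, FALSE), length.out = nrow(grid)),
      inductionFold = 4
    )
  }
  stopifnot(all(c("cobind", "occupancy", "enrichment", "induced",
                  "inductionFold") %in% names(siteSpec)),
            all(siteSpec$cobind %in% cobindClasses()),
            all(siteSpec$occupancy %in% c("both", "ES-only", "EpiS-only")),
            all(siteSpec$enrichment > 1),
            all(siteSpec$inductionFold[siteSpec$induced] > 1),
            genicChrom %in% names(genome),
            all(genome > 0))
  cfg <- list(seed = as.integer(seed), genome = genome,
              genicChrom = genicChrom,
              nCodingGenes = as.integer(nCodingGenes),
              nNoncodingGenes = as.integer(nNoncodingGenes),
              nIntergenicPromoters = as.integer(nIntergenicPromoters),
              siteSpec = siteSpec, siteWidth = as.integer(siteWidth),
              depths = depths,
              fragmentExtension = as.integer(fragmentExtension),
              promoterTags = as.integer(promoterTags))
  class(cfg) <- "SyntheticConfig"
  cfg
}

## internal: stable fingerprint of a config (seed included)
configHash <- function(config) {
  sprintf("%010.0f", fnv1a32(paste(deparse(unclass(config)), collapse = "\n")))
}

## internal: Seqinfo of the configured genome
cfgSeqinfo <- function(config) {
  GenomeInfoDb::Seqinfo(seqnames = names(config$genome),
                        seqlengths = unname(config$genome))
}

#' Generate the synthetic genome and gene models
#'
#' Genes are placed without overlap on the genic chromosome by drawing
#' log-uniform lengths in 1-20 kb and separating consecutive genes by random
#' gaps; strands and the coding/non-coding split are random.
#'
#' @param config A [syntheticConfig()].
#' @return List with elements `seqinfo` ([GenomeInfoDb::Seqinfo]) and `genes`
#'   ([GenomicRanges::GRanges] with `gene_id`, `coding`).
#' @export
generateAnnotation <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  si <- GenomeInfoDb::Seqinfo(seqnames = names(config$genome),
                              seqlengths = unname(config$genome))
  n <- config$nCodingGenes + config$nNoncodingGenes
  if (n == 0L) {
    genes <- GenomicRanges::GRanges(seqinfo = si)
    S4Vectors::mcols(genes)$gene_id <- character(0)
    S4Vectors::mcols(genes)$coding <- logical(0)
    return(list(seqinfo = si, genes = genes))
  }
  chromLen <- config$genome[[config$genicChrom]]
  withSeed(subSeed(config$seed, "annotation"), {
    len <- as.integer(round(exp(stats::runif(n, log(1000), log(20000)))))
    slack <- chromLen - sum(len)
    if (slack < n + 1L)
      stop("cannot place ", n, " genes without overlap on ",
           config$genicChrom)
    g <- stats::runif(n + 1L)
    gaps <- floor(g / sum(g) * slack)
    starts <- cumsum(c(1L, len[-n] )) + cumsum(gaps[-(n + 1L)])
    strand <- sample(c("+", "-"), n, replace = TRUE)
    coding <- sample(rep(c(TRUE, FALSE),
                         c(config$nCodingGenes, config$nNoncodingGenes)))
  })
  ids <- character(n)
  ids[coding] <- sprintf("G%03d", seq_len(sum(coding)))
  ids[!coding] <- sprintf("NC%03d", seq_len(sum(!coding)))
  genes <- GenomicRanges::GRanges(config$genicChrom,
                                  IRanges::IRanges(starts,
                                                   width = len),
                                  strand = strand, seqinfo = si)
  S4Vectors::mcols(genes)$gene_id <- ids
  S4Vectors::mcols(genes)$coding <- coding
  list(seqinfo = si, genes = genes)
}

#' Plant binding sites, expression baselines and intergenic promoters
#'
#' Each row of the config's `siteSpec` becomes one planted site, placed
#' upstream of a distinct randomly chosen gene's 5' end (within the 50 kb
#' association rule by construction) with at least 2 kb between sites so
#' neighbouring peaks cannot bleed into each other. Per-gene baseline
#' expression levels are log-uniform in 1-10, except site anchor genes which
#' are drawn low (log-uniform in 0.5-2): repressor-bound genes are repressed
#' at baseline, which also keeps the induced transcript mass a small share of
#' the knock-down library. Genes of induced sites carry the configured
#' knock-down induction fold. Intergenic promoters are placed on the
#' gene-free chromosome.
#'
#' @param config A [syntheticConfig()].
#' @param annotation Output of [generateAnnotation()].
#' @return A list of class `"SyntheticTruth"` with data frames `sites`
#'   (chrom, start, end, cobind, occupancy, enrichment, gene_id, induced,
#'   inductionFold), `genes` (gene_id, exprLevel, kdFold) and `promoters`
#'   (chrom, pos, strand, expectedTags).
#' @export
plantSites <- function(config, annotation) {
  stopifnot(inherits(config, "SyntheticConfig"))
  genes <- annotation$genes
  spec <- config$siteSpec
  nSites <- nrow(spec)
  w <- config$siteWidth
  minGap <- 2000L
  if (nSites > length(genes))
    stop("more planted sites than genes to anchor them to")
  withSeed(subSeed(config$seed, "sites"), {
    anchorGenes <- sample(seq_along(genes), nSites)
    exprLevel <- exp(stats::runif(length(genes), log(1), log(10)))
    ## repressor-bound genes sit at the low end of the expression range
    ## while the repressor is present, so baseline expression of site
    ## anchor genes is drawn low; this also keeps the induced mass a small
    ## share of the knock-down library, as in the real experiment
    exprLevel[anchorGenes] <- exp(stats::runif(nSites, log(0.5), log(2)))
    offsets <- sample(1000:5000, nSites, replace = TRUE)
    promPos <- integer(0)
    if (config$nIntergenicPromoters > 0L) {
      free <- setdiff(names(config$genome), config$genicChrom)
      if (!length(free))
        stop("no gene-free chromosome available for intergenic promoters")
      promChrom <- free[1L]
      span <- config$genome[[promChrom]] - 2000L
      step <- span %/% config$nIntergenicPromoters
      if (step < 2000L) stop("not enough space for intergenic promoters")
      promPos <- 1000L + step * (seq_len(config$nIntergenicPromoters) - 1L) +
        sample.int(step - 1000L, config$nIntergenicPromoters, replace = TRUE)
      promStrand <- sample(c("+", "-"), config$nIntergenicPromoters,
                           replace = TRUE)
    } else {
      promChrom <- character(0); promStrand <- character(0)
    }
  })
  tss <- start(geneTss(genes))[anchorGenes]
  str <- as.character(strand(genes))[anchorGenes]
  chrLen <- config$genome[[config$genicChrom]]
  placed <- IRanges::IRanges()
  starts <- integer(nSites)
  for (i in seq_len(nSites)) {
    off <- offsets[i]
    ok <- FALSE
    for (try in 0:120) {
      o <- off + try * (minGap + w)
      s <- if (str[i] == "+") tss[i] - o - w + 1L else tss[i] + o
      if (is.na(s) || s < 1L || s + w - 1L > chrLen || o + w > 50000L) next
      cand <- IRanges::IRanges(s - minGap, s + w - 1L + minGap)
      if (length(placed) &&
          any(IRanges::overlapsAny(cand, placed))) next
      placed <- c(placed, IRanges::IRanges(s, s + w - 1L))
      starts[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place planted site ", i,
                  " without collision; genome too crowded")
  }
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(nSites)),
    chrom = config$genicChrom,
    start = starts,
    end = starts + w - 1L,
    cobind = spec$cobind,
    occupancy = spec$occupancy,
    enrichment = spec$enrichment,
    gene_id = genes$gene_id[anchorGenes],
    induced = spec$induced,
    inductionFold = ifelse(spec$induced, spec$inductionFold, 1),
    stringsAsFactors = FALSE
  )
  kdFold <- rep(1, length(genes))
  kdFold[anchorGenes[spec$induced]] <-
    spec$inductionFold[spec$induced]
  truth <- list(
    sites = sites,
    genes = data.frame(gene_id = genes$gene_id,
                       exprLevel = exprLevel,
                       kdFold = kdFold,
                       stringsAsFactors = FALSE),
    promoters = if (config$nIntergenicPromoters > 0L)
      data.frame(chrom = promChrom, pos = promPos, strand = promStrand,
                 expectedTags = config$promoterTags,
                 stringsAsFactors = FALSE)
    else data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), expectedTags = integer(0))
  )
  class(truth) <- "SyntheticTruth"
  truth
}

## internal: draw n background tag positions uniformly over the genome
backgroundTags <- function(n, genome, si) {
  lens <- as.numeric(genome)
  chr <- sample(names(genome), n, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(stats::runif(n) * genome[chr]) + 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  GenomicRanges::GRanges(chr, IRanges::IRanges(as.integer(pos), width = 1L),
                         strand = strand, seqinfo = si)
}

## internal: is `factorName` planted at sites of class `cobind`?
factorAtClass <- function(factorName, cobind) {
  switch(factorName,
         Rest = rep(TRUE, length(cobind)),
         Sin3A = grepl("S\\+", cobind),
         Lsd1 = grepl("L\\+", cobind),
         stop("unknown factor: ", factorName))
}

## internal: one ChIP (or input) sample: uniform Poisson background plus
## site-level enrichment at the occupied sites
simulateChipSample <- function(config, truth, factorName, cell, label) {
  depth <- if (factorName == "input") config$depths$input
           else config$depths$chip
  ext <- config$fragmentExtension
  genome <- config$genome
  G <- sum(as.numeric(genome))
  occ <- truth$sites$occupancy %in% c("both", paste0(cell, "-only"))
  occ <- if (factorName == "input") rep(FALSE, nrow(truth$sites))
         else occ & factorAtClass(factorName, truth$sites$cobind)
  siteW <- truth$sites$end - truth$sites$start + 1L
  extraMass <- sum((truth$sites$enrichment[occ] - 1) * siteW[occ])
  lambda0 <- depth / (G + extraMass)
  si <- cfgSeqinfo(config)
  withSeed(subSeed(config$seed, label), {
    nBg <- stats::rpois(1, lambda0 * G)
    bg <- backgroundTags(nBg, genome, si)
    extras <- list()
    for (i in which(occ)) {
      nS <- stats::rpois(1, lambda0 * (truth$sites$enrichment[i] - 1) *
                           siteW[i])
      if (nS == 0L) next
      center <- sample(truth$sites$start[i]:truth$sites$end[i], nS,
                       replace = TRUE)
      strand <- sample(c("+", "-"), nS, replace = TRUE)
      pos5 <- ifelse(strand == "+", center - ext %/% 2L,
                     center + ext %/% 2L)
      pos5 <- pmin(pmax(pos5, 1L), genome[[truth$sites$chrom[i]]])
      extras[[length(extras) + 1L]] <-
        GenomicRanges::GRanges(truth$sites$chrom[i],
                               IRanges::IRanges(as.integer(pos5),
                                                width = 1L),
                               strand = strand, seqinfo = si)
    }
    gr <- if (length(extras)) c(bg, do.call(c, extras)) else bg
  })
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$sample_id <- label
  gr
}

## internal: one TSS-seq sample: per-gene Poisson tag counts proportional to
## expression at the gene 5' end (0-49 b downstream jitter) plus the planted
## intergenic promoters
simulateTssSample <- function(config, truth, annotation, cell, label) {
  genes <- annotation$genes
  depth <- config$depths$tss
  promMass <- sum(truth$promoters$expectedTags)
  e <- truth$genes$exprLevel
  lam <- if (length(e)) (depth - promMass) * e / sum(e) else numeric(0)
  tssPos <- start(geneTss(genes))
  str <- as.character(strand(genes))
  geneChr <- as.character(GenomeInfoDb::seqnames(genes))
  si <- cfgSeqinfo(config)
  withSeed(subSeed(config$seed, label), {
    cnt <- if (length(lam)) stats::rpois(length(lam), lam) else integer(0)
    parts <- list()
    for (i in which(cnt > 0L)) {
      jit <- sample.int(50L, cnt[i], replace = TRUE) - 1L
      pos <- if (str[i] == "+") tssPos[i] + jit else tssPos[i] - jit
      pos <- pmin(pmax(pos, 1L), config$genome[[geneChr[i]]])
      parts[[length(parts) + 1L]] <-
        GenomicRanges::GRanges(geneChr[i],
          IRanges::IRanges(as.integer(pos), width = 1L), strand = str[i],
          seqinfo = si)
    }
    for (j in seq_len(nrow(truth$promoters))) {
      nP <- stats::rpois(1, truth$promoters$expectedTags[j])
      if (nP == 0L) next
      jit <- sample.int(50L, nP, replace = TRUE) - 1L
      pos <- if (truth$promoters$strand[j] == "+")
        truth$promoters$pos[j] + jit else truth$promoters$pos[j] - jit
      pos <- pmin(pmax(pos, 1L), config$genome[[truth$promoters$chrom[j]]])
      parts[[length(parts) + 1L]] <-
        GenomicRanges::GRanges(truth$promoters$chrom[j],
                               IRanges::IRanges(as.integer(pos), width = 1L),
                               strand = truth$promoters$strand[j],
                               seqinfo = si)
    }
    gr <- if (length(parts)) do.call(c, parts)
          else GenomicRanges::GRanges(seqinfo = si)
  })
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$sample_id <- label
  gr
}

## internal: one mRNA-seq sample: per-gene Poisson counts proportional to
## expression x length (times the induction fold under knock-down), tag
## positions uniform over the gene body
simulateMrnaSample <- function(config, truth, annotation, condition, label) {
  genes <- annotation$genes
  depth <- config$depths$mrna
  w <- truth$genes$exprLevel * width(genes) / 1000
  lam <- depth * w / sum(w)
  if (condition == "kd") lam <- lam * truth$genes$kdFold
  chr <- as.character(GenomeInfoDb::seqnames(genes))
  si <- cfgSeqinfo(config)
  withSeed(subSeed(config$seed, label), {
    cnt <- stats::rpois(length(lam), lam)
    parts <- list()
    for (i in which(cnt > 0L)) {
      pos <- start(genes)[i] +
        floor(stats::runif(cnt[i]) * width(genes)[i])
      strand <- sample(c("+", "-"), cnt[i], replace = TRUE)
      parts[[length(parts) + 1L]] <-
        GenomicRanges::GRanges(chr[i],
                               IRanges::IRanges(as.integer(pos), width = 1L),
                               strand = strand, seqinfo = si)
    }
    gr <- if (length(parts)) do.call(c, parts)
          else GenomicRanges::GRanges(seqinfo = si)
  })
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::mcols(gr)$sample_id <- label
  gr
}

## internal: piecewise-constant conservation track: low baseline everywhere,
## elevated windows (+/- 50 b) around the centers of cell-shared sites
simulateConservation <- function(config, truth, baseline = 0.1,
                                 elevated = 0.8, half = 50L) {
  genomeGr <- GenomicRanges::GRanges(
    names(config$genome),
    IRanges::IRanges(1L, unname(config$genome)))
  common <- truth$sites[truth$sites$occupancy == "both", , drop = FALSE]
  if (nrow(common)) {
    center <- (common$start + common$end) %/% 2L
    elev <- GenomicRanges::reduce(GenomicRanges::GRanges(
      common$chrom, IRanges::IRanges(pmax(center - half, 1L),
                                     center + half)))
    base <- GenomicRanges::setdiff(genomeGr, elev, ignore.strand = TRUE)
    S4Vectors::mcols(base)$score <- baseline
    S4Vectors::mcols(elev)$score <- elevated
    track <- GenomicRanges::sort(c(base, elev), ignore.strand = TRUE)
  } else {
    track <- genomeGr
    S4Vectors::mcols(track)$score <- baseline
  }
  track
}

#' Simulate all sequencing samples
#'
#' Generates every tag set of the study design: ChIP for Rest/Sin3A/Lsd1 and
#' input in both cell states, TSS-seq per cell state, and mRNA-seq for the
#' control and Rest knock-down conditions, plus the conservation track.
#' Background tags are uniform Poisson; a factor's tags are enriched only at
#' sites occupied by that factor in that cell; knock-down multiplies induced
#' genes' mRNA rates by the induction fold.
#'
#' @param truth Output of [plantSites()].
#' @param config The [syntheticConfig()] used to build `truth`.
#' @param annotation Output of [generateAnnotation()].
#' @return List with `tags` (named list of width-1 tag
#'   [GenomicRanges::GRanges]: `Rest_ES`, `Sin3A_ES`, `Lsd1_ES`, `input_ES`,
#'   the `_EpiS` counterparts, `TSS_ES`, `TSS_EpiS`, `mRNA_ctrl`,
#'   `mRNA_kd`) and `conservation` (scored [GenomicRanges::GRanges]).
#' @export
simulateTags <- function(truth, config, annotation) {
  stopifnot(inherits(truth, "SyntheticTruth"),
            inherits(config, "SyntheticConfig"))
  tags <- list()
  for (cell in c("ES", "EpiS")) {
    for (fac in c("Rest", "Sin3A", "Lsd1", "input")) {
      label <- paste(fac, cell, sep = "_")
      tags[[label]] <- simulateChipSample(config, truth, fac, cell, label)
    }
    label <- paste("TSS", cell, sep = "_")
    tags[[label]] <- simulateTssSample(config, truth, annotation, cell,
                                       label)
  }
  tags[["mRNA_ctrl"]] <- simulateMrnaSample(config, truth, annotation,
                                            "ctrl", "mRNA_ctrl")
  tags[["mRNA_kd"]] <- simulateMrnaSample(config, truth, annotation,
                                          "kd", "mRNA_kd")
  list(tags = tags,
       conservation = simulateConservation(config, truth))
}

#' Generate a complete in-memory fixture
#'
#' Convenience wrapper: [generateAnnotation()] + [plantSites()] +
#' [simulateTags()].
#'
#' @param config A [syntheticConfig()].
#' @return List with `config`, `seqinfo`, `genes`, `truth`, `tags`,
#'   `conservation`.
#' @export
generateFixture <- function(config = syntheticConfig()) {
  ann <- generateAnnotation(config)
  truth <- plantSites(config, ann)
  sim <- simulateTags(truth, config, ann)
  list(config = config, seqinfo = ann$seqinfo, genes = ann$genes,
       truth = truth, tags = sim$tags, conservation = sim$conservation)
}

#' Write a fixture to disk
#'
#' Writes BED6 tag files (under `tags/`), a refFlat-like gene table, a
#' chrom.sizes file, a bedGraph conservation track, the truth tables, and a
#' YAML-like manifest with the seed and config hash.
#'
#' @param fixture Output of [generateFixture()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(file.path(dir, "tags"), recursive = TRUE, showWarnings = FALSE)
  writeChromSizes(fixture$seqinfo, file.path(dir, "chrom.sizes"))
  writeGeneModels(fixture$genes, file.path(dir, "genes.refflat.tsv"))
  for (nm in names(fixture$tags))
    writeTags(fixture$tags[[nm]], file.path(dir, "tags",
                                            paste0(nm, ".bed")))
  rtracklayer::export(fixture$conservation,
                      file.path(dir, "conservation.bedgraph"),
                      format = "bedGraph")
  utils::write.table(fixture$truth$sites,
                     file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$truth$genes,
                     file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$truth$promoters,
                     file.path(dir, "truth_promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(paste0("seed: ", fixture$config$seed),
                paste0("config_hash: ", configHash(fixture$config)))
  writeLines(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a fixture back from disk
#'
#' Inverse of [writeFixture()]; the returned tag sets, gene models and truth
#' tables reproduce the in-memory objects.
#'
#' @param dir Fixture directory.
#' @return List with `seqinfo`, `genes`, `truth`, `tags`, `conservation`,
#'   `manifest`.
#' @export
readFixture <- function(dir) {
  si <- readChromSizes(file.path(dir, "chrom.sizes"))
  genes <- readGeneModels(file.path(dir, "genes.refflat.tsv"), seqinfo = si)
  tagFiles <- list.files(file.path(dir, "tags"), pattern = "\\.bed$",
                         full.names = TRUE)
  tags <- lapply(tagFiles, readTags)
  names(tags) <- sub("\\.bed$", "", basename(tagFiles))
  truth <- list(
    sites = utils::read.table(file.path(dir, "truth_sites.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE),
    genes = utils::read.table(file.path(dir, "truth_genes.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE),
    promoters = utils::read.table(file.path(dir, "truth_promoters.tsv"),
                                  sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  )
  class(truth) <- "SyntheticTruth"
  cons <- readConservation(file.path(dir, "conservation.bedgraph"))
  manifest <- readLines(file.path(dir, "manifest.yaml"))
  list(seqinfo = si, genes = genes, truth = truth, tags = tags,
       conservation = cons, manifest = manifest)
}
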