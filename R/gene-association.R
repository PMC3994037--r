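## Site-to-gene association through the 50 kb 5'-end rule, TSS tag clustering
## in fixed 500-base bins, and discovery of novel intergenic lncRNA TSS
## clusters. Gene models are GRanges with metadata columns `gene_id` and
## `coding`; the 5' end is the transcription start honoring strand.

#' Read gene models from a refFlat-like TSV
#'
#' Six tab-separated columns without header: gene id, chromosome, strand,
#' transcription start (0-based), transcription end, coding flag (0/1).
#' Coordinates are converted to the in-memory 1-based closed convention.
#'
#' @param path Path to the file.
#' @param seqinfo Optional [GenomeInfoDb::Seqinfo].
#' @return [GenomicRanges::GRanges] with `gene_id` and `coding` columns.
#' @export
readGeneModels <- function(path, seqinfo = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_id", "chrom", "strand",
                                        "txStart", "txEnd", "coding"),
                          colClasses = c("character", "character",
                                         "character", "integer", "integer",
                                         "integer"))
  if (any(df$txEnd <= df$txStart)) stop("gene models must have txEnd > txStart")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$txStart + 1L, df$txEnd),
                               strand = df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$coding <- df$coding == 1L
  if (!is.null(seqinfo))
    GenomeInfoDb::seqinfo(gr) <- seqinfo[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write gene models as refFlat-like TSV
#'
#' @param genes Gene model [GenomicRanges::GRanges] (see [readGeneModels()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(
    gene_id = genes$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(genes)),
    strand = as.character(strand(genes)),
    txStart = start(genes) - 1L,
    txEnd = end(genes),
    coding = as.integer(genes$coding)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12 (or BED6)
#'
#' The BED name column is taken as the gene id. BED carries no coding flag,
#' so one is supplied by the caller.
#'
#' @param path Path to the BED file.
#' @param coding Logical coding flag applied to all records (default `TRUE`).
#' @return [GenomicRanges::GRanges] with `gene_id` and `coding` columns.
#' @export
readGenesBed12 <- function(path, coding = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$gene_id <-
    if (!is.null(gr$name)) gr$name else sprintf("gene_%d", seq_along(gr))
  S4Vectors::mcols(out)$coding <- rep_len(coding, length(gr))
  out
}

#' 5' ends of gene models
#'
#' @param genes Gene model [GenomicRanges::GRanges].
#' @return Width-1 [GenomicRanges::GRanges] at each gene's transcription
#'   start (strand-aware).
#' @export
geneTss <- function(genes) {
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' Associate sites with genes through the 50 kb 5'-end rule
#'
#' A gene is associated with a site when its body overlaps the site, or when
#' its 5' end lies within `flank` bases of the site (distance 0 inside the
#' site; the flank is applied on both sides of the 5' end). A site may map to
#' several genes and a gene may collect several sites.
#'
#' @param sites [GenomicRanges::GRanges] (or [ClassifiedSites-class]).
#' @param genes Gene model [GenomicRanges::GRanges].
#' @param flank Maximum distance in bases from site to gene 5' end
#'   (default 50000).
#' @return List (one element per site) of sorted unique associated gene ids.
#' @export
associateSiteToGenes <- function(sites, genes, flank = 50000L) {
  stopifnot(is(sites, "GRanges"), is(genes, "GRanges"))
  if (!length(sites)) return(list())
  if (!length(genes)) return(rep(list(character(0)), length(sites)))
  u <- unifySeqlevels(GenomicRanges::granges(sites),
                      GenomicRanges::granges(genes))
  geneIds <- genes$gene_id
  sites <- u$a; genes <- u$b
  S4Vectors::mcols(genes)$gene_id <- geneIds
  bodyHits <- GenomicRanges::findOverlaps(sites, genes, ignore.strand = TRUE)
  ## pad sites by `flank`: a TSS point lies in the padded site iff its
  ## point-distance to the site is <= flank (padding is built without
  ## seqlengths so windows may run past chromosome ends)
  padded <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(sites),
    IRanges::IRanges(pmax(1L, start(sites) - as.integer(flank)),
                     end(sites) + as.integer(flank)))
  tssHits <- GenomicRanges::findOverlaps(padded, geneTss(genes),
                                         ignore.strand = TRUE)
  qh <- c(S4Vectors::queryHits(bodyHits), S4Vectors::queryHits(tssHits))
  sh <- c(S4Vectors::subjectHits(bodyHits), S4Vectors::subjectHits(tssHits))
  out <- rep(list(character(0)), length(sites))
  if (length(qh)) {
    byQ <- split(genes$gene_id[sh], qh)
    idx <- as.integer(names(byQ))
    out[idx] <- lapply(byQ, function(g) sort(unique(g)))
  }
  out
}

#' Cluster TSS tags in fixed 500-base bins
#'
#' Per strand, the genome is partitioned into fixed bins
#' `[k*bin, (k+1)*bin)`; each non-empty bin yields one cluster whose tag
#' count is the number of 5'-end tags falling in it, with
#' `ppm = 1e6 * tagCount / librarySize`.
#'
#' @param tags Width-1 stranded TSS tag [GenomicRanges::GRanges].
#' @param bin Bin width in bases (default 500).
#' @param librarySize Total tags in the TSS library (defaults to
#'   `length(tags)`).
#' @return A [TssClusters-class] object (gene associations unset).
#' @export
clusterTssTags <- function(tags, bin = 500L, librarySize = length(tags)) {
  stopifnot(is(tags, "GRanges"))
  if (librarySize <= 0) stop("librarySize must be positive")
  if (!length(tags)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      tagCount = integer(0), ppm = numeric(0), gene = character(0),
      novelLnc = logical(0))
    return(new("TssClusters", gr, librarySize = as.numeric(librarySize)))
  }
  chr <- as.character(GenomeInfoDb::seqnames(tags))
  str <- as.character(strand(tags))
  k <- (start(tags) - 1L) %/% as.integer(bin)
  key <- paste(chr, str, k, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  kk <- as.integer(parts[, 3])
  gr <- GenomicRanges::GRanges(parts[, 1],
                               IRanges::IRanges(kk * bin + 1L,
                                                (kk + 1L) * bin),
                               strand = parts[, 2])
  S4Vectors::mcols(gr)$tagCount <- as.integer(tab)
  S4Vectors::mcols(gr)$ppm <- 1e6 * as.integer(tab) / librarySize
  S4Vectors::mcols(gr)$gene <- rep(NA_character_, length(gr))
  S4Vectors::mcols(gr)$novelLnc <- rep(FALSE, length(gr))
  o <- order(parts[, 1], kk, parts[, 2])
  new("TssClusters", gr[o], librarySize = as.numeric(librarySize))
}

#' Associate TSS clusters with the nearest gene 5' end
#'
#' Each cluster is associated with the gene whose 5' end lies within `flank`
#' bases of the cluster interval and is nearest to it; ties are broken by
#' lexicographic gene id. Only same-strand genes are considered (TSS tags are
#' stranded). Clusters with no qualifying gene keep `NA`.
#'
#' @param clusters A [TssClusters-class] object.
#' @param genes Gene model [GenomicRanges::GRanges].
#' @param flank Maximum distance in bases (default 50000).
#' @return The clusters with the `gene` column filled in.
#' @export
associateClusterToGene <- function(clusters, genes, flank = 50000L) {
  stopifnot(is(clusters, "TssClusters"), is(genes, "GRanges"))
  if (!length(clusters) || !length(genes)) return(clusters)
  u <- unifySeqlevels(GenomicRanges::granges(clusters, use.mcols = FALSE),
                      geneTss(genes))
  tss <- u$b
  clGr <- u$a
  padded <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(clGr),
    IRanges::IRanges(pmax(1L, start(clGr) - as.integer(flank)),
                     end(clGr) + as.integer(flank)),
    strand = strand(clGr))
  hits <- GenomicRanges::findOverlaps(padded, tss, ignore.strand = FALSE)
  gene <- rep(NA_character_, length(clusters))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    d <- pointDistance(clGr[qh], start(tss)[sh])
    gid <- genes$gene_id[sh]
    ord <- order(qh, d, gid)
    first <- !duplicated(qh[ord])
    gene[qh[ord][first]] <- gid[ord][first]
  }
  S4Vectors::mcols(clusters)$gene <- gene
  ## a newly assigned gene invalidates any previous novel-lnc flag
  S4Vectors::mcols(clusters)$novelLnc <-
    S4Vectors::mcols(clusters)$novelLnc & is.na(gene)
  clusters
}

#' Identify novel intergenic lncRNA TSS clusters
#'
#' Flags and returns exactly the clusters with `ppm` strictly above the
#' cutoff and no gene association. These join the annotated non-coding genes
#' as the lncRNA universe of the association tables.
#'
#' @param clusters A [TssClusters-class] object with gene associations filled
#'   (see [associateClusterToGene()]).
#' @param ppmCutoff Strict lower ppm bound (default 5).
#' @return The qualifying clusters, with `novelLnc = TRUE`.
#' @export
identifyNovelLncTscs <- function(clusters, ppmCutoff = 5) {
  stopifnot(is(clusters, "TssClusters"))
  sel <- tagPpm(clusters) > ppmCutoff & is.na(S4Vectors::mcols(clusters)$gene)
  out <- clusters[sel]
  if (length(out)) S4Vectors::mcols(out)$novelLnc <- TRUE
  out
}
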