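## Transcript quantification (TSS ppm, mRNA rpkm), fold changes, and
## selection of knock-down responsive Rest targets.

#' Reads (tags) per kilobase per million
#'
#' `rpkm = tagCount / ((geneLength/1000) * (librarySize/1e6))`.
#'
#' @param tagCount Integer vector of per-gene tag counts.
#' @param geneLength Gene length(s) in bases (> 0).
#' @param librarySize Total mapped tags in the library (> 0).
#' @return Numeric rpkm values.
#' @export
#' @examples
#' computeRpkm(1000, 1000, 1e6)  # 1000
computeRpkm <- function(tagCount, geneLength, librarySize) {
  if (any(geneLength <= 0)) stop("geneLength must be positive")
  if (any(librarySize <= 0)) stop("librarySize must be positive")
  tagCount / ((geneLength / 1000) * (librarySize / 1e6))
}

#' Pseudocounted fold change
#'
#' `(numerator + p) / (denominator + p)`; with both values zero the fold is 1.
#'
#' @param numerator,denominator Non-negative values.
#' @param pseudocount Pseudocount `p` (> 0, default 1).
#' @return Fold change(s).
#' @export
#' @examples
#' foldChange(9, 4)  # 2
foldChange <- function(numerator, denominator, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  (numerator + pseudocount) / (denominator + pseudocount)
}

#' Select knock-down responsive target genes
#'
#' For every (gene, specificity, co-binding class) row, computes the
#' knock-down/control expression fold change on the rpkm scale with a
#' one-tag pseudocount applied before normalization:
#' `((kd + 1)/kdLib) / ((ctrl + 1)/ctrlLib)` (gene length cancels). A gene is
#' a target iff its fold change is strictly greater than `threshold`. Genes
#' missing from either condition are excluded with a warning.
#'
#' @param classifiedGenes Data frame with columns `gene_id`, `specificity`
#'   (`"unique"`/`"common"`), `cobind`.
#' @param ctrl,kd Data frames with columns `gene_id`, `tag_count` for the
#'   control and knock-down conditions.
#' @param ctrlLibSize,kdLibSize Library sizes; default to the column sums.
#' @param threshold Strict fold-change cutoff (default 2).
#' @param pseudocount Tag pseudocount (default 1).
#' @return Data frame with columns `gene_id`, `specificity`, `cobind`,
#'   `kd_fold`, `is_target`.
#' @export
selectTargets <- function(classifiedGenes, ctrl, kd,
                          ctrlLibSize = sum(ctrl$tag_count),
                          kdLibSize = sum(kd$tag_count),
                          threshold = 2, pseudocount = 1) {
  stopifnot(all(c("gene_id", "specificity", "cobind") %in%
                  names(classifiedGenes)),
            all(c("gene_id", "tag_count") %in% names(ctrl)),
            all(c("gene_id", "tag_count") %in% names(kd)))
  ic <- match(classifiedGenes$gene_id, ctrl$gene_id)
  ik <- match(classifiedGenes$gene_id, kd$gene_id)
  miss <- is.na(ic) | is.na(ik)
  if (any(miss)) {
    warning(sum(miss), " gene(s) missing from one condition; excluded: ",
            paste(unique(classifiedGenes$gene_id[miss]), collapse = ", "))
    classifiedGenes <- classifiedGenes[!miss, , drop = FALSE]
    ic <- ic[!miss]; ik <- ik[!miss]
  }
  kdNorm <- (kd$tag_count[ik] + pseudocount) / kdLibSize
  ctrlNorm <- (ctrl$tag_count[ic] + pseudocount) / ctrlLibSize
  fold <- kdNorm / ctrlNorm
  data.frame(
    gene_id = classifiedGenes$gene_id,
    specificity = classifiedGenes$specificity,
    cobind = classifiedGenes$cobind,
    kd_fold = fold,
    is_target = fold > threshold,
    row.names = NULL
  )
}

#' Target rates per specificity and co-binding class
#'
#' Tallies, for every specificity x co-binding category, the total genes, the
#' induced targets and the induced percentage (half-up integer rounding).
#' Empty categories report percent 0 with a flag.
#'
#' @param targetCalls Data frame from [selectTargets()].
#' @return Data frame with columns `specificity`, `cobind`, `total`,
#'   `induced`, `percent`, `empty`.
#' @export
targetRateTable <- function(targetCalls) {
  stopifnot(all(c("specificity", "cobind", "is_target") %in%
                  names(targetCalls)))
  classes <- setdiff(cobindClasses(), "R+/S-/L-")
  specs <- c("unique", "common")
  grid <- expand.grid(specificity = specs, cobind = classes,
                      stringsAsFactors = FALSE)
  key <- paste(targetCalls$specificity, targetCalls$cobind)
  total <- vapply(paste(grid$specificity, grid$cobind),
                  function(k) sum(key == k), integer(1))
  induced <- vapply(paste(grid$specificity, grid$cobind),
                    function(k) sum(targetCalls$is_target[key == k]),
                    integer(1))
  empty <- total == 0L
  percent <- integer(nrow(grid))
  percent[!empty] <- roundHalfUp(100 * induced[!empty] / total[!empty])
  data.frame(grid, total = unname(total), induced = unname(induced),
             percent = percent, empty = empty, row.names = NULL)
}

#' Per-gene expression from TSS clusters
#'
#' The TSS-based expression of a gene is the sum of the tag counts of all
#' clusters associated with it; ppm is recomputed against the cluster
#' library size.
#'
#' @param clusters A [TssClusters-class] with gene associations filled.
#' @return Data frame with columns `gene_id`, `tag_count`, `ppm`.
#' @export
geneTssExpression <- function(clusters) {
  stopifnot(is(clusters, "TssClusters"))
  gene <- S4Vectors::mcols(clusters)$gene
  keep <- !is.na(gene)
  if (!any(keep))
    return(data.frame(gene_id = character(0), tag_count = integer(0),
                      ppm = numeric(0)))
  counts <- tapply(tagCount(clusters)[keep], gene[keep], sum)
  data.frame(gene_id = names(counts),
             tag_count = as.integer(counts),
             ppm = 1e6 * as.integer(counts) / librarySize(clusters),
             row.names = NULL)
}
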