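# Gene-level counting, size-factor/FPKM normalisation and the miCLIP
# over mRNA-seq enrichment comparison.

# per-gene exonic union intervals (IRanges), keyed by contig(+strand)
.geneExonUnions <- function(models, stranded = TRUE) {
  genes <- unique(vapply(models, function(m) m@gene_id, ""))
  out <- list()
  for (g in genes) {
    ms <- Filter(function(m) m@gene_id == g, models)
    ex <- do.call(rbind, lapply(ms, exonIntervals))
    ir <- IRanges::reduce(IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]))
    out[[g]] <- list(contig = ms[[1L]]@contig, strand = ms[[1L]]@strand, ranges = ir)
  }
  out
}

#' Exonic model length per gene (bp of the exon union)
#'
#' @param models list of [TranscriptModel].
#' @return named numeric vector.
#' @export
geneExonicLengths <- function(models) {
  u <- .geneExonUnions(models)
  vapply(u, function(g) sum(IRanges::width(g$ranges)), numeric(1))
}

#' Count reads per gene by exonic overlap
#'
#' A read counts towards a gene when its interval overlaps the gene's
#' exonic union (on the same strand when `stranded`); reads overlapping
#' the exons of more than one gene are discarded as ambiguous.
#'
#' @param aln a [TagAlignments-class].
#' @param models list of [TranscriptModel].
#' @param stranded require matching strand (default TRUE; both the
#'   miCLIP and the mRNA-seq libraries are strand-specific).
#' @return named integer vector over all genes (zeros included), with
#'   attributes `ambiguous` and `unassigned` giving discarded-read counts.
#' @export
countReadsPerGene <- function(aln, models, stranded = TRUE) {
  t <- tagsTable(aln)
  unions <- .geneExonUnions(models)
  genes <- names(unions)
  nhits <- integer(nrow(t))
  hitGene <- rep(NA_character_, nrow(t))
  reads_ir <- IRanges::IRanges(start = t$start + 1L, end = t$end)
  for (g in genes) {
    u <- unions[[g]]
    sel <- t$contig == u$contig & (!stranded | t$strand == u$strand)
    if (!any(sel)) next
    ov <- IRanges::overlapsAny(reads_ir[sel], u$ranges)
    idx <- which(sel)[ov]
    nhits[idx] <- nhits[idx] + 1L
    hitGene[idx] <- g
  }
  assigned <- hitGene[nhits == 1L]
  counts <- table(factor(assigned, levels = genes))
  out <- stats::setNames(as.integer(counts), genes)
  attr(out, "ambiguous") <- sum(nhits > 1L)
  attr(out, "unassigned") <- sum(nhits == 0L)
  out
}

#' Median-of-ratios size factors
#'
#' The DESeq-style size factor: per library, the median over genes of the
#' ratio of its count to the gene's geometric mean across libraries,
#' using only genes with non-zero counts in every library. With fewer
#' than two libraries, or when no gene qualifies, factors fall back to 1
#' with a warning.
#'
#' @param counts genes x libraries numeric matrix.
#' @return numeric vector of per-library size factors.
#' @export
medianRatioSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) return(rep(1, ncol(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no gene with non-zero counts in all libraries; size factors set to 1")
    return(rep(1, ncol(counts)))
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(lg, 2L, function(col) exp(stats::median(col - geo)))
}

#' FPKM after size-factor scaling
#'
#' `fpkm = (count / size_factor) * 1e9 / (exonic_length * total_scaled)`,
#' where `total_scaled` is the library's scaled count total: reads per
#' kilobase of exonic gene model per million (scaled) mapped reads.
#'
#' @param counts genes x libraries matrix (or named vector for one
#'   library).
#' @param exonic_lengths named vector of exon-union lengths (bp).
#' @param size_factors optional; estimated by [medianRatioSizeFactors()]
#'   when NULL.
#' @return matrix of FPKM values, same shape as `counts`.
#' @export
computeFpkm <- function(counts, exonic_lengths, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- medianRatioSizeFactors(counts)
  lens <- exonic_lengths[rownames(counts)]
  if (is.null(rownames(counts))) lens <- exonic_lengths
  scaled <- sweep(counts, 2L, size_factors, "/")
  tot <- colSums(scaled)
  sweep(scaled, 2L, tot, "/") / lens * 1e9
}

#' Per-gene miCLIP vs mRNA-seq expression table
#'
#' Counts both libraries over the same gene models, normalises with
#' median-of-ratios size factors, computes FPKM and the miCLIP/mRNA
#' enrichment ratio, and flags genes carrying at least one CIMS call.
#' Enrichment is NA where the mRNA FPKM is zero.
#'
#' @param miclip_aln,mrna_aln [TagAlignments-class] objects.
#' @param models list of [TranscriptModel].
#' @param sites optional [CimsSites-class]; used with `models` to set
#'   `has_cims` (a site belongs to a gene when its adenosine falls in the
#'   gene's transcript span on the matching strand).
#' @param stranded passed to [countReadsPerGene()].
#' @return data.frame: `gene_id`, `miclip_count`, `mrna_count`,
#'   `miclip_fpkm`, `mrna_fpkm`, `enrichment`, `has_cims`.
#' @export
geneExpressionTable <- function(miclip_aln, mrna_aln, models, sites = NULL,
                                stranded = TRUE) {
  c1 <- countReadsPerGene(miclip_aln, models, stranded = stranded)
  c2 <- countReadsPerGene(mrna_aln, models, stranded = stranded)
  counts <- cbind(miclip = c1, mrna = c2)
  lens <- geneExonicLengths(models)
  fp <- computeFpkm(counts, lens)
  hasCims <- rep(FALSE, nrow(counts))
  names(hasCims) <- rownames(counts)
  if (!is.null(sites) && length(sites)) {
    s <- sitesTable(sites)
    for (tm in models) {
      span <- transcriptSpan(tm)
      hit <- any(s$contig == tm@contig & s$strand == tm@strand &
                   s$apos >= span[1L] & s$apos < span[2L])
      if (hit) hasCims[tm@gene_id] <- TRUE
    }
  }
  data.frame(gene_id = rownames(counts),
             miclip_count = counts[, "miclip"], mrna_count = counts[, "mrna"],
             miclip_fpkm = fp[, "miclip"], mrna_fpkm = fp[, "mrna"],
             enrichment = ifelse(fp[, "mrna"] > 0, fp[, "miclip"] / fp[, "mrna"], NA_real_),
             has_cims = hasCims, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genes enriched in miCLIP signal over mRNA-seq
#'
#' Strictly-greater-than `fold` enrichment of miCLIP FPKM over mRNA FPKM,
#' optionally restricted to genes bearing CIMS calls (the catalogue
#' definition uses >2-fold and requires CIMS).
#'
#' @param records data.frame from [geneExpressionTable()].
#' @param fold fold-change threshold (strict), default 2.
#' @param require_cims restrict to `has_cims` genes, default TRUE.
#' @return character vector of gene ids.
#' @export
enrichedGenes <- function(records, fold = 2.0, require_cims = TRUE) {
  keep <- !is.na(records$enrichment) & records$enrichment > fold
  if (require_cims) keep <- keep & records$has_cims
  records$gene_id[keep]
}

#' Rank correlation of miCLIP and mRNA-seq expression
#'
#' Spearman correlation of log-transformed FPKM with a pseudocount of 1;
#' reported descriptively, not thresholded.
#'
#' @param records data.frame from [geneExpressionTable()].
#' @export
expressionCorrelation <- function(records) {
  stats::cor(log(records$miclip_fpkm + 1), log(records$mrna_fpkm + 1), method = "spearman")
}
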