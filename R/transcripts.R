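#' Transcript model with derived feature segments
#'
#' Stranded exon/CDS structure of one transcript isoform. All coordinates
#' are 0-based half-open genomic intervals on the plus strand of `contig`;
#' `strand` records the transcription direction. `segments` holds the
#' derived interval lists for `five_prime_utr`, `cds`, `three_prime_utr`
#' and `intron` (each a 2-column integer matrix of `[start, end)` rows,
#' sorted by genomic start). When a CDS span is present the UTR and CDS
#' segments exactly partition the exonic space.
#'
#' @slot gene_id,transcript_id identifiers.
#' @slot contig contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons 2-column integer matrix of sorted, non-overlapping exons.
#' @slot cds integer of length 2 (`c(start, end)`, genomic) or length 0.
#' @slot segments named list of 2-column interval matrices.
#' @export
setClass("TranscriptModel", representation(
  gene_id = "character", transcript_id = "character",
  contig = "character", strand = "character",
  exons = "matrix", cds = "integer", segments = "list"
))

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (nrow(ex) == 0L) return("transcript has no exons")
  if (any(ex[, 2L] <= ex[, 1L])) return("exon with non-positive width")
  if (is.unsorted(ex[, 1L], strictly = TRUE) && nrow(ex) > 1L) return("exons not sorted by start")
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) return("overlapping exons")
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  if (length(object@cds) %in% c(0L, 2L) == FALSE) return("cds must be length 0 or 2")
  if (length(object@cds) == 2L) {
    seg <- object@segments
    exonic <- sum(ex[, 2L] - ex[, 1L])
    part <- sum(vapply(seg[c("five_prime_utr", "cds", "three_prime_utr")],
                       function(m) if (nrow(m)) sum(m[, 2L] - m[, 1L]) else 0L, numeric(1)))
    if (part != exonic) return("UTR+CDS segments do not partition exonic space")
  }
  TRUE
})

# derive 5'UTR / CDS / 3'UTR / intron segment matrices from exons + cds span
.deriveSegments <- function(exons, cds, strand) {
  n <- nrow(exons)
  introns <- if (n > 1L) cbind(exons[-n, 2L], exons[-1L, 1L]) else .emptyIntervals()
  if (length(cds) != 2L) {
    return(list(five_prime_utr = .emptyIntervals(), cds = .emptyIntervals(),
                three_prime_utr = .emptyIntervals(), intron = introns))
  }
  cs <- cds[1L]; ce <- cds[2L]
  cdsSeg <- .emptyIntervals(); leftU <- .emptyIntervals(); rightU <- .emptyIntervals()
  for (i in seq_len(n)) {
    s <- exons[i, 1L]; e <- exons[i, 2L]
    if (max(s, cs) < min(e, ce)) cdsSeg <- rbind(cdsSeg, c(max(s, cs), min(e, ce)))
    if (s < min(e, cs)) leftU <- rbind(leftU, c(s, min(e, cs)))
    if (max(s, ce) < e) rightU <- rbind(rightU, c(max(s, ce), e))
  }
  if (strand == "+") {
    list(five_prime_utr = leftU, cds = cdsSeg, three_prime_utr = rightU, intron = introns)
  } else {
    list(five_prime_utr = rightU, cds = cdsSeg, three_prime_utr = leftU, intron = introns)
  }
}

#' Construct a TranscriptModel
#'
#' @param gene_id,transcript_id identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column matrix (or data.frame) of 0-based half-open exon
#'   intervals; rows are sorted by start internally.
#' @param cds optional genomic CDS span `c(start, end)`, 0-based half-open.
#' @export
TranscriptModel <- function(gene_id, transcript_id, contig, strand, exons, cds = NULL) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  dimnames(exons) <- NULL
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  cds <- if (is.null(cds)) integer(0) else as.integer(cds)
  methods::new("TranscriptModel",
               gene_id = gene_id, transcript_id = transcript_id,
               contig = contig, strand = strand, exons = exons, cds = cds,
               segments = .deriveSegments(exons, cds, strand))
}

#' @describeIn TranscriptModel exon interval matrix.
#' @param x a `TranscriptModel`.
#' @export
exonIntervals <- function(x) x@exons

#' @describeIn TranscriptModel CDS genomic span (length-2 integer) or NULL.
#' @export
cdsSpan <- function(x) if (length(x@cds)) x@cds else NULL

#' @describeIn TranscriptModel derived segment list
#'   (`five_prime_utr`, `cds`, `three_prime_utr`, `intron`).
#' @export
featureSegments <- function(x) x@segments

#' @describeIn TranscriptModel total exonic length (bp).
#' @export
exonicLength <- function(x) sum(x@exons[, 2L] - x@exons[, 1L])

#' @describeIn TranscriptModel genomic span `c(start, end)` of the transcript.
#' @export
transcriptSpan <- function(x) c(x@exons[1L, 1L], x@exons[nrow(x@exons), 2L])

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (%s) %s:%d-%d(%s) %d exon(s)%s\n",
              object@transcript_id, object@gene_id, object@contig,
              transcriptSpan(object)[1L], transcriptSpan(object)[2L],
              object@strand, nrow(object@exons),
              if (length(object@cds)) " +CDS" else ""))
})

#' Read gene models from GTF
#'
#' Parses exon and CDS features (via [rtracklayer::import]), groups them by
#' `transcript_id`, converts GTF's 1-based closed coordinates to the
#' package-internal 0-based half-open convention and derives UTR/CDS/intron
#' segments. Transcripts without exon features are rejected.
#'
#' @param path GTF file.
#' @param genome optional `GenomeRef`; when given, exon coordinates are
#'   validated against contig lengths.
#' @return list of [TranscriptModel] objects, named by transcript_id.
#' @export
readGTF <- function(path, genome = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ", conditionMessage(e)))
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,       # -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id, transcript_id = gr$transcript_id,
    stringsAsFactors = FALSE
  )
  if (anyNA(df$transcript_id) || anyNA(df$gene_id))
    stop("GTF features missing gene_id/transcript_id attributes")
  out <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, ]
    ex <- sub[sub$type == "exon", ]
    if (nrow(ex) == 0L) next   # transcripts with no exons rejected
    cds <- sub[sub$type == "CDS", ]
    cdsSp <- if (nrow(cds)) c(min(cds$start), max(cds$end)) else NULL
    tm <- TranscriptModel(ex$gene_id[1L], tid, ex$contig[1L], ex$strand[1L],
                          cbind(ex$start, ex$end), cdsSp)
    if (!is.null(genome)) {
      len <- contigLengths(genome)[[tm@contig]]
      if (is.null(len) || any(tm@exons < 0L) || any(tm@exons > len))
        stop("exon outside contig bounds for transcript ", tid)
    }
    out[[tid]] <- tm
  }
  if (length(out) == 0L) stop("no transcript with exons in ", path)
  out
}

#' Write gene models to GTF (1-based closed coordinates)
#'
#' @param models list of [TranscriptModel].
#' @param path output file.
#' @export
writeGTF <- function(models, path) {
  lines <- character(0)
  for (tm in models) {
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s";', tm@gene_id, tm@transcript_id)
    ex <- tm@exons
    lines <- c(lines, sprintf("%s\tcimscall\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tm@contig, ex[, 1L] + 1L, ex[, 2L], tm@strand, attr0))
    seg <- tm@segments$cds
    if (nrow(seg)) lines <- c(lines, sprintf("%s\tcimscall\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                             tm@contig, seg[, 1L] + 1L, seg[, 2L], tm@strand, attr0))
  }
  writeLines(lines, path)
  invisible(path)
}
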