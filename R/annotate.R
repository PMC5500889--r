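# Feature annotation, metagene profiling and intronic site counting.

.CATEGORY_ORDER <- c("cds", "five_prime_utr", "three_prime_utr", "exon",
                     "intron", "upstream", "downstream", "intergenic")

# per-base depth over [from, to) for tags on one contig+strand
.depthVector <- function(tags, contig, strand, from, to) {
  t <- tags[tags$contig == contig & tags$strand == strand, , drop = FALSE]
  depth <- integer(to - from)
  if (nrow(t) == 0L) return(depth)
  s <- pmax(t$start, from); e <- pmin(t$end, to)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0L) return(depth)
  dd <- tabulate(s - from + 1L, nbins = to - from + 1L) -
    tabulate(e - from + 1L, nbins = to - from + 1L)
  cumsum(dd)[seq_len(to - from)]
}

#' Annotate CIMS sites with genomic features
#'
#' Assigns each site (at its methylated-adenosine coordinate) a category
#' per isoform from the derived segments, then resolves disagreements by
#' the precedence cds > 5'UTR > 3'UTR > exon > intron > upstream >
#' downstream > intergenic (`exon` covers isoforms without an annotated
#' CDS). Flanking windows extend `upstream_window` bp 5' of the TSS and
#' `downstream_window` bp 3' of the transcript end, strand-aware; a site
#' is intergenic iff no isoform places it in any other category.
#'
#' @param sites a [CimsSites-class].
#' @param models list of [TranscriptModel].
#' @param upstream_window,downstream_window flank sizes in bp.
#' @param precedence category order, highest first (configurable since
#'   the convention is a tool choice, not a property of the data).
#' @return data.frame with one row per site: `site_index`, `category`,
#'   `gene_id` (gene providing the winning category; ties collapsed with
#'   commas), carrying the per-isoform calls as attribute
#'   `isoform_calls`.
#' @export
annotateSites <- function(sites, models, upstream_window = 5000L, downstream_window = 1000L,
                          precedence = .CATEGORY_ORDER) {
  s <- sitesTable(sites)
  iso <- list()
  for (tm in models) {
    i <- which(s$contig == tm@contig & s$strand == tm@strand)
    if (length(i) == 0L) next
    seg <- featureSegments(tm)
    span <- transcriptSpan(tm)
    cat <- rep(NA_character_, length(i))
    pos <- s$apos[i]
    hasCds <- length(tm@cds) == 2L
    inExon <- .inIntervals(pos, exonIntervals(tm))
    if (hasCds) {
      cat[.inIntervals(pos, seg$three_prime_utr)] <- "three_prime_utr"
      cat[.inIntervals(pos, seg$five_prime_utr)] <- "five_prime_utr"
      cat[.inIntervals(pos, seg$cds)] <- "cds"
    } else {
      cat[inExon] <- "exon"
    }
    cat[is.na(cat) & .inIntervals(pos, seg$intron)] <- "intron"
    upIv <- if (tm@strand == "+") c(span[1L] - upstream_window, span[1L]) else
      c(span[2L], span[2L] + upstream_window)
    dnIv <- if (tm@strand == "+") c(span[2L], span[2L] + downstream_window) else
      c(span[1L] - downstream_window, span[1L])
    cat[is.na(cat) & pos >= upIv[1L] & pos < upIv[2L]] <- "upstream"
    cat[is.na(cat) & pos >= dnIv[1L] & pos < dnIv[2L]] <- "downstream"
    got <- !is.na(cat)
    if (any(got)) {
      iso[[length(iso) + 1L]] <- data.frame(site_index = i[got], gene_id = tm@gene_id,
                                            transcript_id = tm@transcript_id,
                                            category = cat[got], stringsAsFactors = FALSE)
    }
  }
  isoDf <- if (length(iso)) do.call(rbind, iso) else
    data.frame(site_index = integer(0), gene_id = character(0),
               transcript_id = character(0), category = character(0),
               stringsAsFactors = FALSE)
  out <- data.frame(site_index = seq_len(nrow(s)), category = "intergenic",
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  if (nrow(isoDf)) {
    isoDf$rank <- match(isoDf$category, precedence)
    for (i in unique(isoDf$site_index)) {
      sub <- isoDf[isoDf$site_index == i, , drop = FALSE]
      best <- min(sub$rank)
      out$category[i] <- precedence[best]
      out$gene_id[i] <- paste(sort(unique(sub$gene_id[sub$rank == best])), collapse = ",")
    }
  }
  attr(out, "isoform_calls") <- isoDf[, c("site_index", "gene_id", "transcript_id", "category")]
  out
}

#' Rescaled metagene profile of miCLIP coverage
#'
#' Builds the canonical 5'UTR/CDS/3'UTR metagene: for each contributing
#' transcript the per-nucleotide tag depth over each feature's exonic
#' nucleotides (concatenated 5'->3' in transcript orientation) is
#' linearly rebinned onto fixed meta-lengths (defaults 200/1000/300,
#' summing to 1500 bins) with mass-conserving fractional weights, the
#' 1500-vector is normalised to total 1 so every transcript carries equal
#' weight, and the profile is the mean over transcripts. Intended input
#' is the gene set with at least one CIMS call.
#'
#' @param aln a [TagAlignments-class] supplying stranded tag depth.
#' @param models list of [TranscriptModel].
#' @param genes gene ids to include (default all genes in `models`).
#' @param meta_lengths bin counts for 5'UTR, CDS, 3'UTR.
#' @param isoform `"longest_cds"` (one isoform per gene, the one with the
#'   longest CDS) or `"all"` (every CDS-bearing isoform contributes).
#' @return list: `profile` (numeric, length `sum(meta_lengths)`),
#'   `n_transcripts`, `skipped_missing_feature`, `skipped_zero_coverage`.
#' @export
metageneProfile <- function(aln, models, genes = NULL, meta_lengths = c(200L, 1000L, 300L),
                            isoform = c("longest_cds", "all")) {
  isoform <- match.arg(isoform)
  tags <- tagsTable(aln)
  if (!is.null(genes)) models <- Filter(function(m) m@gene_id %in% genes, models)
  byGene <- split(models, vapply(models, function(m) m@gene_id, ""))
  chosen <- list()
  for (g in names(byGene)) {
    ms <- byGene[[g]]
    cdsLen <- vapply(ms, function(m) {
      seg <- featureSegments(m)$cds
      if (nrow(seg)) sum(seg[, 2L] - seg[, 1L]) else 0L
    }, numeric(1))
    ms <- ms[cdsLen > 0]
    if (length(ms) == 0L) next
    chosen <- c(chosen, if (isoform == "all") ms else
      ms[which.max(cdsLen[cdsLen > 0])])
  }
  total <- numeric(sum(meta_lengths))
  n_used <- 0L; n_missing <- 0L; n_zero <- 0L
  feats <- c("five_prime_utr", "cds", "three_prime_utr")
  for (tm in chosen) {
    seg <- featureSegments(tm)
    if (any(vapply(feats, function(f) nrow(seg[[f]]) == 0L, logical(1)))) {
      n_missing <- n_missing + 1L
      next
    }
    vec <- numeric(0)
    for (fi in seq_along(feats)) {
      ivs <- seg[[feats[fi]]]
      cov <- unlist(lapply(seq_len(nrow(ivs)), function(r)
        .depthVector(tags, tm@contig, tm@strand, ivs[r, 1L], ivs[r, 2L])))
      if (tm@strand == "-") cov <- rev(cov)
      vec <- c(vec, rebinConserve(cov, meta_lengths[fi]))
    }
    tot <- sum(vec)
    if (tot <= 0) { n_zero <- n_zero + 1L; next }
    total <- total + vec / tot
    n_used <- n_used + 1L
  }
  list(profile = if (n_used) total / n_used else total, n_transcripts = n_used,
       skipped_missing_feature = n_missing, skipped_zero_coverage = n_zero)
}

#' Per-gene intronic CIMS counts with max-over-isoform summarisation
#'
#' Any site lying in an exon of any isoform of any gene (strand-agnostic)
#' is first excluded; surviving sites are then summed per isoform over
#' that isoform's introns, and each gene reports the maximum over its
#' isoforms together with the supporting mutation-read count (`sum of m`)
#' at the counted sites.
#'
#' @param sites a [CimsSites-class].
#' @param models list of [TranscriptModel].
#' @return data.frame: `gene_id`, `reported` (max-over-isoform intronic
#'   site count), `reads` (supporting m at the reporting isoform's
#'   sites), sorted by gene_id; per-isoform sums in attribute
#'   `per_isoform`.
#' @export
countIntronic <- function(sites, models) {
  s <- sitesTable(sites)
  inAnyExon <- rep(FALSE, nrow(s))
  for (tm in models) {
    i <- which(s$contig == tm@contig)
    if (length(i)) inAnyExon[i] <- inAnyExon[i] | .inIntervals(s$apos[i], exonIntervals(tm))
  }
  surv <- s[!inAnyExon, , drop = FALSE]
  iso <- list()
  for (tm in models) {
    i <- which(surv$contig == tm@contig & surv$strand == tm@strand)
    hit <- if (length(i)) .inIntervals(surv$apos[i], featureSegments(tm)$intron) else logical(0)
    iso[[length(iso) + 1L]] <- data.frame(gene_id = tm@gene_id,
                                          transcript_id = tm@transcript_id,
                                          n_sites = sum(hit),
                                          reads = if (any(hit)) sum(surv$m[i[hit]]) else 0L,
                                          stringsAsFactors = FALSE)
  }
  isoDf <- do.call(rbind, iso)
  isoDf <- isoDf[order(isoDf$gene_id, isoDf$transcript_id), , drop = FALSE]
  rownames(isoDf) <- NULL
  out <- do.call(rbind, lapply(split(isoDf, isoDf$gene_id), function(g) {
    top <- which.max(g$n_sites)
    data.frame(gene_id = g$gene_id[1L], reported = g$n_sites[top],
               reads = g$reads[top], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_isoform") <- isoDf
  out
}

#' Rank genes by intronic CIMS burden
#'
#' Descending by reported site count, ties broken by supporting intronic
#' mutation reads (descending) then gene id; fully deterministic.
#'
#' @param counts data.frame from [countIntronic()].
#' @export
rankIntronicGenes <- function(counts) {
  out <- counts[order(-counts$reported, -counts$reads, counts$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
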