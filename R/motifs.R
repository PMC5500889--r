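#' Extract stranded sequence contexts around CIMS sites
#'
#' Returns the `2*flank + 1` nt stranded sequence centred on each site's
#' mutated C (reverse-complemented for minus-strand sites), so with the
#' default flank of 10 the C sits at string position 11 and the inferred
#' adenosine at position 10. Sites closer than `flank` to a contig edge
#' are dropped with a warning.
#'
#' @param sites a [CimsSites-class].
#' @param genome a [GenomeRef].
#' @param flank half-width in nt, default 10.
#' @return data.frame with `context` and `stratum` columns (a context
#'   set), plus a `site_index` column mapping back to rows of
#'   `sitesTable(sites)`.
#' @export
extractContexts <- function(sites, genome, flank = 10L) {
  s <- sitesTable(sites)
  if (nrow(s) == 0L) return(data.frame(context = character(0), stratum = character(0),
                                       site_index = integer(0), stringsAsFactors = FALSE))
  lens <- contigLengths(genome)[s$contig]
  ok <- s$cpos - flank >= 0L & s$cpos + flank + 1L <= lens
  if (any(!ok)) warning(sum(!ok), " site(s) within ", flank, " nt of a contig edge dropped")
  idx <- which(ok)
  ctx <- character(length(idx))
  for (ctg in unique(s$contig[idx])) {
    i <- idx[s$contig[idx] == ctg]
    ctx[match(i, idx)] <- strandedSeq(genome, ctg, s$cpos[i] - flank,
                                      s$cpos[i] + flank + 1L, s$strand[i])
  }
  data.frame(context = ctx, stratum = s$stratum[idx], site_index = idx,
             stringsAsFactors = FALSE)
}

#' @describeIn extractContexts fill the `context` column of a
#'   [CimsSites-class] in place (sites too close to an edge keep NA).
#' @export
fillContexts <- function(sites, genome, flank = 10L) {
  cs <- suppressWarnings(extractContexts(sites, genome, flank = flank))
  s <- sitesTable(sites)
  s$context[cs$site_index] <- cs$context
  CimsSites(s)
}

#' Sample background contexts from exonic space
#'
#' Draws random stranded C positions (by default preceded by A, the same
#' conditioning the site catalogue has passed) from the exons of the
#' supplied transcripts and returns their contexts. This is the
#' background against which motif enrichment is tested; it is matched to
#' the transcriptome space where C->T candidates could have arisen.
#'
#' @param genome a [GenomeRef].
#' @param models list of [TranscriptModel].
#' @param n number of background positions.
#' @param flank context half-width.
#' @param preceded_by_a require a stranded upstream A (default TRUE).
#' @param exclude optional data.frame with `contig`/`pos` columns of
#'   positions to avoid (e.g. planted site coordinates).
#' @return character vector of context sequences.
#' @export
sampleBackgroundContexts <- function(genome, models, n, flank = 10L,
                                     preceded_by_a = TRUE, exclude = NULL) {
  pool <- list()
  for (tm in models) {
    ex <- exonIntervals(tm)
    pos <- unlist(lapply(seq_len(nrow(ex)), function(i) seq.int(ex[i, 1L], ex[i, 2L] - 1L)))
    pool[[length(pool) + 1L]] <- data.frame(contig = tm@contig, pos = pos,
                                            strand = tm@strand, stringsAsFactors = FALSE)
  }
  pool <- unique(do.call(rbind, pool))
  lens <- contigLengths(genome)[pool$contig]
  pool <- pool[pool$pos - flank >= 0L & pool$pos + flank + 1L <= lens, , drop = FALSE]
  if (!is.null(exclude)) {
    pool <- pool[!paste0(pool$contig, ":", pool$pos) %in%
                   paste0(exclude$contig, ":", exclude$pos), , drop = FALSE]
  }
  keep <- logical(nrow(pool))
  for (ctg in unique(pool$contig)) {
    i <- which(pool$contig == ctg)
    b <- strandedBase(genome, ctg, pool$pos[i], pool$strand[i])
    ok <- b == "C"
    if (preceded_by_a) {
      up <- ifelse(pool$strand[i] == "+", pool$pos[i] - 1L, pool$pos[i] + 1L)
      ok <- ok & strandedBase(genome, ctg, up, pool$strand[i]) == "A"
    }
    keep[i] <- ok
  }
  pool <- pool[keep, , drop = FALSE]
  if (nrow(pool) == 0L) stop("no eligible background positions")
  sel <- pool[sample.int(nrow(pool), n, replace = nrow(pool) < n), , drop = FALSE]
  ctx <- character(nrow(sel))
  for (ctg in unique(sel$contig)) {
    i <- which(sel$contig == ctg)
    ctx[i] <- strandedSeq(genome, ctg, sel$pos[i] - flank, sel$pos[i] + flank + 1L,
                          sel$strand[i])
  }
  ctx
}

#' Position frequency matrix of a context set
#'
#' @param contexts character vector of equal-length DNA contexts (or the
#'   data.frame from [extractContexts()]).
#' @return 4 x width numeric matrix (rows A/C/G/T), columns summing to 1.
#'   Column names give the offset relative to the mutated C at 0.
#' @export
frequencyMatrix <- function(contexts) {
  if (is.data.frame(contexts)) contexts <- contexts$context
  contexts <- contexts[!is.na(contexts)]
  if (length(contexts) == 0L) stop("empty context set")
  w <- unique(nchar(contexts))
  if (length(w) != 1L) stop("contexts must share one length")
  m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(contexts), as.prob = TRUE)
  m <- m[.DNA, , drop = FALSE]
  flank <- (w - 1L) %/% 2L
  colnames(m) <- as.character(seq_len(w) - flank - 1L)
  m
}

#' Positional triplet frequency profile
#'
#' For each offset o (relative to the mutated C at 0) reports the fraction
#' of contexts whose 3-mer starting at o equals each query triplet; the
#' signature readout is, e.g., GGA enrichment in the three nucleotides
#' upstream of the transition.
#'
#' @param contexts character vector (or [extractContexts()] data.frame).
#' @param triplets character vector of 3-mers over A/C/G/T.
#' @param background optional second context set profiled identically and
#'   returned alongside.
#' @return data.frame: `triplet`, `offset`, `frequency` and, when a
#'   background is given, `background_frequency`.
#' @export
tripletPositionalProfile <- function(contexts, triplets, background = NULL) {
  if (is.data.frame(contexts)) contexts <- contexts$context
  contexts <- contexts[!is.na(contexts)]
  if (!all(grepl("^[ACGT]{3}$", triplets))) stop("triplets must be 3-mers over A/C/G/T")
  w <- unique(nchar(contexts))
  if (length(w) != 1L) stop("contexts must share one length")
  flank <- (w - 1L) %/% 2L
  offsets <- seq(-flank, flank - 2L)
  prof <- function(ctx) {
    sapply(triplets, function(tri) {
      vapply(offsets, function(o) {
        i <- o + flank + 1L
        mean(substr(ctx, i, i + 2L) == tri)
      }, numeric(1))
    })
  }
  p <- prof(contexts)
  out <- data.frame(triplet = rep(triplets, each = length(offsets)),
                    offset = rep(offsets, length(triplets)),
                    frequency = as.vector(p), stringsAsFactors = FALSE)
  if (!is.null(background)) {
    if (is.data.frame(background)) background <- background$context
    out$background_frequency <- as.vector(prof(background[!is.na(background)]))
  }
  out
}

#' Motif definitions anchored on the methylated adenosine
#'
#' Built-ins: `A_preceding` (`AC`, anchor 1), `RAC` (anchor 2), `DRACH`
#' (anchor 3); any other IUPAC string can be supplied with an explicit
#' anchor. The anchor is the 1-based offset of the methylated A within
#' the motif, used to align it onto a context (A at position `flank`,
#' C at `flank + 1`).
#'
#' @param name motif name; one of the built-ins or a free name.
#' @param iupac IUPAC string (required for non-built-ins).
#' @param anchor offset of the methylated A within the motif.
#' @export
motifDef <- function(name, iupac = NULL, anchor = NULL) {
  builtin <- list(A_preceding = list(iupac = "AC", anchor = 1L),
                  RAC = list(iupac = "RAC", anchor = 2L),
                  DRACH = list(iupac = "DRACH", anchor = 3L))
  if (name %in% names(builtin)) {
    b <- builtin[[name]]
    return(structure(list(name = name, iupac = b$iupac, anchor = b$anchor), class = "MotifDef"))
  }
  if (is.null(iupac) || is.null(anchor)) stop("custom motifs need iupac and anchor")
  structure(list(name = name, iupac = iupac, anchor = as.integer(anchor)), class = "MotifDef")
}

#' Does each context match a motif?
#'
#' @param contexts character vector of contexts (C at `flank + 1`).
#' @param motif a [motifDef()].
#' @param flank context half-width (default inferred from string length).
#' @return logical vector.
#' @export
matchesMotif <- function(contexts, motif, flank = NULL) {
  if (is.data.frame(contexts)) contexts <- contexts$context
  w <- unique(nchar(contexts))
  if (length(w) != 1L) stop("contexts must share one length")
  if (is.null(flank)) flank <- (w - 1L) %/% 2L
  start <- flank + 1L - motif$anchor   # A sits at position flank (1-based)
  if (start < 1L || start + nchar(motif$iupac) - 1L > w)
    stop("motif does not fit inside the context")
  .iupacMatch(substr(contexts, start, start + nchar(motif$iupac) - 1L), motif$iupac)
}

#' Motif enrichment test at CIMS sites
#'
#' Tests whether the fraction of site contexts matching a motif exceeds
#' the background fraction, either by a one-sided binomial test (default)
#' with the background match fraction as the null probability, or by a
#' permutation test drawing `B` resamples of `|sites|` contexts from the
#' background (p = (1 + #\{null >= observed\}) / (1 + B)).
#'
#' @param site_contexts,background_contexts character vectors (or
#'   [extractContexts()] data.frames); the background should be at least
#'   as large as the site set.
#' @param motif a [motifDef()].
#' @param method `"binomial"` or `"permutation"`.
#' @param B permutation resamples, default 10000.
#' @return one-row data.frame: `motif`, `observed_fraction`,
#'   `background_fraction`, `p_value`, `test`, `n_sites`, `n_background`.
#' @export
motifEnrichmentTest <- function(site_contexts, background_contexts, motif,
                                method = c("binomial", "permutation"), B = 10000L) {
  method <- match.arg(method)
  if (is.data.frame(site_contexts)) site_contexts <- site_contexts$context
  if (is.data.frame(background_contexts)) background_contexts <- background_contexts$context
  site_contexts <- site_contexts[!is.na(site_contexts)]
  background_contexts <- background_contexts[!is.na(background_contexts)]
  hit <- matchesMotif(site_contexts, motif)
  bg <- matchesMotif(background_contexts, motif)
  n <- length(hit); x <- sum(hit); p0 <- mean(bg)
  if (method == "binomial") {
    if (p0 == 0) stop("background fraction is 0; use method = 'permutation'")
    p <- stats::binom.test(x, n, p = p0, alternative = "greater")$p.value
  } else {
    null <- vapply(seq_len(B), function(b) sum(sample(bg, n, replace = TRUE)), integer(1))
    p <- (1 + sum(null >= x)) / (1 + B)
  }
  data.frame(motif = motif$name, observed_fraction = x / n, background_fraction = p0,
             p_value = p, test = method, n_sites = n, n_background = length(bg),
             stringsAsFactors = FALSE)
}

#' Fraction of A-preceded sites in an RAC context
#'
#' Among sites that already passed the upstream-A filter, the fraction
#' whose stranded base two nucleotides 5' of the C is A or G (the R of
#' RAC). The fly catalogue reports 62-68% across libraries.
#'
#' @param contexts character vector of contexts (or [extractContexts()]
#'   data.frame).
#' @export
racFraction <- function(contexts) {
  if (is.data.frame(contexts)) contexts <- contexts$context
  contexts <- contexts[!is.na(contexts)]
  if (length(contexts) == 0L) stop("empty context set")
  w <- nchar(contexts[1L]); flank <- (w - 1L) %/% 2L
  mean(substr(contexts, flank - 1L, flank - 1L) %in% c("A", "G"))
}
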