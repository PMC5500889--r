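#' Strand-aware mismatch pileup over unique tags
#'
#' For every stranded position covered by at least `min_k` unique tags
#' where at least one tag mismatches the reference, emits a tally of the
#' spanning-tag count `k` and per-base substitution support, expressed in
#' read-strand space: a minus-strand tag reading A over a plus-strand
#' reference G is recorded as a stranded C->T. `m` is the count for the
#' C->T class (zero for tallies whose stranded reference base is not C).
#'
#' @param aln a deduplicated [TagAlignments-class].
#' @param genome a [GenomeRef].
#' @param min_k minimum spanning unique-tag count for a tally to be
#'   emitted. No coverage floor is inherent to the method; the default of
#'   5 guards the m/k ratio against degeneracy at tiny k and changes site
#'   counts, so it is logged by [callCims()].
#' @return data.frame with columns `contig`, `pos` (0-based, the mutated
#'   base), `strand`, `ref` (stranded reference base), `k`, `nA`, `nC`,
#'   `nG`, `nT` (stranded read-base support), `m`.
#' @export
pileupMismatches <- function(aln, genome, min_k = 5L) {
  t <- tagsTable(aln)
  bad <- setdiff(unique(t$contig), contigNames(genome))
  if (length(bad)) stop("tag references unknown contig: ", bad[1L])
  mm <- mismatchTable(aln)
  if (nrow(mm) == 0L) return(.emptyTally())
  mm <- merge(mm, t[, c("read_id", "contig", "strand")], by = "read_id")
  out <- list()
  for (grp in split(seq_len(nrow(t)), paste(t$contig, t$strand))) {
    ctg <- t$contig[grp[1L]]; strand <- t$strand[grp[1L]]
    sub <- mm[mm$contig == ctg & mm$strand == strand, , drop = FALSE]
    if (nrow(sub) == 0L) next
    lo <- min(t$start[grp]); hi <- max(t$end[grp])
    depth <- integer(hi - lo + 1L)
    dd <- tabulate(t$start[grp] - lo + 1L, nbins = hi - lo + 1L) -
      tabulate(t$end[grp] - lo + 1L, nbins = hi - lo + 1L)
    depth <- cumsum(dd)
    pos <- sort(unique(sub$pos))
    k <- depth[pos - lo + 1L]
    keep <- k >= min_k
    pos <- pos[keep]; k <- k[keep]
    if (length(pos) == 0L) next
    counts <- matrix(0L, nrow = length(pos), ncol = 4L, dimnames = list(NULL, .DNA))
    tb <- table(factor(sub$pos, levels = pos), factor(sub$alt, levels = .DNA))
    counts[] <- as.integer(tb)
    ref <- getBase(genome, ctg, pos)
    if (strand == "-") {   # express in read-strand space
      ref <- complementBases(ref)
      counts <- counts[, c("T", "G", "C", "A"), drop = FALSE]
      colnames(counts) <- .DNA
    }
    out[[length(out) + 1L]] <- data.frame(
      contig = ctg, pos = pos, strand = strand, ref = ref, k = k,
      nA = counts[, "A"], nC = counts[, "C"], nG = counts[, "G"], nT = counts[, "T"],
      m = ifelse(ref == "C", counts[, "T"], 0L), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(.emptyTally())
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  stopifnot(all(res$m <= res$k), all(res$nA + res$nC + res$nG + res$nT <= res$k))
  res
}

.emptyTally <- function() data.frame(contig = character(0), pos = integer(0),
                                     strand = character(0), ref = character(0),
                                     k = integer(0), nA = integer(0), nC = integer(0),
                                     nG = integer(0), nT = integer(0), m = integer(0),
                                     stringsAsFactors = FALSE)

#' Restrict tallies to the C->T transition class
#'
#' Keeps tallies whose stranded reference base is C with read-base T
#' support (`m > 0`) as CIMS candidates. Every substitution class,
#' including the retained one, is also returned in a long-format
#' diagnostics table so the class composition can be inspected (the
#' comparison that singles out C->T as the crosslink signature).
#'
#' @param tallies data.frame from [pileupMismatches()].
#' @return list with `candidates` (tally rows, `m = nT`) and
#'   `diagnostics` (columns `contig`, `pos`, `strand`, `ref`, `alt`,
#'   `count`, `k`).
#' @export
filterTransitions <- function(tallies) {
  long <- list()
  for (b in .DNA) {
    cnt <- tallies[[paste0("n", b)]]
    sel <- which(cnt > 0L & tallies$ref != b)
    if (length(sel)) {
      long[[b]] <- data.frame(contig = tallies$contig[sel], pos = tallies$pos[sel],
                              strand = tallies$strand[sel], ref = tallies$ref[sel],
                              alt = b, count = cnt[sel], k = tallies$k[sel],
                              stringsAsFactors = FALSE)
    }
  }
  diagnostics <- if (length(long)) do.call(rbind, long) else
    data.frame(contig = character(0), pos = integer(0), strand = character(0),
               ref = character(0), alt = character(0), count = integer(0),
               k = integer(0), stringsAsFactors = FALSE)
  rownames(diagnostics) <- NULL
  candidates <- tallies[tallies$ref == "C" & tallies$nT > 0L, , drop = FALSE]
  candidates$m <- candidates$nT
  rownames(candidates) <- NULL
  list(candidates = candidates, diagnostics = diagnostics)
}

#' Keep candidates whose stranded upstream base is adenosine
#'
#' The methylated adenosine sits one stranded nucleotide 5' of the mutated
#' C; candidates without an upstream A are discarded, and the adenosine
#' coordinate `apos` is recorded for the survivors. Candidates at a contig
#' edge (no upstream base) are dropped with a warning.
#'
#' @param candidates tally rows from [filterTransitions()].
#' @param genome a [GenomeRef].
#' @export
filterPrecededByA <- function(candidates, genome) {
  if (nrow(candidates) == 0L) { candidates$apos <- integer(0); return(candidates) }
  up <- ifelse(candidates$strand == "+", candidates$pos - 1L, candidates$pos + 1L)
  lens <- contigLengths(genome)[candidates$contig]
  inb <- up >= 0L & up < lens
  if (any(!inb)) warning(sum(!inb), " candidate(s) at contig edge dropped (no upstream base)")
  candidates <- candidates[inb, , drop = FALSE]; up <- up[inb]
  keep <- logical(nrow(candidates))
  for (ctg in unique(candidates$contig)) {
    i <- candidates$contig == ctg
    keep[i] <- strandedBase(genome, ctg, up[i], candidates$strand[i]) == "A"
  }
  candidates <- candidates[keep, , drop = FALSE]
  candidates$apos <- up[keep]
  rownames(candidates) <- NULL
  candidates
}

#' Remove candidates at known SNP positions
#'
#' Drops, strand-agnostically, any candidate whose mutated-C or inferred
#' adenosine coordinate is a known SNP position.
#'
#' @param candidates data.frame with `contig`, `pos` and (optionally)
#'   `apos` columns.
#' @param snps a [SnpCatalog].
#' @export
filterSnps <- function(candidates, snps) {
  if (nrow(candidates) == 0L || length(snps) == 0L) return(candidates)
  hit <- snpContains(snps, candidates$contig, candidates$pos)
  if (!is.null(candidates$apos)) hit <- hit | snpContains(snps, candidates$contig, candidates$apos)
  out <- candidates[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the m/k mutation-ratio window and stratify
#'
#' Retains candidates with `lo <= m/k <= hi` (both boundaries inclusive;
#' compared in rational form so exact boundary cases are kept) and assigns
#' the m-based stratum: `high` for m > 10, `medium` for 5 <= m <= 10,
#' `low` for m < 5.
#'
#' @param candidates data.frame with `m`, `k` and `apos` populated.
#' @param lo,hi ratio window, defaults 0.01 and 0.50.
#' @return a [CimsSites-class] (contexts unfilled; see [extractContexts()]).
#' @export
filterRatio <- function(candidates, lo = 0.01, hi = 0.50) {
  if (nrow(candidates) && any(candidates$k == 0L)) stop("tally with k = 0 violates the pileup invariant")
  eps <- 1e-9
  keep <- candidates$m >= lo * candidates$k - eps & candidates$m <= hi * candidates$k + eps
  s <- candidates[keep, , drop = FALSE]
  if (nrow(s) == 0L) return(CimsSites())
  stratum <- ifelse(s$m > 10L, "high", ifelse(s$m >= 5L, "medium", "low"))
  CimsSites(data.frame(contig = s$contig, cpos = s$pos, apos = s$apos, strand = s$strand,
                       m = s$m, k = s$k, ratio = s$m / s$k, stratum = stratum,
                       stringsAsFactors = FALSE))
}

#' Cluster unique tags into peaks
#'
#' Same-strand tags connected transitively by overlap form one cluster;
#' a cluster's height is its maximum per-base unique-tag depth, and only
#' clusters reaching `min_height` stacked tags are retained.
#'
#' @param aln a deduplicated [TagAlignments-class] (or its tag data.frame).
#' @param min_height minimum peak height, default 4.
#' @return data.frame: `contig`, `strand`, `start`, `end`, `n_tags`,
#'   `height`, sorted by position.
#' @export
clusterPeaks <- function(aln, min_height = 4L) {
  t <- if (methods::is(aln, "TagAlignments")) tagsTable(aln) else aln
  out <- list()
  for (grp in split(seq_len(nrow(t)), paste(t$contig, t$strand))) {
    g <- t[grp, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    cl_start <- g$start[1L]; cl_end <- g$end[1L]; members <- 1L
    flush <- function(s, e, idx) {
      lo <- s; depth <- integer(e - s)
      for (i in idx) depth[(g$start[i] - lo + 1L):(g$end[i] - lo)] <-
          depth[(g$start[i] - lo + 1L):(g$end[i] - lo)] + 1L
      data.frame(contig = g$contig[1L], strand = g$strand[1L], start = s, end = e,
                 n_tags = length(idx), height = max(depth), stringsAsFactors = FALSE)
    }
    if (nrow(g) > 1L) {
      for (i in 2:nrow(g)) {
        if (g$start[i] < cl_end) {   # overlap on half-open intervals
          cl_end <- max(cl_end, g$end[i]); members <- c(members, i)
        } else {
          out[[length(out) + 1L]] <- flush(cl_start, cl_end, members)
          cl_start <- g$start[i]; cl_end <- g$end[i]; members <- i
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cl_start, cl_end, members)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), strand = character(0), start = integer(0),
               end = integer(0), n_tags = integer(0), height = integer(0),
               stringsAsFactors = FALSE)
  res <- res[res$height >= min_height, , drop = FALSE]
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Restrict sites to those inside retained peak clusters
#'
#' Optional post-filter keeping only sites whose mutated C lies within a
#' retained peak on the same strand; by default the site catalogue and
#' the peak set are parallel outputs.
#'
#' @param sites a [CimsSites-class].
#' @param peaks data.frame from [clusterPeaks()].
#' @export
intersectSitesWithPeaks <- function(sites, peaks) {
  s <- sitesTable(sites)
  if (nrow(s) == 0L || nrow(peaks) == 0L) return(CimsSites(s[integer(0), , drop = FALSE]))
  keep <- vapply(seq_len(nrow(s)), function(i) {
    any(peaks$contig == s$contig[i] & peaks$strand == s$strand[i] &
          peaks$start <= s$cpos[i] & peaks$end > s$cpos[i])
  }, logical(1))
  CimsSites(s[keep, , drop = FALSE])
}

#' Full CIMS calling chain with per-filter attrition
#'
#' Runs pileup, the C->T transition restriction, the upstream-adenosine
#' filter, the SNP exclusion and the m/k ratio window, fills sequence
#' contexts, and reports how many candidates each filter removed.
#'
#' @inheritParams pileupMismatches
#' @param snps a [SnpCatalog] (possibly empty).
#' @param lo,hi m/k ratio window.
#' @param flank context half-width (nt) around the mutated C.
#' @return list: `sites` ([CimsSites-class]), `tallies`, `diagnostics`,
#'   `attrition` (data.frame of stage counts).
#' @export
callCims <- function(aln, genome, snps = SnpCatalog(), min_k = 5L, lo = 0.01, hi = 0.50,
                     flank = 10L) {
  message("pileup with min_k = ", min_k, " (coverage floor; changes site counts)")
  tallies <- pileupMismatches(aln, genome, min_k = min_k)
  tr <- filterTransitions(tallies)
  cand <- tr$candidates
  n0 <- nrow(cand)
  candA <- filterPrecededByA(cand, genome)
  n1 <- nrow(candA)
  candS <- filterSnps(candA, snps)
  n2 <- nrow(candS)
  sites <- filterRatio(candS, lo = lo, hi = hi)
  n3 <- length(sites)
  sites <- fillContexts(sites, genome, flank = flank)
  attrition <- data.frame(
    stage = c("candidates_in", "removed_no_upstream_A", "removed_snp", "removed_ratio", "sites_out"),
    count = c(n0, n0 - n1, n1 - n2, n2 - n3, n3), stringsAsFactors = FALSE)
  list(sites = sites, tallies = tallies, diagnostics = tr$diagnostics, attrition = attrition)
}
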