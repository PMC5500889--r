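#' Planted ground truth for a simulated miCLIP experiment
#'
#' Records everything the generator planted so the pipeline's recovery can
#' be scored exactly: methylated adenosines with their DRACH contexts,
#' SNPs with their allele-ratio class, every unique tag's true origin, and
#' every simulated mismatch labelled as crosslink-induced, SNP or
#' sequencing error. All coordinates 0-based, plus-strand space.
#'
#' @slot m6a data.frame: `contig`, `apos` (methylated A), `cpos` (mutated
#'   C), `strand`, `context5` (stranded DRACH 5-mer), `feature`
#'   (`exonic`/`intronic`).
#' @slot snps data.frame: `contig`, `pos`, `strand`, `class`
#'   (`het`/`hom`), `ref`, `alt` (plus-strand bases).
#' @slot reads data.frame: `read_id`, `contig`, `start`, `end`, `strand`,
#'   `barcode`, `n_copies`, `origin` (`site`/`background`).
#' @slot mismatches data.frame: `read_id`, `pos`, `ref`, `alt`, `origin`
#'   (`crosslink`/`snp`/`error`).
#' @export
setClass("TruthTable", representation(m6a = "data.frame", snps = "data.frame",
                                      reads = "data.frame", mismatches = "data.frame"))

#' @describeIn TruthTable-class planted m6A site table.
#' @param x a `TruthTable`.
#' @export
truthM6a <- function(x) x@m6a

#' @describeIn TruthTable-class planted SNP table.
#' @export
truthSnps <- function(x) x@snps

#' @describeIn TruthTable-class unique-tag provenance table.
#' @export
truthReads <- function(x) x@reads

#' @describeIn TruthTable-class per-mismatch provenance table.
#' @export
truthMismatches <- function(x) x@mismatches

setMethod("show", "TruthTable", function(object) {
  cat(sprintf("TruthTable: %d m6A site(s), %d SNP(s), %d unique tag(s), %d mismatch record(s)\n",
              nrow(object@m6a), nrow(object@snps), nrow(object@reads), nrow(object@mismatches)))
})

#' Write / read a TruthTable as a directory of TSVs
#'
#' @param truth a [TruthTable-class].
#' @param dir directory (created if missing).
#' @export
writeTruthTable <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("m6a", "snps", "reads", "mismatches")) {
    utils::write.table(methods::slot(truth, nm), file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(dir) {
  rd <- function(nm) utils::read.delim(file.path(dir, paste0("truth_", nm, ".tsv")),
                                       stringsAsFactors = FALSE,
                                       colClasses = NULL)
  methods::new("TruthTable", m6a = rd("m6a"), snps = rd("snps"),
               reads = rd("reads"), mismatches = rd("mismatches"))
}

#' Simulation parameters
#'
#' Defaults describe the package's standard demonstration experiment: a
#' 100 kb single-contig genome carrying 20 genes, 50 planted m6A sites in
#' DRACH contexts, a 20% per-tag crosslink-mutation rate, mean 50 unique
#' tags over each site, a 0.1% uniform substitution error rate, 30 SNPs
#' (half heterozygous), one extra PCR copy per unique tag on average, and
#' the 9-nt iCLIP barcode layout `NNNXXXXNN` (N = random/UMI base, X =
#' sample index base).
#'
#' @param n_genes number of genes.
#' @param genome_size total genome length (bp); must be >= 500 * n_genes.
#' @param n_m6a_sites number of planted methylated adenosines.
#' @param cims_rate probability a spanning unique tag acquires the C->T
#'   transition at a planted site's C.
#' @param base_error_rate per-base uniform substitution error probability.
#' @param coverage mean unique tags spanning each planted site.
#' @param n_snps number of planted SNPs.
#' @param het_fraction fraction of SNPs simulated at ~50% allele ratio
#'   (the rest homozygous-alternate).
#' @param pcr_duplication_mean mean extra PCR copies per unique tag.
#' @param read_length sequenced insert length (nt), excluding barcode.
#' @param barcode_layout mask over `{N, X}`.
#' @param sample_codes named character vector of sample index sequences
#'   (names are sample names); lengths must equal the number of X in the
#'   layout.
#' @param exon_fraction fraction of planted sites placed in exons (the
#'   rest in introns).
#' @param background_coverage mean per-transcript background tag depth.
#' @param n_mrna_reads number of simulated mRNA-seq reads.
#' @param mrna_abundance_sdlog log-normal sdlog of per-gene mRNA abundance.
#' @param seed master RNG seed; every generator stage derives its own
#'   sub-seed from it, so a fixed seed gives byte-identical outputs.
#' @return a validated `SimulationParams` list.
#' @export
simParams <- function(n_genes = 20L, genome_size = 100000L, n_m6a_sites = 50L,
                      cims_rate = 0.2, base_error_rate = 0.001, coverage = 50,
                      n_snps = 30L, het_fraction = 0.5, pcr_duplication_mean = 1,
                      read_length = 36L, barcode_layout = "NNNXXXXNN",
                      sample_codes = c(s1 = "TTTT"), exon_fraction = 0.9,
                      background_coverage = 2, n_mrna_reads = 20000L,
                      mrna_abundance_sdlog = 1, seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), genome_size = as.integer(genome_size),
            n_m6a_sites = as.integer(n_m6a_sites), cims_rate = cims_rate,
            base_error_rate = base_error_rate, coverage = coverage,
            n_snps = as.integer(n_snps), het_fraction = het_fraction,
            pcr_duplication_mean = pcr_duplication_mean,
            read_length = as.integer(read_length), barcode_layout = barcode_layout,
            sample_codes = sample_codes, exon_fraction = exon_fraction,
            background_coverage = background_coverage,
            n_mrna_reads = as.integer(n_mrna_reads),
            mrna_abundance_sdlog = mrna_abundance_sdlog, seed = as.integer(seed))
  probs <- c(p$cims_rate, p$base_error_rate, p$het_fraction, p$exon_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!grepl("^[NX]+$", p$barcode_layout)) stop("barcode_layout must be a mask over {N, X}")
  if (p$read_length <= nchar(p$barcode_layout)) stop("read_length must exceed barcode length")
  nx <- sum(strsplit(p$barcode_layout, "")[[1]] == "X")
  if (any(nchar(p$sample_codes) != nx)) stop("sample codes must match the X count of the layout")
  if (p$coverage < 0 || p$background_coverage < 0 || p$pcr_duplication_mean < 0)
    stop("rates must be non-negative")
  class(p) <- "SimulationParams"
  p
}

# random split of `total` into `n` parts, each >= minlen
.randomSplit <- function(total, n, minlen) {
  if (total < n * minlen) stop("sizing error: cannot split ", total, " into ", n, " parts of >= ", minlen)
  u <- stats::runif(n)
  extra <- total - n * minlen
  lens <- minlen + floor(extra * u / sum(u))
  lens[1L] <- lens[1L] + (total - sum(lens))
  lens
}

#' Generate a random genome with layered gene models
#'
#' Lays out `n_genes` non-overlapping genes on one random-sequence contig,
#' alternating strands. Each gene gets a master isoform of 1-4 exons with
#' explicit 5'UTR/CDS/3'UTR whose exonic lengths follow roughly the
#' 200:1000:300 ratio of typical fly transcripts (scaled down when the
#' per-gene space is tight), plus 0-2 additional isoforms formed by
#' retaining individual introns (intron retention keeps the CDS span and
#' all segment invariants intact while diversifying exon/intron structure).
#'
#' @param params a [simParams()] list.
#' @return list with elements `genome` ([GenomeRef]) and `models`
#'   (named list of [TranscriptModel], grouped by gene).
#' @export
generateGenomeAndModels <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (params$n_genes > 0L && params$genome_size < params$n_genes * 500L)
    stop("sizing error: genome_size must be >= 500 bp per gene")
  set.seed(.subSeed(params$seed, "genome"))
  contig <- "chrS1"
  seq <- paste(sample(.DNA, params$genome_size, replace = TRUE), collapse = "")
  genome <- GenomeRef(stats::setNames(seq, contig))
  models <- list()
  if (params$n_genes > 0L) {
    allot <- params$genome_size %/% params$n_genes
    for (g in seq_len(params$n_genes)) {
      slot0 <- (g - 1L) * allot
      avail <- allot - 100L                       # 50 bp margin each side
      E <- min(1500L, as.integer(floor(avail * 0.55)))
      u5 <- max(30L, as.integer(round(E * 200 / 1500)))
      u3 <- max(40L, as.integer(round(E * 300 / 1500)))
      cdslen <- E - u5 - u3
      n_ex <- sample(1:4, 1L)
      ibudget <- avail - E
      while (n_ex > 1L && ibudget < 30L * (n_ex - 1L)) n_ex <- n_ex - 1L
      exlens <- .randomSplit(E, n_ex, 20L)
      inlens <- if (n_ex > 1L) .randomSplit(as.integer(min(ibudget, 60L * (n_ex - 1L))),
                                            n_ex - 1L, 30L) else integer(0)
      footprint <- E + sum(inlens)
      gstart <- slot0 + 50L + sample.int(max(avail - footprint, 1L), 1L) - 1L
      pos <- gstart
      exons <- matrix(integer(0), ncol = 2L)
      for (i in seq_len(n_ex)) {
        exons <- rbind(exons, c(pos, pos + exlens[i]))
        pos <- pos + exlens[i] + if (i < n_ex) inlens[i] else 0L
      }
      strand <- if (g %% 2L == 1L) "+" else "-"
      # CDS genomic span from exonic index range [left_len, E - right_len)
      left_len <- if (strand == "+") u5 else u3
      right_len <- if (strand == "+") u3 else u5
      exonic_pos <- unlist(lapply(seq_len(n_ex), function(i) seq.int(exons[i, 1L], exons[i, 2L] - 1L)))
      cds_span <- c(exonic_pos[left_len + 1L], exonic_pos[E - right_len] + 1L)
      gid <- sprintf("g%03d", g)
      n_iso <- sample(1:3, 1L)
      iso_exons <- list(exons)
      if (n_iso > 1L && n_ex > 1L) {
        for (v in 2:n_iso) {
          keep <- stats::runif(n_ex - 1L) < 0.7    # retained introns
          ex2 <- exons[1L, , drop = FALSE]
          for (i in 2:n_ex) {
            if (keep[i - 1L]) ex2 <- rbind(ex2, exons[i, ]) else ex2[nrow(ex2), 2L] <- exons[i, 2L]
          }
          iso_exons[[v]] <- ex2
        }
      }
      for (v in seq_along(iso_exons)) {
        tid <- sprintf("%s.t%d", gid, v)
        models[[tid]] <- TranscriptModel(gid, tid, contig, strand, iso_exons[[v]], cds_span)
      }
    }
  }
  list(genome = genome, models = models)
}

# stranded DRACH 5-mer centred on the A (positions A-2..A+2), written into
# the plus strand of the genome at [apos-2, apos+3)
.plantContext <- function() {
  paste0(sample(c("A", "G", "T"), 1L), sample(c("A", "G"), 1L), "A", "C",
         sample(c("A", "C", "T"), 1L))
}

#' Plant m6A sites and SNPs into a simulated genome
#'
#' Selects `n_m6a_sites` adenosine positions inside exons and introns
#' (exon share `exon_fraction`, intronic count drawn binomially) and edits
#' the genome so every planted site sits in a stranded DRACH 5-mer with
#' the methylated A at position 3 and the mutation-prone C at position 4.
#' SNPs are placed at stranded A-preceded C positions within read range of
#' planted sites (alternate allele T), so that heterozygous SNPs generate
#' exactly the A-preceded ~50% C->T candidates that only the SNP filter
#' can remove, while homozygous ones additionally exceed the m/k ceiling.
#'
#' @param genome a [GenomeRef] from [generateGenomeAndModels()].
#' @param models transcript models from the same call.
#' @param params a [simParams()] list.
#' @return list with the edited `genome` and a `truth` [TruthTable-class].
#' @export
plantM6aSites <- function(genome, models, params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (length(models) == 0L) stop("models must be non-empty to plant sites")
  set.seed(.subSeed(params$seed, "plant"))
  n <- params$n_m6a_sites
  n_intronic <- stats::rbinom(1L, n, 1 - params$exon_fraction)
  want <- c(rep("exonic", n - n_intronic), rep("intronic", n_intronic))
  clen <- contigLengths(genome)
  taken <- data.frame(contig = character(0), pos = integer(0))
  tooClose <- function(ctg, p, mindist) {
    any(taken$contig == ctg & abs(taken$pos - p) < mindist)
  }
  m6a <- data.frame()
  for (feat in want) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      tm <- models[[sample.int(length(models), 1L)]]
      segs <- if (feat == "exonic") exonIntervals(tm) else featureSegments(tm)$intron
      if (nrow(segs) == 0L) next
      iv <- segs[sample.int(nrow(segs), 1L), ]
      if (iv[2L] - iv[1L] < 9L) next
      apos <- iv[1L] + sample.int(iv[2L] - iv[1L] - 8L, 1L) + 3L  # 5-mer inside interval
      if (apos - 2L < 0L || apos + 3L > clen[[tm@contig]]) next
      if (tooClose(tm@contig, apos, 10L)) next
      strand <- tm@strand
      ctx <- .plantContext()
      plus5 <- if (strand == "+") ctx else revComp(ctx)
      genome <- .replaceSeq(genome, tm@contig, apos - 2L, plus5)
      cpos <- if (strand == "+") apos + 1L else apos - 1L
      m6a <- rbind(m6a, data.frame(contig = tm@contig, apos = apos, cpos = cpos,
                                   strand = strand, context5 = ctx, feature = feat,
                                   stringsAsFactors = FALSE))
      taken <- rbind(taken, data.frame(contig = tm@contig, pos = apos))
      placed <- TRUE
      break
    }
    if (!placed) stop("sizing error: could not place all m6A sites; enlarge the genome")
  }
  # -- SNPs at stranded A-preceded C positions near planted sites --------
  L <- params$read_length
  snps <- data.frame()
  snpTaken <- taken
  for (i in seq_len(params$n_snps)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      site <- m6a[sample.int(nrow(m6a), 1L), ]
      w0 <- max(site$cpos - (L - 6L), 1L)
      w1 <- min(site$cpos + (L - 6L), clen[[site$contig]] - 2L)
      cand <- w0:w1
      sb <- strandedBase(genome, site$contig, cand, site$strand)
      up <- if (site$strand == "+") cand - 1L else cand + 1L
      ub <- strandedBase(genome, site$contig, up, site$strand)
      ok <- sb == "C" & ub == "A"
      cand <- cand[ok]
      cand <- cand[!vapply(cand, function(p)
        any(snpTaken$contig == site$contig & abs(snpTaken$pos - p) < 4L), logical(1))]
      if (length(cand) == 0L) next
      p <- cand[sample.int(length(cand), 1L)]
      ref <- getBase(genome, site$contig, p)
      alt <- if (site$strand == "+") "T" else "A"   # stranded T
      cls <- if (stats::runif(1L) < params$het_fraction) "het" else "hom"
      snps <- rbind(snps, data.frame(contig = site$contig, pos = p, strand = site$strand,
                                     class = cls, ref = ref, alt = alt,
                                     stringsAsFactors = FALSE))
      snpTaken <- rbind(snpTaken, data.frame(contig = site$contig, pos = p))
      placed <- TRUE
      break
    }
    if (!placed) stop("sizing error: could not place all SNPs")
  }
  truth <- methods::new("TruthTable", m6a = m6a, snps = snps,
                        reads = .emptyTruthReads(), mismatches = .emptyTruthMismatches())
  list(genome = genome, truth = truth)
}

.emptyTruthReads <- function() data.frame(read_id = character(0), contig = character(0),
                                          start = integer(0), end = integer(0),
                                          strand = character(0), barcode = character(0),
                                          n_copies = integer(0), origin = character(0),
                                          stringsAsFactors = FALSE)

.emptyTruthMismatches <- function() data.frame(read_id = character(0), pos = integer(0),
                                               ref = character(0), alt = character(0),
                                               origin = character(0), stringsAsFactors = FALSE)

# build the barcode prefix from a layout mask, UMI bases and a sample code
.barcodePrefix <- function(layout, umi, code) {
  mask <- strsplit(layout, "")[[1]]
  out <- character(length(mask))
  out[mask == "N"] <- strsplit(umi, "")[[1]]
  out[mask == "X"] <- strsplit(code, "")[[1]]
  paste(out, collapse = "")
}

#' Simulate miCLIP reads over planted sites
#'
#' Draws `Poisson(coverage)` unique tags spanning each planted site plus
#' background tags along every transcript; any tag spanning a planted C
#' on the matching strand acquires the C->T transition independently with
#' probability `cims_rate`. SNP alleles (het ~50%, hom 100%) and uniform
#' sequencing errors are layered on top, and every resulting mismatch is
#' recorded with its provenance. Each unique tag is written
#' `1 + Poisson(pcr_duplication_mean)` times to FASTQ, all copies sharing
#' one random-barcode realisation; UMIs are guaranteed distinct among
#' tags sharing an alignment start, so duplicate collapsing is exactly
#' invertible against the truth. A truth SAM records the intended
#' alignment of every unique tag.
#'
#' @param genome edited [GenomeRef] from [plantM6aSites()].
#' @param models transcript models.
#' @param truth the [TruthTable-class] from [plantM6aSites()].
#' @param params a [simParams()] list.
#' @param fastq_path,sam_path output files.
#' @return the `truth` object with `reads` and `mismatches` populated.
#' @export
simulateMiclipReads <- function(genome, models, truth, params, fastq_path, sam_path) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(.subSeed(params$seed, "miclip"))
  L <- params$read_length
  clen <- contigLengths(genome)
  m6a <- truthM6a(truth); snps <- truthSnps(truth)
  n_umi <- sum(strsplit(params$barcode_layout, "")[[1]] == "N")

  draws <- list()   # per unique tag: contig,start,strand,origin
  for (i in seq_len(nrow(m6a))) {
    n_i <- stats::rpois(1L, params$coverage)
    if (n_i == 0L) next
    cp <- m6a$cpos[i]; ctg <- m6a$contig[i]
    st <- cp - sample.int(L, n_i, replace = TRUE) + 1L
    st <- pmin(pmax(st, 0L), clen[[ctg]] - L)
    draws[[length(draws) + 1L]] <- data.frame(contig = ctg, start = st,
                                              strand = m6a$strand[i], origin = "site",
                                              stringsAsFactors = FALSE)
  }
  for (tm in models) {
    span <- transcriptSpan(tm)
    if (span[2L] - span[1L] <= L) next
    n_bg <- stats::rpois(1L, exonicLength(tm) * params$background_coverage / L)
    if (n_bg == 0L) next
    st <- span[1L] + sample.int(span[2L] - span[1L] - L, n_bg, replace = TRUE) - 1L
    draws[[length(draws) + 1L]] <- data.frame(contig = tm@contig, start = st,
                                              strand = tm@strand, origin = "background",
                                              stringsAsFactors = FALSE)
  }
  tags <- if (length(draws)) do.call(rbind, draws) else
    data.frame(contig = character(0), start = integer(0), strand = character(0),
               origin = character(0), stringsAsFactors = FALSE)
  ntag <- nrow(tags)
  ids <- sprintf("t%06d", seq_len(ntag))

  usedBarcodes <- new.env(parent = emptyenv())  # key contig:strand:start -> umis
  reads <- vector("list", ntag); mms <- vector("list", ntag)
  fq <- vector("list", ntag); plus_seqs <- character(ntag)
  for (i in seq_len(ntag)) {
    ctg <- tags$contig[i]; st <- tags$start[i]; en <- st + L; strand <- tags$strand[i]
    refseq <- strsplit(strandedSeq(genome, ctg, st, en, "+"), "")[[1L]]
    cur <- refseq
    origin <- character(L)
    # crosslink-induced C->T at any planted C this tag spans (stranded)
    hits <- which(m6a$contig == ctg & m6a$strand == strand & m6a$cpos >= st & m6a$cpos < en)
    for (h in hits) {
      if (stats::runif(1L) < params$cims_rate) {
        off <- m6a$cpos[h] - st + 1L
        cur[off] <- if (strand == "+") "T" else "A"
        origin[off] <- "crosslink"
      }
    }
    # SNP alleles
    sh <- which(snps$contig == ctg & snps$pos >= st & snps$pos < en)
    for (h in sh) {
      take <- if (snps$class[h] == "hom") TRUE else stats::runif(1L) < 0.5
      if (take) {
        off <- snps$pos[h] - st + 1L
        cur[off] <- snps$alt[h]
        origin[off] <- "snp"
      }
    }
    # uniform errors (substitute away from the current base)
    nerr <- stats::rbinom(1L, L, params$base_error_rate)
    if (nerr > 0L) {
      at <- sample.int(L, nerr)
      for (off in at) {
        cur[off] <- sample(setdiff(.DNA, cur[off]), 1L)
        origin[off] <- "error"
      }
    }
    diffs <- which(cur != refseq)
    if (length(diffs)) {
      mms[[i]] <- data.frame(read_id = ids[i], pos = st + diffs - 1L,
                             ref = refseq[diffs], alt = cur[diffs],
                             origin = origin[diffs], stringsAsFactors = FALSE)
    }
    plus_seq <- paste(cur, collapse = "")
    plus_seqs[i] <- plus_seq
    # UMI, unique within this (contig, strand, start) group
    key <- paste(ctg, strand, st, sep = ":")
    used <- if (is.null(usedBarcodes[[key]])) character(0) else usedBarcodes[[key]]
    umi <- paste(sample(.DNA, n_umi, replace = TRUE), collapse = "")
    tries <- 0L
    while (umi %in% used && tries < 200L) {
      umi <- paste(sample(.DNA, n_umi, replace = TRUE), collapse = "")
      tries <- tries + 1L
    }
    usedBarcodes[[key]] <- c(used, umi)
    code <- params$sample_codes[[sample.int(length(params$sample_codes), 1L)]]
    prefix <- .barcodePrefix(params$barcode_layout, umi, code)
    read_seq <- if (strand == "+") plus_seq else revComp(plus_seq)
    n_copies <- 1L + stats::rpois(1L, params$pcr_duplication_mean)
    reads[[i]] <- data.frame(read_id = ids[i], contig = ctg, start = st, end = en,
                             strand = strand, barcode = umi, n_copies = n_copies,
                             origin = tags$origin[i], stringsAsFactors = FALSE)
    qual <- strrep("I", L + nchar(prefix))
    fq[[i]] <- as.vector(rbind(sprintf("@%s_d%d", ids[i], seq_len(n_copies)),
                               paste0(prefix, read_seq), "+", qual))
  }
  writeLines(unlist(fq), fastq_path)
  readsDf <- if (ntag) do.call(rbind, reads) else .emptyTruthReads()
  mmsDf <- do.call(rbind, mms[!vapply(mms, is.null, logical(1))])
  if (is.null(mmsDf)) mmsDf <- .emptyTruthMismatches()
  aln <- TagAlignments(readsDf[, c("read_id", "barcode", "contig", "strand", "start", "end")],
                       mmsDf[, c("read_id", "pos", "ref", "alt")])
  writeTagSam(aln, plus_seqs, genome, sam_path)
  methods::new("TruthTable", m6a = m6a, snps = snps, reads = readsDf, mismatches = mmsDf)
}

#' Simulate control mRNA-seq alignments
#'
#' Uniform fragment sampling within exons of each gene's first isoform,
#' with per-gene abundance drawn log-normally (or supplied); reads carry
#' SNP alleles and uniform errors but no crosslink mutations. Output is a
#' truth SAM of intended alignments.
#'
#' @param genome a [GenomeRef].
#' @param models transcript models (non-empty).
#' @param params a [simParams()] list.
#' @param sam_path output SAM.
#' @param truth optional [TruthTable-class] supplying SNPs to apply.
#' @param abundances optional named numeric vector of per-gene relative
#'   abundances (names = gene ids); drawn log-normally when NULL.
#' @return invisibly, a list with the per-read truth data.frame (`reads`,
#'   including the source `gene_id`) and the `abundances` used.
#' @export
simulateMrnaReads <- function(genome, models, params, sam_path, truth = NULL,
                              abundances = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  if (length(models) == 0L) stop("models must be non-empty")
  set.seed(.subSeed(params$seed, "mrna"))
  gene_ids <- unique(vapply(models, function(m) m@gene_id, ""))
  iso1 <- lapply(gene_ids, function(g) {
    models[[which(vapply(models, function(m) m@gene_id, "") == g)[1L]]]
  })
  names(iso1) <- gene_ids
  if (is.null(abundances)) {
    abundances <- stats::setNames(stats::rlnorm(length(gene_ids), 0, params$mrna_abundance_sdlog),
                                  gene_ids)
  }
  exlen <- vapply(iso1, exonicLength, numeric(1))
  w <- abundances[gene_ids] * exlen
  n <- params$n_mrna_reads
  snps <- if (is.null(truth)) data.frame() else truthSnps(truth)
  L <- params$read_length
  n_umi <- sum(strsplit(params$barcode_layout, "")[[1]] == "N")
  rows <- vector("list", n); seqs <- character(n); mat <- vector("list", n)
  if (n > 0L) {
    gidx <- sample.int(length(gene_ids), n, replace = TRUE, prob = w / sum(w))
    for (i in seq_len(n)) {
      tm <- iso1[[gidx[i]]]
      ex <- exonIntervals(tm)
      elen <- ex[, 2L] - ex[, 1L]
      e <- if (nrow(ex) == 1L) 1L else sample.int(nrow(ex), 1L, prob = elen)
      rl <- min(L, elen[e])
      st <- ex[e, 1L] + sample.int(elen[e] - rl + 1L, 1L) - 1L
      en <- st + rl
      refseq <- strsplit(strandedSeq(genome, tm@contig, st, en, "+"), "")[[1L]]
      cur <- refseq
      if (nrow(snps)) {
        sh <- which(snps$contig == tm@contig & snps$pos >= st & snps$pos < en)
        for (h in sh) {
          take <- if (snps$class[h] == "hom") TRUE else stats::runif(1L) < 0.5
          if (take) cur[snps$pos[h] - st + 1L] <- snps$alt[h]
        }
      }
      nerr <- stats::rbinom(1L, rl, params$base_error_rate)
      if (nerr > 0L) for (off in sample.int(rl, nerr)) cur[off] <- sample(setdiff(.DNA, cur[off]), 1L)
      umi <- paste(sample(.DNA, n_umi, replace = TRUE), collapse = "")
      rows[[i]] <- data.frame(read_id = sprintf("m%06d", i), contig = tm@contig,
                              start = st, end = en, strand = tm@strand, barcode = umi,
                              n_copies = 1L, origin = tm@gene_id, stringsAsFactors = FALSE)
      seqs[i] <- paste(cur, collapse = "")
    }
  }
  readsDf <- if (n) do.call(rbind, rows) else .emptyTruthReads()
  aln <- TagAlignments(readsDf[, c("read_id", "barcode", "contig", "strand", "start", "end")])
  writeTagSam(aln, seqs[seq_len(nrow(readsDf))], genome, sam_path)
  invisible(list(reads = readsDf, abundances = abundances))
}
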