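# Shared fixtures: tiny genomes/models built in code, a brute-force pileup
# oracle, random caller instances, and a cached demo pipeline run.

.fixture_env <- new.env(parent = emptyenv())

# one full demo pipeline run (default parameters, seed 1), cached per session
demoRun <- function() {
  if (is.null(.fixture_env$demo)) {
    dir <- file.path(tempdir(), "cimscall_demo")
    cfg <- pipelineConfig(seed = 1L)
    t0 <- Sys.time()
    res <- suppressMessages(runPipeline(cfg, dir))
    .fixture_env$demo <- list(
      res = res, dir = dir, config = cfg,
      elapsed = as.numeric(Sys.time() - t0, units = "secs"))
  }
  .fixture_env$demo
}

# a smaller simulated bundle for module-level truth comparisons
smallSim <- function(key = "default", ...) {
  if (is.null(.fixture_env[[key]])) {
    params <- simParams(n_genes = 8L, genome_size = 40000L, n_m6a_sites = 20L,
                        coverage = 25, n_snps = 10L, n_mrna_reads = 4000L, seed = 7L, ...)
    gm <- generateGenomeAndModels(params)
    pl <- plantM6aSites(gm$genome, gm$models, params)
    dir <- file.path(tempdir(), paste0("cimscall_sim_", key))
    dir.create(dir, showWarnings = FALSE)
    fq <- file.path(dir, "miclip.fastq"); sam <- file.path(dir, "tags.sam")
    truth <- simulateMiclipReads(pl$genome, gm$models, pl$truth, params, fq, sam)
    .fixture_env[[key]] <- list(params = params, genome = pl$genome, models = gm$models,
                                truth = truth, fastq = fq, sam = sam, dir = dir)
  }
  .fixture_env[[key]]
}

# deterministic random caller instance built directly (no simulator):
# tags with injected mismatches over a random genome
randomInstance <- function(seed, n_tags = 200L, glen = 3000L, read_len = 30L,
                           mut_prob = 0.08) {
  set.seed(seed)
  genome <- GenomeRef(c(ctgA = paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                                     collapse = "")))
  tags <- data.frame(
    read_id = sprintf("r%04d", seq_len(n_tags)),
    barcode = replicate(n_tags, paste(sample(c("A", "C", "G", "T"), 5L, replace = TRUE),
                                      collapse = "")),
    contig = "ctgA",
    strand = sample(c("+", "-"), n_tags, replace = TRUE),
    start = sample.int(glen - read_len, n_tags, replace = TRUE) - 1L,
    stringsAsFactors = FALSE)
  tags$end <- tags$start + read_len
  # cluster some tags so positions reach k >= 5
  hot <- sample.int(glen - read_len, 5L) - 1L
  idx <- sample.int(n_tags, n_tags %/% 2L)
  tags$start[idx] <- hot[sample.int(5L, length(idx), replace = TRUE)] +
    sample(-4:4, length(idx), replace = TRUE)
  tags$start <- pmax(tags$start, 0L)
  tags$end <- tags$start + read_len
  mm <- list()
  for (i in seq_len(n_tags)) {
    nmut <- rbinom(1L, read_len, mut_prob)
    if (nmut == 0L) next
    at <- sample.int(read_len, nmut)
    pos <- tags$start[i] + at - 1L
    ref <- getBase(genome, "ctgA", pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    mm[[length(mm) + 1L]] <- data.frame(read_id = tags$read_id[i], pos = pos,
                                        ref = ref, alt = unname(alt),
                                        stringsAsFactors = FALSE)
  }
  list(genome = genome,
       aln = TagAlignments(tags, do.call(rbind, mm)))
}

# independent brute-force oracle: per-position, per-tag recount in
# read-strand space, then literal application of the published filters
bruteForceTallies <- function(aln, genome, min_k) {
  t <- tagsTable(aln)
  mm <- mismatchTable(aln)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (ctg in unique(t$contig)) {
    for (strand in c("+", "-")) {
      sub <- t[t$contig == ctg & t$strand == strand, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (pos in min(sub$start):(max(sub$end) - 1L)) {
        k <- 0L
        counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
        for (i in seq_len(nrow(sub))) {
          if (pos >= sub$start[i] && pos < sub$end[i]) {
            k <- k + 1L
            hit <- mm[mm$read_id == sub$read_id[i] & mm$pos == pos, , drop = FALSE]
            if (nrow(hit) == 1L) {
              alt <- if (strand == "-") comp[[hit$alt]] else hit$alt
              counts[alt] <- counts[alt] + 1L
            }
          }
        }
        if (k >= min_k && sum(counts) > 0L) {
          ref <- getBase(genome, ctg, pos)
          if (strand == "-") ref <- comp[[ref]]
          rows[[length(rows) + 1L]] <- data.frame(
            contig = ctg, pos = pos, strand = strand, ref = ref, k = k,
            nA = counts[["A"]], nC = counts[["C"]], nG = counts[["G"]], nT = counts[["T"]],
            m = if (ref == "C") counts[["T"]] else 0L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# literal brute-force filter chain on oracle tallies -> final site keys
bruteForceSites <- function(tallies, genome, snps, lo = 0.01, hi = 0.50) {
  keep <- list()
  for (i in seq_len(nrow(tallies))) {
    r <- tallies[i, ]
    if (r$ref != "C" || r$nT == 0L) next
    up <- if (r$strand == "+") r$pos - 1L else r$pos + 1L
    if (up < 0L || up >= contigLengths(genome)[[r$contig]]) next
    if (strandedBase(genome, r$contig, up, r$strand) != "A") next
    if (snpContains(snps, r$contig, r$pos) || snpContains(snps, r$contig, up)) next
    ratio <- r$nT / r$k
    if (ratio < lo - 1e-9 || ratio > hi + 1e-9) next
    keep[[length(keep) + 1L]] <- data.frame(contig = r$contig, cpos = r$pos, apos = up,
                                            strand = r$strand, m = r$nT, k = r$k,
                                            stringsAsFactors = FALSE)
  }
  if (length(keep) == 0L) return(NULL)
  out <- do.call(rbind, keep)
  out[order(out$contig, out$cpos, out$strand), , drop = FALSE]
}

# random A-preceded-C context strings (A at flank, C at flank+1)
randomBackgroundPool <- function(n, flank = 10L) {
  w <- 2L * flank + 1L
  mat <- matrix(sample(c("A", "C", "G", "T"), n * w, replace = TRUE), nrow = n)
  mat[, flank] <- "A"
  mat[, flank + 1L] <- "C"
  apply(mat, 1L, paste, collapse = "")
}

# three-gene toy annotation fixture used across annotation tests
toyModels <- function() {
  list(
    # two-isoform gene: t1 has two introns, t2 retains the first
    t1 = TranscriptModel("gA", "t1", "ctgA", "+",
                         rbind(c(100L, 200L), c(300L, 400L), c(500L, 600L)),
                         cds = c(150L, 550L)),
    t2 = TranscriptModel("gA", "t2", "ctgA", "+",
                         rbind(c(100L, 400L), c(500L, 600L)), cds = c(150L, 550L)),
    t3 = TranscriptModel("gB", "t3", "ctgA", "-",
                         rbind(c(1000L, 1200L), c(1300L, 1500L)), cds = c(1100L, 1400L))
  )
}

toyGenomeFor <- function(models, len = 2000L, seed = 11L) {
  set.seed(seed)
  GenomeRef(c(ctgA = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
}
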