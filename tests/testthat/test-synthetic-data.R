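# Generator contracts: determinism, planted-context guarantees, and
# agreement between provenance labels and the reads actually emitted.

test_that("fixed seed gives byte-identical genome, FASTQ and SAM outputs", {
  params <- simParams(n_genes = 4L, genome_size = 20000L, n_m6a_sites = 8L,
                      coverage = 10, n_snps = 4L, seed = 123L)
  out <- replicate(2, {
    gm <- generateGenomeAndModels(params)
    pl <- plantM6aSites(gm$genome, gm$models, params)
    fq <- tempfile(); sam <- tempfile()
    simulateMiclipReads(pl$genome, gm$models, pl$truth, params, fq, sam)
    fa <- tempfile(); writeGenomeFasta(pl$genome, fa)
    list(fa = readLines(fa), fq = readLines(fq), sam = readLines(sam))
  }, simplify = FALSE)
  expect_identical(out[[1]]$fa, out[[2]]$fa)
  expect_identical(out[[1]]$fq, out[[2]]$fq)
  expect_identical(out[[1]]$sam, out[[2]]$sam)
})

test_that("n_genes = 0 yields an empty model list but a genome", {
  params <- simParams(n_genes = 0L, genome_size = 5000L, seed = 2L)
  gm <- generateGenomeAndModels(params)
  expect_length(gm$models, 0L)
  expect_identical(unname(contigLengths(gm$genome)), 5000L)
  expect_error(generateGenomeAndModels(simParams(n_genes = 30L, genome_size = 5000L)),
               "sizing")
})

test_that("generated models satisfy all segment invariants", {
  params <- simParams(n_genes = 20L, genome_size = 100000L, seed = 5L)
  gm <- generateGenomeAndModels(params)
  genes <- unique(vapply(gm$models, function(m) m@gene_id, ""))
  expect_length(genes, 20L)
  strands <- vapply(gm$models, function(m) m@strand, "")
  expect_setequal(unique(strands), c("+", "-"))
  for (tm in gm$models) {
    # validity already enforces partition; check containment in contig
    expect_true(all(exonIntervals(tm) >= 0) &&
                  all(exonIntervals(tm) <= contigLengths(gm$genome)[[tm@contig]]))
    expect_true(methods::validObject(tm))
  }
})

test_that("planted sites sit in stranded DRACH 5-mers, both strands", {
  sim <- smallSim()
  m6a <- truthM6a(sim$truth)
  expect_gt(nrow(m6a), 0L)
  for (i in seq_len(nrow(m6a))) {
    five <- strandedSeq(sim$genome, m6a$contig[i], m6a$apos[i] - 2L, m6a$apos[i] + 3L,
                        m6a$strand[i])
    expect_true(grepl("^[AGT][AG]AC[ACT]$", five))
    expect_identical(five, m6a$context5[i])
    # the C immediately follows the A in stranded space
    expect_identical(strandedBase(sim$genome, m6a$contig[i], m6a$cpos[i], m6a$strand[i]), "C")
  }
  minus <- m6a[m6a$strand == "-", , drop = FALSE]
  if (nrow(minus)) {
    i <- 1L
    plus_seq <- strandedSeq(sim$genome, minus$contig[i], minus$apos[i] - 2L,
                            minus$apos[i] + 3L, "+")
    expect_identical(plus_seq, revComp(minus$context5[i]))
  }
})

test_that("exon:intron split of planted sites is respected binomially", {
  params <- simParams(n_genes = 10L, genome_size = 50000L, n_m6a_sites = 40L,
                      exon_fraction = 0.5, seed = 31L)
  gm <- generateGenomeAndModels(params)
  pl <- plantM6aSites(gm$genome, gm$models, params)
  n_int <- sum(truthM6a(pl$truth)$feature == "intronic")
  # 20 +- 4 sd at p = 0.5, n = 40 (sd ~ 3.2); generous 4 sd band
  expect_true(n_int >= 8 && n_int <= 32)
})

test_that("every read mismatch is explained by the provenance labels", {
  sim <- smallSim()
  aln <- readTagAlignments(sim$sam, sim$genome)
  got <- mismatchTable(aln)
  want <- truthMismatches(sim$truth)
  key <- function(df) sort(paste(df$read_id, df$pos, df$ref, df$alt))
  expect_identical(key(got), key(want))
  expect_setequal(unique(want$origin), intersect(unique(want$origin),
                                                 c("crosslink", "snp", "error")))
})

test_that("cims_rate = 0 plants no crosslink mismatches", {
  params <- simParams(n_genes = 4L, genome_size = 20000L, n_m6a_sites = 6L,
                      cims_rate = 0, coverage = 15, n_snps = 2L, seed = 13L)
  gm <- generateGenomeAndModels(params)
  pl <- plantM6aSites(gm$genome, gm$models, params)
  truth <- simulateMiclipReads(pl$genome, gm$models, pl$truth, params,
                               tempfile(), tempfile())
  expect_false("crosslink" %in% truthMismatches(truth)$origin)
})

test_that("pcr_duplication_mean = 0 emits exactly one FASTQ record per unique tag", {
  params <- simParams(n_genes = 4L, genome_size = 20000L, n_m6a_sites = 6L,
                      pcr_duplication_mean = 0, coverage = 15, n_snps = 2L, seed = 17L)
  gm <- generateGenomeAndModels(params)
  pl <- plantM6aSites(gm$genome, gm$models, params)
  fq <- tempfile()
  truth <- simulateMiclipReads(pl$genome, gm$models, pl$truth, params, fq, tempfile())
  expect_identical(nrow(readFastq(fq)), nrow(truthReads(truth)))
  expect_true(all(truthReads(truth)$n_copies == 1L))
})

test_that("truth m/k at planted sites estimates cims_rate and tightens with coverage", {
  mkEstimate <- function(coverage, seed) {
    params <- simParams(n_genes = 12L, genome_size = 60000L, n_m6a_sites = 35L,
                        coverage = coverage, base_error_rate = 0, n_snps = 0L,
                        seed = seed)
    gm <- generateGenomeAndModels(params)
    pl <- plantM6aSites(gm$genome, gm$models, params)
    truth <- simulateMiclipReads(pl$genome, gm$models, pl$truth, params,
                                 tempfile(), tempfile())
    m6a <- truthM6a(truth); reads <- truthReads(truth); mm <- truthMismatches(truth)
    ratios <- vapply(seq_len(nrow(m6a)), function(i) {
      span <- reads$contig == m6a$contig[i] & reads$strand == m6a$strand[i] &
        reads$start <= m6a$cpos[i] & reads$end > m6a$cpos[i]
      k <- sum(span)
      m <- sum(mm$pos == m6a$cpos[i] & mm$origin == "crosslink" &
                 mm$read_id %in% reads$read_id[span])
      if (k > 0) m / k else NA_real_
    }, numeric(1))
    ratios[!is.na(ratios)]
  }
  r50 <- mkEstimate(50, 19L)
  expect_gte(length(r50), 30L)
  expect_lt(abs(mean(r50) - 0.2), 0.03)
  # convergence property: per-site spread shrinks as coverage grows
  r20 <- mkEstimate(20, 23L)
  r80 <- mkEstimate(80, 29L)
  expect_lt(sd(r80), sd(r20))
  expect_lt(abs(mean(r80) - 0.2), 0.03)
})

test_that("mRNA simulation respects abundances and handles edge cases", {
  params <- simParams(n_genes = 2L, genome_size = 10000L, n_m6a_sites = 2L,
                      n_mrna_reads = 10000L, seed = 37L)
  gm <- generateGenomeAndModels(params)
  genes <- unique(vapply(gm$models, function(m) m@gene_id, ""))
  iso1 <- lapply(genes, function(g) gm$models[[
    which(vapply(gm$models, function(m) m@gene_id, "") == g)[1]]])
  lens <- vapply(iso1, exonicLength, numeric(1))

  # equal abundance, equal length-weighted sampling -> counts proportional to length
  ab <- stats::setNames(c(1, 1), genes)
  out <- simulateMrnaReads(gm$genome, gm$models, params, tempfile(), abundances = ab)
  counts <- table(factor(out$reads$origin, levels = genes))
  expected <- lens / sum(lens)
  expect_lt(abs(counts[[1]] / 10000 - expected[1]), 0.02)

  # 2x abundance -> ~2x length-normalised count ratio
  ab2 <- stats::setNames(c(2, 1), genes)
  out2 <- simulateMrnaReads(gm$genome, gm$models, params, tempfile(), abundances = ab2)
  c2 <- table(factor(out2$reads$origin, levels = genes))
  ratio <- (c2[[1]] / lens[1]) / (c2[[2]] / lens[2])
  expect_lt(abs(ratio - 2), 0.2)

  # zero reads -> valid empty SAM with header
  p0 <- simParams(n_genes = 2L, genome_size = 10000L, n_mrna_reads = 0L, seed = 37L)
  sam <- tempfile()
  simulateMrnaReads(gm$genome, gm$models, p0, sam)
  lines <- readLines(sam)
  expect_true(all(startsWith(lines, "@")))
  expect_identical(length(readTagAlignments(sam, gm$genome)), 0L)
})
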