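# Pileup counting, the filter chain with its exact boundaries, peak
# clustering, and equivalence with an independent brute-force oracle.

# helper: n identical tags over one interval, a subset carrying one mismatch
stackedTags <- function(n, n_mut, contig = "c1", strand = "+", start = 10L, end = 40L,
                        mut_pos = 20L, ref = "C", alt = "T") {
  tags <- data.frame(read_id = sprintf("r%03d", 1:n),
                     barcode = sprintf("B%04d", 1:n), contig = contig,
                     strand = strand, start = start, end = end, stringsAsFactors = FALSE)
  mm <- if (n_mut > 0) data.frame(read_id = tags$read_id[1:n_mut], pos = mut_pos,
                                  ref = ref, alt = alt, stringsAsFactors = FALSE)
  TagAlignments(tags, if (is.null(mm)) NULL else mm)
}

genomeWith <- function(base_at, base, len = 100L, before = "A") {
  s <- rep("G", len)
  s[base_at + 1L] <- base
  s[base_at] <- before          # plus-strand base just 5' of base_at
  GenomeRef(c(c1 = paste(s, collapse = "")))
}

test_that("pileup counts k and m exactly, plus strand", {
  g <- genomeWith(20L, "C")
  aln <- stackedTags(10, 3)
  tal <- pileupMismatches(aln, g, min_k = 5L)
  expect_identical(nrow(tal), 1L)
  expect_identical(tal$k, 10L)
  expect_identical(tal$m, 3L)
  expect_identical(tal$ref, "C")
  # below the coverage floor nothing is emitted
  expect_identical(nrow(pileupMismatches(stackedTags(4, 2), g, min_k = 5L)), 0L)
})

test_that("minus-strand tallies are expressed in read-strand space", {
  # plus-strand G with 3 tags reading A, on minus-strand tags -> stranded C>T
  s <- rep("C", 100); s[21] <- "G"; s[22] <- "T"   # stranded upstream of 20 on '-' is 21
  g <- GenomeRef(c(c1 = paste(s, collapse = "")))
  aln <- stackedTags(10, 3, strand = "-", mut_pos = 20L, ref = "G", alt = "A")
  tal <- pileupMismatches(aln, g, min_k = 5L)
  expect_identical(tal$ref, "C")
  expect_identical(tal$m, 3L)
  expect_identical(tal$nT, 3L)
})

test_that("transition restriction keeps C>T and diagnoses every class", {
  g <- genomeWith(20L, "C")
  ct <- pileupMismatches(stackedTags(10, 3), g, min_k = 5L)
  ag <- pileupMismatches(stackedTags(10, 5, mut_pos = 25L, ref = "G", alt = "A"),
                         genomeWith(25L, "G"), min_k = 5L)
  both <- rbind(ct, ag)
  res <- filterTransitions(both)
  expect_identical(nrow(res$candidates), 1L)
  expect_identical(res$candidates$m, 3L)
  expect_setequal(paste(res$diagnostics$ref, res$diagnostics$alt, sep = ">"),
                  c("C>T", "G>A"))
})

test_that("upstream-adenosine filter is strand-aware and fills apos", {
  # plus: ...A C... kept
  g <- genomeWith(20L, "C", before = "A")
  cand <- filterTransitions(pileupMismatches(stackedTags(10, 3), g, 5L))$candidates
  kept <- filterPrecededByA(cand, g)
  expect_identical(kept$apos, 19L)
  # plus: ...G C... dropped
  g2 <- genomeWith(20L, "C", before = "G")
  expect_identical(nrow(filterPrecededByA(
    filterTransitions(pileupMismatches(stackedTags(10, 3), g2, 5L))$candidates, g2)), 0L)
  # minus-strand site whose plus-strand downstream base is T (stranded A) kept
  s <- rep("C", 100); s[21] <- "G"; s[22] <- "T"
  g3 <- GenomeRef(c(c1 = paste(s, collapse = "")))
  cand3 <- filterTransitions(pileupMismatches(
    stackedTags(10, 3, strand = "-", mut_pos = 20L, ref = "G", alt = "A"), g3, 5L))$candidates
  kept3 <- filterPrecededByA(cand3, g3)
  expect_identical(kept3$apos, 21L)
})

test_that("SNP filter drops hits at either coordinate and is identity when empty", {
  cand <- data.frame(contig = "c1", pos = c(20L, 30L, 40L), strand = "+",
                     m = 3L, k = 10L, apos = c(19L, 29L, 39L), stringsAsFactors = FALSE)
  snps <- SnpCatalog(data.frame(contig = "c1", pos = c(20L, 29L)))
  out <- filterSnps(cand, snps)
  expect_identical(out$pos, 40L)         # 20 hit at C, 30 hit at A
  expect_identical(filterSnps(cand, SnpCatalog()), cand)
})

test_that("m/k ratio window is inclusive at the printed boundaries", {
  mk <- function(m, k) data.frame(contig = "c1", pos = 20L, strand = "+", ref = "C",
                                  k = k, nA = 0L, nC = 0L, nG = 0L, nT = m, m = m,
                                  apos = 19L, stringsAsFactors = FALSE)
  expect_identical(length(filterRatio(mk(3L, 10L))), 1L)    # 0.30 kept
  expect_identical(sitesTable(filterRatio(mk(3L, 10L)))$stratum, "low")
  expect_identical(length(filterRatio(mk(6L, 10L))), 0L)    # 0.60 dropped
  expect_identical(length(filterRatio(mk(0L, 10L))), 0L)    # below lower bound
  expect_identical(length(filterRatio(mk(1L, 100L))), 1L)   # exactly 0.01 kept
  expect_identical(length(filterRatio(mk(50L, 100L))), 1L)  # exactly 0.50 kept
  expect_identical(length(filterRatio(mk(51L, 100L))), 0L)  # 0.51 rejected
  expect_error(filterRatio(mk(0L, 0L)), "invariant")
})

test_that("strata partition exactly at m = 5, 10", {
  mk <- function(m) data.frame(contig = "c1", pos = 20L, strand = "+", ref = "C",
                               k = 100L, nA = 0L, nC = 0L, nG = 0L, nT = m, m = m,
                               apos = 19L, stringsAsFactors = FALSE)
  strat <- vapply(c(4L, 5L, 10L, 11L),
                  function(m) sitesTable(filterRatio(mk(m)))$stratum, "")
  expect_identical(strat, c("low", "medium", "medium", "high"))
})

test_that("peak clustering enforces the four-stack minimum and merges by overlap", {
  mkTags <- function(ivs) {
    TagAlignments(data.frame(read_id = sprintf("r%02d", seq_len(nrow(ivs))),
                             barcode = sprintf("B%02d", seq_len(nrow(ivs))),
                             contig = "c1", strand = "+",
                             start = ivs[, 1], end = ivs[, 2], stringsAsFactors = FALSE))
  }
  four <- mkTags(cbind(rep(10L, 4), rep(40L, 4)))
  p4 <- clusterPeaks(four)
  expect_identical(nrow(p4), 1L)
  expect_identical(p4$height, 4L)
  expect_identical(p4$n_tags, 4L)
  # three stacked tags fall below the cutoff
  expect_identical(nrow(clusterPeaks(mkTags(cbind(rep(10L, 3), rep(40L, 3))))), 0L)
  # a chain of 5 tags overlapping only their neighbours has height 2
  chain <- mkTags(cbind(seq(0L, 80L, by = 20L), seq(30L, 110L, by = 20L)))
  expect_identical(nrow(clusterPeaks(chain)), 0L)
  p2 <- clusterPeaks(chain, min_height = 2L)
  expect_identical(nrow(p2), 1L)
  expect_identical(p2$height, 2L)
  expect_identical(p2$end - p2$start, 110L)
  # brute-force depth profile agreement on a random instance
  set.seed(77)
  starts <- sample.int(200L, 60L, replace = TRUE)
  ivs <- cbind(starts, starts + 30L)
  peaks <- clusterPeaks(mkTags(ivs), min_height = 1L)
  depth <- integer(300)
  for (i in seq_len(nrow(ivs))) depth[(ivs[i, 1] + 1):ivs[i, 2]] <-
    depth[(ivs[i, 1] + 1):ivs[i, 2]] + 1L
  for (j in seq_len(nrow(peaks))) {
    expect_identical(peaks$height[j], max(depth[(peaks$start[j] + 1):peaks$end[j]]))
  }
  expect_identical(sum(peaks$n_tags), 60L)
})

test_that("caller output equals the brute-force oracle on random instances", {
  for (seed in c(101L, 202L)) {
    inst <- randomInstance(seed, n_tags = 200L)
    tal <- pileupMismatches(inst$aln, inst$genome, min_k = 5L)
    oracle <- bruteForceTallies(inst$aln, inst$genome, min_k = 5L)
    expect_equal(tal, oracle)
    snps <- SnpCatalog(data.frame(contig = "ctgA", pos = sample(tal$pos, 2L)))
    sites <- filterRatio(filterSnps(filterPrecededByA(
      filterTransitions(tal)$candidates, inst$genome), snps))
    want <- bruteForceSites(oracle, inst$genome, snps)
    got <- sitesTable(sites)[, c("contig", "cpos", "apos", "strand", "m", "k")]
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      rownames(want) <- NULL; rownames(got) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("filters only shrink the candidate set and preserve m <= k", {
  inst <- randomInstance(303L, n_tags = 300L)
  tal <- pileupMismatches(inst$aln, inst$genome, min_k = 5L)
  expect_true(all(tal$m <= tal$k))
  c0 <- filterTransitions(tal)$candidates
  c1 <- suppressWarnings(filterPrecededByA(c0, inst$genome))
  c2 <- filterSnps(c1, SnpCatalog(data.frame(contig = "ctgA", pos = 1:50)))
  c3 <- filterRatio(c2)
  expect_true(nrow(c0) <= nrow(tal) && nrow(c1) <= nrow(c0) &&
                nrow(c2) <= nrow(c1) && length(c3) <= nrow(c2))
})

test_that("calls are invariant under a full strand flip of the instance", {
  inst <- randomInstance(404L, n_tags = 150L, glen = 2000L)
  glen <- 2000L
  tal <- pileupMismatches(inst$aln, inst$genome, min_k = 3L)
  sites <- filterRatio(suppressWarnings(filterPrecededByA(
    filterTransitions(tal)$candidates, inst$genome)))
  # reverse-complement the genome, flip every tag and mismatch
  gflip <- GenomeRef(c(ctgA = revComp(as.character(inst$genome@sequences[[1]]))))
  t <- tagsTable(inst$aln)
  tf <- data.frame(read_id = t$read_id, barcode = t$barcode, contig = t$contig,
                   strand = ifelse(t$strand == "+", "-", "+"),
                   start = glen - t$end, end = glen - t$start, stringsAsFactors = FALSE)
  m <- mismatchTable(inst$aln)
  mf <- data.frame(read_id = m$read_id, pos = glen - 1L - m$pos,
                   ref = complementBases(m$ref), alt = complementBases(m$alt),
                   stringsAsFactors = FALSE)
  alnf <- TagAlignments(tf, mf)
  sitesf <- filterRatio(suppressWarnings(filterPrecededByA(
    filterTransitions(pileupMismatches(alnf, gflip, min_k = 3L))$candidates, gflip)))
  a <- sitesTable(sites); b <- sitesTable(sitesf)
  # map flipped coordinates back
  b$cpos <- glen - 1L - b$cpos; b$apos <- glen - 1L - b$apos
  b$strand <- ifelse(b$strand == "+", "-", "+")
  keyfun <- function(d) sort(paste(d$contig, d$cpos, d$apos, d$strand, d$m, d$k))
  expect_identical(keyfun(a), keyfun(b))
})

test_that("simulated candidates stay within planted and SNP positions when error-free", {
  params <- simParams(n_genes = 6L, genome_size = 30000L, n_m6a_sites = 12L,
                      coverage = 25, base_error_rate = 0, n_snps = 5L, seed = 53L)
  gm <- generateGenomeAndModels(params)
  pl <- plantM6aSites(gm$genome, gm$models, params)
  sam <- tempfile()
  truth <- simulateMiclipReads(pl$genome, gm$models, pl$truth, params, tempfile(), sam)
  aln <- dedupAlignments(readTagAlignments(sam, pl$genome))
  tal <- pileupMismatches(aln, pl$genome, min_k = 1L)
  cand <- filterTransitions(tal)$candidates
  legal <- c(paste0(truthM6a(truth)$contig, ":", truthM6a(truth)$cpos),
             paste0(truthSnps(truth)$contig, ":", truthSnps(truth)$pos))
  expect_true(all(paste0(cand$contig, ":", cand$pos) %in% legal))
  # after the SNP filter, zero retained sites at planted SNP coordinates
  snps <- SnpCatalog(truthSnps(truth))
  sites <- sitesTable(filterRatio(filterSnps(filterPrecededByA(cand, pl$genome), snps)))
  expect_false(any(paste0(sites$contig, ":", sites$cpos) %in%
                     paste0(truthSnps(truth)$contig, ":", truthSnps(truth)$pos)))
})
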