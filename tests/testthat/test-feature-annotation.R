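# Feature assignment with isoform precedence, metagene mass conservation,
# and intronic counting with the max-over-isoform rule.

mkSites <- function(apos, strand = "+", contig = "ctgA", m = 3L, k = 20L) {
  strand <- rep(strand, length.out = length(apos))
  cpos <- ifelse(strand == "+", apos + 1L, apos - 1L)
  CimsSites(data.frame(contig = contig, cpos = cpos, apos = apos, strand = strand,
                       m = m, k = k, ratio = m / k, stringsAsFactors = FALSE))
}

test_that("annotation categories follow segments and isoform precedence", {
  models <- toyModels()
  # apos 160 is CDS of gA; 250 is intron of t1 but exonic (CDS) in t2
  ann <- annotateSites(mkSites(c(160L, 250L, 130L, 560L)), models)
  expect_identical(ann$category, c("cds", "cds", "five_prime_utr", "three_prime_utr"))
  expect_true(all(ann$gene_id == "gA"))
  # intron in every isoform
  ann2 <- annotateSites(mkSites(450L), models)
  expect_identical(ann2$category, "intron")
  # flanks and intergenic
  ann3 <- annotateSites(mkSites(c(50L, 620L, 1900L)), models,
                        upstream_window = 80L, downstream_window = 50L)
  expect_identical(ann3$category, c("upstream", "downstream", "intergenic"))
  # minus-strand gene: upstream lies genomically right of the span
  ann4 <- annotateSites(mkSites(1540L, strand = "-"), models, upstream_window = 100L)
  expect_identical(ann4$category, "upstream")
  expect_identical(ann4$gene_id, "gB")
})

test_that("annotation equals a brute-force point-in-interval scan", {
  models <- toyModels()
  set.seed(103)
  n <- 1000L
  apos <- sample.int(1950L, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  sites <- mkSites(apos, strand = strand)
  ann <- annotateSites(sites, models)
  prec <- c("cds", "five_prime_utr", "three_prime_utr", "exon", "intron",
            "upstream", "downstream", "intergenic")
  for (i in seq_len(n)) {
    cats <- character(0)
    for (tm in models) {
      if (tm@strand != strand[i]) next
      seg <- featureSegments(tm)
      span <- transcriptSpan(tm)
      cat <- NA_character_
      for (f in c("cds", "five_prime_utr", "three_prime_utr", "intron")) {
        if (is.na(cat) && nrow(seg[[f]]) &&
            any(apos[i] >= seg[[f]][, 1] & apos[i] < seg[[f]][, 2])) cat <- f
      }
      if (is.na(cat)) {
        upIv <- if (tm@strand == "+") c(span[1] - 5000L, span[1]) else c(span[2], span[2] + 5000L)
        dnIv <- if (tm@strand == "+") c(span[2], span[2] + 1000L) else c(span[1] - 1000L, span[1])
        if (apos[i] >= upIv[1] && apos[i] < upIv[2]) cat <- "upstream"
        else if (apos[i] >= dnIv[1] && apos[i] < dnIv[2]) cat <- "downstream"
      }
      if (!is.na(cat)) cats <- c(cats, cat)
    }
    want <- if (length(cats)) prec[min(match(cats, prec))] else "intergenic"
    expect_identical(ann$category[i], want)
  }
})

test_that("uniform coverage yields flat metagene with 200/1000/300 feature masses", {
  tm <- TranscriptModel("g1", "g1.t1", "ctgA", "+",
                        rbind(c(0L, 1500L)), cds = c(200L, 1200L))
  tags <- TagAlignments(data.frame(read_id = "r1", barcode = "B", contig = "ctgA",
                                   strand = "+", start = 0L, end = 1500L,
                                   stringsAsFactors = FALSE))
  meta <- metageneProfile(tags, list(tm))
  expect_identical(meta$n_transcripts, 1L)
  expect_equal(sum(meta$profile), 1, tolerance = 1e-9)
  expect_equal(sum(meta$profile[1:200]), 200 / 1500, tolerance = 1e-9)
  expect_equal(sum(meta$profile[201:1200]), 1000 / 1500, tolerance = 1e-9)
  expect_equal(sum(meta$profile[1201:1500]), 300 / 1500, tolerance = 1e-9)
  # flat within each feature
  expect_lt(diff(range(meta$profile[1:200])), 1e-12)
})

test_that("coverage concentrated at the stop codon spikes at the CDS/3'UTR boundary", {
  tm <- TranscriptModel("g1", "g1.t1", "ctgA", "+",
                        rbind(c(0L, 1500L)), cds = c(200L, 1200L))
  tags <- TagAlignments(data.frame(read_id = sprintf("r%d", 1:20), barcode = "B",
                                   contig = "ctgA", strand = "+",
                                   start = 1190L, end = 1210L, stringsAsFactors = FALSE))
  meta <- metageneProfile(tags, list(tm))
  peak <- which.max(meta$profile)
  expect_true(peak >= 1190 && peak <= 1210)   # at the bin ~1200 boundary
  expect_equal(sum(meta$profile), 1, tolerance = 1e-9)
})

test_that("rebinning conserves mass at awkward length ratios", {
  set.seed(107)
  x37 <- runif(37)
  out <- rebinConserve(x37, 200L)
  expect_length(out, 200L)
  expect_equal(sum(out), sum(x37), tolerance = 1e-9)
  for (n in c(1, 7, 199, 1000)) {
    x <- rpois(n, 3)
    expect_equal(sum(rebinConserve(x, 200L)), sum(x), tolerance = 1e-9)
  }
  # a transcript with a 37-nt 5'UTR still contributes exactly 1
  tm <- TranscriptModel("g1", "g1.t1", "ctgA", "+",
                        rbind(c(0L, 1337L)), cds = c(37L, 1037L))
  tags <- TagAlignments(data.frame(read_id = sprintf("r%d", 1:5), barcode = "B",
                                   contig = "ctgA", strand = "+",
                                   start = c(0L, 30L, 500L, 1000L, 1300L),
                                   end = c(40L, 70L, 540L, 1040L, 1337L),
                                   stringsAsFactors = FALSE))
  meta <- metageneProfile(tags, list(tm))
  expect_equal(sum(meta$profile), 1, tolerance = 1e-9)
})

test_that("minus-strand metagene reads features in transcript orientation", {
  # coverage only over the genomically-rightmost segment = 5'UTR on minus
  tm <- TranscriptModel("g1", "g1.t1", "ctgA", "-",
                        rbind(c(0L, 1500L)), cds = c(300L, 1300L))
  tags <- TagAlignments(data.frame(read_id = sprintf("r%d", 1:3), barcode = "B",
                                   contig = "ctgA", strand = "-",
                                   start = 1300L, end = 1500L, stringsAsFactors = FALSE))
  meta <- metageneProfile(tags, list(tm))
  expect_equal(sum(meta$profile[1:200]), 1, tolerance = 1e-9)   # all mass in 5'UTR bins
})

test_that("transcripts missing a UTR are excluded and counted", {
  noUtr <- TranscriptModel("g2", "g2.t1", "ctgA", "+", rbind(c(0L, 900L)),
                           cds = c(0L, 900L))
  tags <- TagAlignments(data.frame(read_id = "r1", barcode = "B", contig = "ctgA",
                                   strand = "+", start = 0L, end = 900L,
                                   stringsAsFactors = FALSE))
  meta <- metageneProfile(tags, list(noUtr))
  expect_identical(meta$n_transcripts, 0L)
  expect_identical(meta$skipped_missing_feature, 1L)
})

test_that("intronic counting applies the any-exon exclusion and max-over-isoform rule", {
  # gA: t1 introns (200,300) and (400,500); the shorter t2 starts at 300 and
  # shares only the (400,500) intron. Three sites intronic in t1; two of
  # them also intronic in t2; none exonic anywhere -> reported max is 3
  models <- list(
    t1 = TranscriptModel("gA", "t1", "ctgA", "+",
                         rbind(c(100L, 200L), c(300L, 400L), c(500L, 600L)),
                         cds = c(150L, 550L)),
    t2 = TranscriptModel("gA", "t2", "ctgA", "+",
                         rbind(c(300L, 400L), c(500L, 600L)), cds = c(150L, 550L))
  )
  sites <- mkSites(c(210L, 420L, 460L), m = c(2L, 3L, 4L))
  counts <- countIntronic(sites, models)
  gA <- counts[counts$gene_id == "gA", ]
  expect_identical(gA$reported, 3L)          # max over isoforms: t1 carries all 3
  expect_identical(gA$reads, 9L)             # m support at the reporting isoform
  per <- attr(counts, "per_isoform")
  expect_identical(per$n_sites[per$transcript_id == "t1"], 3L)
  expect_identical(per$n_sites[per$transcript_id == "t2"], 2L)
  # a site exonic in any isoform is excluded even if intronic elsewhere
  s2 <- mkSites(250L)   # intron of toyModels t1, exon of its t2
  expect_identical(countIntronic(s2, toyModels())$reported, c(0L, 0L))
  # order invariance
  perm <- countIntronic(mkSites(c(460L, 210L, 420L), m = c(4L, 2L, 3L)),
                        rev(models))
  expect_identical(perm, {
    x <- counts
    attr(x, "per_isoform") <- attr(perm, "per_isoform")
    x
  })
})

test_that("intronic gene ranking is deterministic with documented tie-breaks", {
  counts <- data.frame(gene_id = c("g1", "g2", "g3"),
                       reported = c(7L, 4L, 4L), reads = c(10L, 5L, 9L),
                       stringsAsFactors = FALSE)
  r <- rankIntronicGenes(counts)
  expect_identical(r$gene_id, c("g1", "g3", "g2"))
  expect_identical(rankIntronicGenes(counts[c(3, 1, 2), ]), r)
  empty <- counts[0, ]
  expect_identical(nrow(rankIntronicGenes(empty)), 0L)
})

test_that("simulated intronic plants are recovered after the exon filter", {
  sim <- smallSim()
  aln <- dedupAlignments(readTagAlignments(sim$sam, sim$genome))
  res <- callCims(aln, sim$genome, SnpCatalog(truthSnps(sim$truth)))
  counts <- countIntronic(res$sites, sim$models)
  m6a <- truthM6a(sim$truth)
  # truth sites surviving the global exon filter, summed the same way
  called <- sitesTable(res$sites)
  calledKey <- paste(called$contig, called$apos, called$strand)
  intronicTruth <- m6a[m6a$feature == "intronic" &
                         paste(m6a$contig, m6a$apos, m6a$strand) %in% calledKey, ]
  inAnyExon <- vapply(seq_len(nrow(intronicTruth)), function(i) {
    any(vapply(sim$models, function(tm) {
      tm@contig == intronicTruth$contig[i] &&
        any(intronicTruth$apos[i] >= exonIntervals(tm)[, 1] &
              intronicTruth$apos[i] < exonIntervals(tm)[, 2])
    }, logical(1)))
  }, logical(1))
  expect_identical(sum(counts$reported > 0) > 0, nrow(intronicTruth[!inAnyExon, ]) > 0)
})
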