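# Configuration-driven orchestration: simulate -> demultiplex -> dedup ->
# call -> motifs -> annotate -> metagene -> intronic -> expression, with a
# recovery report against the planted truth and a hashed output manifest.

.CONFIG_KEYS <- c("seed", "sim", "min_k", "ratio_lo", "ratio_hi", "min_peak_height",
                  "flank", "metagene_lengths", "enrichment_fold", "upstream_window",
                  "downstream_window", "motif_method", "background_factor",
                  "intersect_peaks", "log_level")

#' Build a validated pipeline configuration
#'
#' Holds every tunable of the analysis with its default: the m/k window
#' [0.01, 0.50], the >= 4 stacked-tag peak height, the +/-10 nt context
#' flank, the 200/1000/300 metagene lengths, the strict >2-fold
#' enrichment threshold and the 5000/1000 bp annotation flanks. `sim` is
#' a list of [simParams()] overrides. Unknown keys are rejected.
#'
#' @param ... configuration values overriding the defaults.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(seed = 1L, sim = list(), min_k = 5L, ratio_lo = 0.01, ratio_hi = 0.50,
              min_peak_height = 4L, flank = 10L, metagene_lengths = c(200L, 1000L, 300L),
              enrichment_fold = 2.0, upstream_window = 5000L, downstream_window = 1000L,
              motif_method = "binomial", background_factor = 10L,
              intersect_peaks = FALSE, log_level = "info")
  override <- list(...)
  if (length(override) == 1L && is.null(names(override)) && is.list(override[[1L]]))
    override <- override[[1L]]
  unknown <- setdiff(names(override), .CONFIG_KEYS)
  if (length(unknown)) stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  pipelineConfig(yaml::read_yaml(path))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes every stage in dependency order under a single master seed
#' (each random stage derives its own sub-seed, so identical config and
#' seed give byte-identical outputs), writes all tables, BEDs and
#' sequence files plus the resolved configuration and an MD5 manifest to
#' `outdir`, and returns the in-memory results.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created).
#' @return (invisibly) a list with the genome, models, truth, alignments,
#'   call results, peaks, motif statistics, annotation, metagene,
#'   intronic counts, expression table, recovery report and manifest.
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  params <- do.call(simParams, c(config$sim, list(seed = config$seed)))

  gm <- generateGenomeAndModels(params)
  pl <- plantM6aSites(gm$genome, gm$models, params)
  genome <- pl$genome; models <- gm$models; truth <- pl$truth
  writeGenomeFasta(genome, file.path(outdir, "genome.fa"))
  writeGTF(models, file.path(outdir, "models.gtf"))
  snps <- SnpCatalog(truthSnps(truth)[, c("contig", "pos", "ref", "alt")])
  writeSnpTable(snps, file.path(outdir, "snps.tsv"))

  truth <- simulateMiclipReads(genome, models, truth, params,
                               file.path(outdir, "miclip.fastq"),
                               file.path(outdir, "miclip_tags.sam"))
  simulateMrnaReads(genome, models, params, file.path(outdir, "mrna_tags.sam"),
                    truth = truth)
  writeTruthTable(truth, file.path(outdir, "truth"))

  spec <- barcodeSpec(params$barcode_layout, params$sample_codes)
  demux <- demultiplex(file.path(outdir, "miclip.fastq"), spec,
                       outdir = file.path(outdir, "demux"))
  unique_reads <- lapply(demux[names(spec$samples)], collapseDuplicates)
  demux_counts <- attr(demux, "counts")

  aln <- dedupAlignments(readTagAlignments(file.path(outdir, "miclip_tags.sam"), genome))
  call <- callCims(aln, genome, snps, min_k = config$min_k,
                   lo = config$ratio_lo, hi = config$ratio_hi, flank = config$flank)
  .writeTsv(call$tallies, file.path(outdir, "tallies.tsv"))
  .writeTsv(call$diagnostics, file.path(outdir, "substitution_classes.tsv"))
  .writeTsv(call$attrition, file.path(outdir, "attrition.tsv"))

  peaks <- clusterPeaks(aln, min_height = config$min_peak_height)
  writePeaksBed(peaks, file.path(outdir, "peaks.bed"))
  # CIMS and peaks are parallel outputs by default; optionally restrict the
  # catalogue to sites inside retained peaks
  if (isTRUE(config$intersect_peaks)) call$sites <- intersectSitesWithPeaks(call$sites, peaks)

  ann <- annotateSites(call$sites, models, upstream_window = config$upstream_window,
                       downstream_window = config$downstream_window)
  st <- sitesTable(call$sites)
  st$gene_id <- ann$gene_id
  sites <- CimsSites(st)
  writeSitesBed(sites, file.path(outdir, "sites.bed"))
  .writeTsv(ann, file.path(outdir, "annotation.tsv"))

  motifres <- .motifStage(sites, genome, models, config)
  .writeTsv(motifres$enrichment, file.path(outdir, "motif_enrichment.tsv"))
  utils::write.table(motifres$freq_matrix, file.path(outdir, "context_frequency_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  .writeTsv(motifres$triplet_profile, file.path(outdir, "triplet_profile.tsv"))

  cims_genes <- unique(unlist(strsplit(ann$gene_id[!is.na(ann$gene_id)], ",", fixed = TRUE)))
  meta <- metageneProfile(aln, models, genes = cims_genes,
                          meta_lengths = config$metagene_lengths)
  .writeTsv(data.frame(bin = seq_along(meta$profile), density = meta$profile),
            file.path(outdir, "metagene.tsv"))

  intronic <- rankIntronicGenes(countIntronic(sites, models))
  .writeTsv(intronic, file.path(outdir, "intronic_counts.tsv"))

  mrna_aln <- readTagAlignments(file.path(outdir, "mrna_tags.sam"), genome)
  expr <- geneExpressionTable(aln, mrna_aln, models, sites)
  .writeTsv(expr, file.path(outdir, "expression.tsv"))
  enriched <- enrichedGenes(expr, fold = config$enrichment_fold)
  writeLines(enriched, file.path(outdir, "enriched_genes.txt"))

  recovery <- recoveryReport(sites, truth, attrition = call$attrition)
  .writeTsv(data.frame(metric = c("sensitivity", "precision", "n_called", "n_planted", "n_matched"),
                       value = c(recovery$sensitivity, recovery$precision,
                                 recovery$n_called, recovery$n_planted, recovery$n_matched)),
            file.path(outdir, "recovery.tsv"))

  resolved <- config
  resolved$sim <- params[setdiff(names(params), "sample_codes")]
  yaml::write_yaml(unclass(resolved), file.path(outdir, "resolved_config.yaml"))
  manifest <- writeManifest(outdir)

  invisible(list(genome = genome, models = models, truth = truth, params = params,
                 aln = aln, demux_counts = demux_counts, unique_reads = unique_reads,
                 call = call, sites = sites, peaks = peaks, annotation = ann,
                 motifs = motifres, metagene = meta, intronic = intronic,
                 expression = expr, enriched_genes = enriched, recovery = recovery,
                 manifest = manifest))
}

# motif statistics stage (shared by runPipeline and rerunDownstream)
.motifStage <- function(sites, genome, models, config) {
  ctx <- extractContexts(sites, genome, flank = config$flank)
  set.seed(.subSeed(config$seed, "background"))
  bg <- sampleBackgroundContexts(genome, models,
                                 n = max(config$background_factor * nrow(ctx), 100L),
                                 flank = config$flank, preceded_by_a = TRUE)
  enr <- do.call(rbind, lapply(c("RAC", "DRACH"), function(mn)
    motifEnrichmentTest(ctx, bg, motifDef(mn), method = config$motif_method)))
  enr <- rbind(enr, data.frame(motif = "RAC_fraction", observed_fraction = racFraction(ctx),
                               background_fraction = racFraction(bg), p_value = NA_real_,
                               test = "descriptive", n_sites = nrow(ctx),
                               n_background = length(bg), stringsAsFactors = FALSE))
  list(enrichment = enr, freq_matrix = frequencyMatrix(ctx),
       triplet_profile = tripletPositionalProfile(ctx, c("GGA", "GAC"), background = bg),
       contexts = ctx, background = bg)
}

#' Score called sites against the planted truth
#'
#' A call matches the truth when its inferred adenosine coordinate equals
#' a planted methylated adenosine (contig, position and strand).
#' Sensitivity is the matched fraction of planted sites, precision the
#' matched fraction of calls (NA when nothing was called). The per-filter
#' attrition table is carried through when supplied.
#'
#' @param sites a [CimsSites-class].
#' @param truth a [TruthTable-class].
#' @param attrition optional attrition data.frame from [callCims()].
#' @return list: `sensitivity`, `precision`, `n_called`, `n_planted`,
#'   `n_matched`, `attrition`.
#' @export
recoveryReport <- function(sites, truth, attrition = NULL) {
  s <- sitesTable(sites)
  m6a <- truthM6a(truth)
  callKey <- unique(paste(s$contig, s$apos, s$strand))
  truthKey <- paste(m6a$contig, m6a$apos, m6a$strand)
  matched <- sum(truthKey %in% callKey)
  list(sensitivity = if (nrow(m6a)) matched / nrow(m6a) else NA_real_,
       precision = if (length(callKey)) sum(callKey %in% truthKey) / length(callKey) else NA_real_,
       n_called = length(callKey), n_planted = nrow(m6a), n_matched = matched,
       attrition = attrition)
}

#' Write an MD5 manifest of a pipeline output directory
#'
#' @param outdir directory written by [runPipeline()].
#' @return data.frame `file`/`md5`, also written to `manifest.tsv`.
#' @export
writeManifest <- function(outdir) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = vapply(file.path(outdir, files),
                                      function(f) digest::digest(file = f, algo = "md5"), ""),
                         stringsAsFactors = FALSE)
  .writeTsv(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}

#' Re-run the analysis stages downstream of site calling
#'
#' Resume support: loads the genome, models, alignments and called sites
#' previously written by [runPipeline()] from `outdir` and recomputes the
#' motif, metagene, intronic and expression stages into
#' `file.path(outdir, "resume")`. With the same configuration the
#' resumed outputs are identical to the full run's.
#'
#' @param outdir a completed [runPipeline()] output directory.
#' @param config the same [pipelineConfig()] used for the full run.
#' @return (invisibly) the recomputed stage results.
#' @export
rerunDownstream <- function(outdir, config) {
  stopifnot(inherits(config, "PipelineConfig"))
  genome <- readGenomeFasta(file.path(outdir, "genome.fa"))
  models <- readGTF(file.path(outdir, "models.gtf"), genome)
  sites <- readSitesBed(file.path(outdir, "sites.bed"))
  aln <- dedupAlignments(readTagAlignments(file.path(outdir, "miclip_tags.sam"), genome))
  mrna_aln <- readTagAlignments(file.path(outdir, "mrna_tags.sam"), genome)
  rdir <- file.path(outdir, "resume")
  if (!dir.exists(rdir)) dir.create(rdir)
  ann <- annotateSites(sites, models, upstream_window = config$upstream_window,
                       downstream_window = config$downstream_window)
  .writeTsv(ann, file.path(rdir, "annotation.tsv"))
  motifres <- .motifStage(sites, genome, models, config)
  .writeTsv(motifres$enrichment, file.path(rdir, "motif_enrichment.tsv"))
  cims_genes <- unique(unlist(strsplit(ann$gene_id[!is.na(ann$gene_id)], ",", fixed = TRUE)))
  meta <- metageneProfile(aln, models, genes = cims_genes,
                          meta_lengths = config$metagene_lengths)
  .writeTsv(data.frame(bin = seq_along(meta$profile), density = meta$profile),
            file.path(rdir, "metagene.tsv"))
  intronic <- rankIntronicGenes(countIntronic(sites, models))
  .writeTsv(intronic, file.path(rdir, "intronic_counts.tsv"))
  expr <- geneExpressionTable(aln, mrna_aln, models, sites)
  .writeTsv(expr, file.path(rdir, "expression.tsv"))
  invisible(list(annotation = ann, motifs = motifres, metagene = meta,
                 intronic = intronic, expression = expr))
}
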