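#' Barcode layout and sample index specification
#'
#' The iCLIP barcode occupies the first `nchar(layout)` bases of every
#' read: `N` positions carry random (UMI) bases identifying independent
#' ligation events, `X` positions carry the sample index. Sample codes
#' must be pairwise distinct at more than `max_mismatches` positions so
#' assignment is unambiguous.
#'
#' @param layout mask string over `{N, X}`.
#' @param samples named character vector: sample name -> X-base string.
#' @param max_mismatches tolerated mismatches when matching the index.
#' @export
barcodeSpec <- function(layout = "NNNXXXXNN", samples = c(s1 = "TTTT"), max_mismatches = 0L) {
  if (!grepl("^[NX]+$", layout)) stop("layout must be a mask over {N, X}")
  nx <- sum(strsplit(layout, "")[[1]] == "X")
  if (any(nchar(samples) != nx)) stop("sample codes must have length ", nx)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) stop("samples must be named")
  if (length(samples) > 1L) {
    cmb <- utils::combn(length(samples), 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- strsplit(samples[[cmb[1L, j]]], "")[[1]]
      b <- strsplit(samples[[cmb[2L, j]]], "")[[1]]
      if (sum(a != b) <= max_mismatches)
        stop("sample codes not distinguishable at > max_mismatches positions")
    }
  }
  structure(list(layout = layout, samples = samples,
                 max_mismatches = as.integer(max_mismatches)),
            class = "BarcodeSpec")
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file.
#' @return data.frame with `id` (header without `@`), `seq`, `qual`.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  n <- length(lines) %/% 4L
  if (n == 0L) return(data.frame(id = character(0), seq = character(0),
                                 qual = character(0), stringsAsFactors = FALSE))
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[seq(1L, by = 4L, length.out = n)])),
             seq = lines[seq(2L, by = 4L, length.out = n)],
             qual = lines[seq(4L, by = 4L, length.out = n)], stringsAsFactors = FALSE)
}

#' Write a FASTQ data.frame back to disk
#'
#' @param reads data.frame as returned by [readFastq()].
#' @param path output file.
#' @export
writeFastq <- function(reads, path) {
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)), path)
  invisible(path)
}

#' Demultiplex barcoded reads by sample index
#'
#' Matches the X positions of the layout against the sample table
#' (tolerating up to `max_mismatches` mismatches), records the N-position
#' bases as the random barcode by appending `#<barcode>` to the read
#' header, and strips the whole layout prefix from sequence and
#' qualities. Reads whose index matches no sample go to the
#' `undetermined` stream; reads shorter than the layout are discarded
#' (counted with a warning).
#'
#' @param reads FASTQ path or data.frame from [readFastq()].
#' @param spec a [barcodeSpec()].
#' @param outdir optional directory; when given, per-sample FASTQ files
#'   `<sample>.fastq` (plus `undetermined.fastq`) are written.
#' @return named list of per-sample read data.frames (including
#'   `undetermined`), with a `counts` attribute.
#' @export
demultiplex <- function(reads, spec, outdir = NULL) {
  if (is.character(reads)) reads <- readFastq(reads)
  mask <- strsplit(spec$layout, "")[[1]]
  blen <- length(mask)
  short <- nchar(reads$seq) < blen
  if (any(short)) warning(sum(short), " read(s) shorter than the barcode layout discarded")
  reads <- reads[!short, , drop = FALSE]
  prefix <- substr(reads$seq, 1L, blen)
  xIdx <- which(mask == "X"); nIdx <- which(mask == "N")
  getChars <- function(strings, idx) {
    do.call(paste0, lapply(idx, function(i) substr(strings, i, i)))
  }
  index <- getChars(prefix, xIdx)
  barcode <- getChars(prefix, nIdx)
  assign <- rep("undetermined", nrow(reads))
  for (s in names(spec$samples)) {
    code <- spec$samples[[s]]
    if (spec$max_mismatches == 0L) {
      hit <- index == code
    } else {
      cc <- strsplit(code, "")[[1]]
      mm <- Reduce(`+`, lapply(seq_along(cc), function(i) substr(index, i, i) != cc[i]))
      hit <- mm <= spec$max_mismatches
    }
    assign[hit] <- s
  }
  out <- list()
  for (s in c(names(spec$samples), "undetermined")) {
    sel <- which(assign == s)
    df <- data.frame(id = if (length(sel)) paste0(reads$id[sel], "#", barcode[sel]) else character(0),
                     seq = substr(reads$seq[sel], blen + 1L, nchar(reads$seq[sel])),
                     qual = substr(reads$qual[sel], blen + 1L, nchar(reads$qual[sel])),
                     stringsAsFactors = FALSE)
    if (s == "undetermined") df$id <- reads$id[sel]   # no barcode claim for unmatched
    out[[s]] <- df
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      writeFastq(df, file.path(outdir, paste0(s, ".fastq")))
    }
  }
  attr(out, "counts") <- c(table(factor(assign, levels = c(names(spec$samples), "undetermined"))),
                           too_short = sum(short))
  out
}

#' Collapse PCR duplicates by (random barcode, sequence)
#'
#' Reads sharing both the random barcode (from the `#<barcode>` header
#' suffix added by [demultiplex()]) and the full read sequence are PCR
#' copies of one ligation event; one representative per group is kept,
#' chosen as the lexicographically smallest read id for determinism. The
#' operation is idempotent.
#'
#' @param reads data.frame from [demultiplex()] (one sample) or a FASTQ path.
#' @return the surviving reads, with a `dup_count` column giving group sizes.
#' @export
collapseDuplicates <- function(reads) {
  if (is.character(reads)) reads <- readFastq(reads)
  if (nrow(reads) == 0L) {
    reads$dup_count <- integer(0)
    return(reads)
  }
  bc <- .splitBarcode(reads$id)
  key <- paste0(bc$barcode, "|", reads$seq)
  ord <- order(key, reads$id)
  reads <- reads[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$dup_count <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

#' Deduplicate alignments by (contig, start, strand, barcode)
#'
#' Post-alignment safety net mirroring [collapseDuplicates()]: alignments
#' sharing position, strand and random barcode are collapsed to the
#' lexicographically smallest read id. Complements the sequence-keyed
#' collapse, which sequencing errors can defeat.
#'
#' @param aln a [TagAlignments-class] (barcodes required).
#' @return a deduplicated [TagAlignments-class].
#' @export
dedupAlignments <- function(aln) {
  t <- tagsTable(aln)
  if (any(is.na(t$barcode) | !nzchar(t$barcode))) stop("alignments missing barcodes")
  if (nrow(t) == 0L) return(aln)
  key <- paste(t$contig, t$start, t$strand, t$barcode, sep = "|")
  ord <- order(key, t$read_id)
  t2 <- t[ord, , drop = FALSE]
  keep_ids <- t2$read_id[!duplicated(key[ord])]
  TagAlignments(t[t$read_id %in% keep_ids, , drop = FALSE],
                mismatchTable(aln)[mismatchTable(aln)$read_id %in% keep_ids, , drop = FALSE])
}
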