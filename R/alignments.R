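#' Deduplicated tag alignments with per-base mismatches
#'
#' The counting unit of the whole analysis: a "unique tag" is one aligned,
#' duplicate-collapsed read. `tags` holds one row per alignment; all
#' coordinates are 0-based half-open on the plus strand, `strand` records
#' read orientation. `mismatches` lists every substituted base as one row
#' in plus-strand space (`ref` and `alt` are the plus-strand reference and
#' read bases); strand-aware stages complement these on the fly.
#'
#' @slot tags data.frame: `read_id`, `barcode`, `contig`, `strand`,
#'   `start`, `end`.
#' @slot mismatches data.frame: `read_id`, `pos`, `ref`, `alt`.
#' @export
setClass("TagAlignments", representation(tags = "data.frame", mismatches = "data.frame"))

setValidity("TagAlignments", function(object) {
  t <- object@tags; m <- object@mismatches
  if (!all(c("read_id", "barcode", "contig", "strand", "start", "end") %in% names(t)))
    return("missing tag columns")
  if (!all(c("read_id", "pos", "ref", "alt") %in% names(m)))
    return("missing mismatch columns")
  if (nrow(t) && any(t$end <= t$start)) return("tag with non-positive width")
  if (nrow(t) && anyDuplicated(t$read_id)) return("duplicate read ids")
  if (nrow(m) && !all(m$read_id %in% t$read_id)) return("mismatch rows for unknown reads")
  TRUE
})

.emptyTags <- function() data.frame(read_id = character(0), barcode = character(0),
                                    contig = character(0), strand = character(0),
                                    start = integer(0), end = integer(0),
                                    stringsAsFactors = FALSE)

.emptyMismatches <- function() data.frame(read_id = character(0), pos = integer(0),
                                          ref = character(0), alt = character(0),
                                          stringsAsFactors = FALSE)

#' @rdname TagAlignments-class
#' @param tags,mismatches data.frames as documented above.
#' @export
TagAlignments <- function(tags = .emptyTags(), mismatches = .emptyMismatches()) {
  tags$start <- as.integer(tags$start); tags$end <- as.integer(tags$end)
  if (nrow(mismatches)) mismatches$pos <- as.integer(mismatches$pos)
  rownames(tags) <- NULL; rownames(mismatches) <- NULL
  methods::new("TagAlignments", tags = tags, mismatches = mismatches)
}

#' @describeIn TagAlignments-class alignment table.
#' @param x a `TagAlignments`.
#' @export
tagsTable <- function(x) x@tags

#' @describeIn TagAlignments-class mismatch table (plus-strand space).
#' @export
mismatchTable <- function(x) x@mismatches

#' @describeIn TagAlignments-class number of alignments.
#' @export
setMethod("length", "TagAlignments", function(x) nrow(x@tags))

setMethod("show", "TagAlignments", function(object) {
  cat("TagAlignments with", nrow(object@tags), "tag(s) and",
      nrow(object@mismatches), "mismatch record(s)\n")
})

# barcode convention: "<read_id>#<barcode>" in SAM qname / FASTQ header
.splitBarcode <- function(ids) {
  has <- grepl("#", ids, fixed = TRUE)
  if (!all(has)) stop("barcode missing from read name(s): expected '<id>#<barcode>'")
  list(id = sub("#[^#]*$", "", ids), barcode = sub("^.*#", "", ids))
}

#' Write tag alignments as SAM
#'
#' Minimal single-end SAM: substitution-only alignments (`<len>M` CIGAR),
#' sequence stored in plus-strand orientation, barcode appended to the
#' query name as `id#barcode`. `seqs` must be the plus-strand read
#' sequences (i.e. already reverse-complemented for minus-strand tags).
#'
#' @param aln a [TagAlignments].
#' @param seqs character vector of plus-strand sequences, parallel to
#'   `tagsTable(aln)` rows.
#' @param genome a [GenomeRef] supplying the header contig lengths.
#' @param path output file.
#' @export
writeTagSam <- function(aln, seqs, genome, path) {
  t <- tagsTable(aln)
  stopifnot(length(seqs) == nrow(t))
  lens <- contigLengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  body <- if (nrow(t)) {
    sprintf("%s#%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
            t$read_id, t$barcode, ifelse(t$strand == "-", 16L, 0L),
            t$contig, t$start + 1L, t$end - t$start, seqs)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments into a TagAlignments object
#'
#' Accepts SAM text or BAM (via [Rsamtools::scanBam]). Unmapped, secondary
#' and supplementary records are dropped; only substitution-only
#' (all-`M` CIGAR) alignments are supported, matching the package's
#' indel-free alignment contract. Mismatches are derived by comparing the
#' stored sequence with the reference.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param genome a [GenomeRef] for mismatch extraction.
#' @return a [TagAlignments]; per-base mismatches in plus-strand space.
#' @export
readTagAlignments <- function(path, genome) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    df <- data.frame(qname = b$qname, flag = b$flag, rname = as.character(b$rname),
                     pos = b$pos, cigar = b$cigar, seq = as.character(b$seq),
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (length(lines) == 0L) return(TagAlignments())
    f <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(qname = vapply(f, `[`, "", 1L),
                     flag = as.integer(vapply(f, `[`, "", 2L)),
                     rname = vapply(f, `[`, "", 3L),
                     pos = as.integer(vapply(f, `[`, "", 4L)),
                     cigar = vapply(f, `[`, "", 6L),
                     seq = vapply(f, `[`, "", 10L), stringsAsFactors = FALSE)
  }
  keep <- !bitwAnd(df$flag, 0x4) & !bitwAnd(df$flag, 0x100) & !bitwAnd(df$flag, 0x800)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(TagAlignments())
  if (!all(grepl("^[0-9]+M$", df$cigar)))
    stop("unsupported CIGAR (only substitution-only '<len>M' alignments are handled)")
  width <- as.integer(sub("M$", "", df$cigar))
  bad <- !df$rname %in% contigNames(genome)
  if (any(bad)) stop("alignment references unknown contig: ", df$rname[which(bad)[1L]])
  bc <- .splitBarcode(df$qname)
  tags <- data.frame(read_id = bc$id, barcode = bc$barcode, contig = df$rname,
                     strand = ifelse(bitwAnd(df$flag, 0x10) > 0L, "-", "+"),
                     start = df$pos - 1L, end = df$pos - 1L + width,
                     stringsAsFactors = FALSE)
  mm <- vector("list", nrow(tags))
  for (ctg in unique(tags$contig)) {
    s <- .contigChar(genome, ctg)
    idx <- which(tags$contig == ctg)
    refs <- substring(s, tags$start[idx] + 1L, tags$end[idx])
    for (j in seq_along(idx)) {
      i <- idx[j]
      rb <- strsplit(refs[j], "")[[1L]]
      qb <- strsplit(toupper(df$seq[i]), "")[[1L]]
      if (length(qb) != length(rb)) stop("sequence length disagrees with CIGAR for ", df$qname[i])
      d <- which(qb != rb & qb != "N" & rb != "N")
      if (length(d)) {
        mm[[i]] <- data.frame(read_id = tags$read_id[i], pos = tags$start[i] + d - 1L,
                              ref = rb[d], alt = qb[d], stringsAsFactors = FALSE)
      }
    }
  }
  mm <- mm[!vapply(mm, is.null, logical(1))]
  TagAlignments(tags, if (length(mm)) do.call(rbind, mm) else .emptyMismatches())
}
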