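#' Reference genome container
#'
#' A thin wrapper over a [Biostrings::DNAStringSet] holding uppercase
#' contig sequences. All coordinates in this package are 0-based
#' half-open; a position `pos` on contig `ctg` refers to the base at
#' string offset `pos + 1`.
#'
#' @slot sequences a `DNAStringSet`, one entry per contig, names unique.
#' @export
setClass("GenomeRef", representation(sequences = "DNAStringSet"))

setValidity("GenomeRef", function(object) {
  s <- object@sequences
  if (length(s) == 0L) return("genome has no contigs")
  if (is.null(names(s)) || anyDuplicated(names(s))) return("contig names missing or duplicated")
  if (any(Biostrings::width(s) == 0L)) return("empty contig sequence")
  alph <- Biostrings::uniqueLetters(s)
  if (!all(alph %in% c("A", "C", "G", "T", "N")))
    return("genome contains non-ACGTN letters")
  TRUE
})

#' Construct a GenomeRef
#'
#' @param sequences a named `DNAStringSet` or named character vector of
#'   contig sequences (coerced to uppercase DNA).
#' @return a `GenomeRef` object.
#' @export
GenomeRef <- function(sequences) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(toupper(sequences))
  methods::new("GenomeRef", sequences = sequences)
}

#' @describeIn GenomeRef contig names.
#' @param x a `GenomeRef`.
#' @export
contigNames <- function(x) names(x@sequences)

#' @describeIn GenomeRef named integer vector of contig lengths (bp).
#' @export
contigLengths <- function(x) stats::setNames(Biostrings::width(x@sequences), names(x@sequences))

setMethod("show", "GenomeRef", function(object) {
  cat("GenomeRef with", length(object@sequences), "contig(s),",
      sum(Biostrings::width(object@sequences)), "bp total\n")
})

#' Read / write genome FASTA
#'
#' @param path FASTA file path.
#' @return `readGenomeFasta` returns a `GenomeRef`.
#' @export
readGenomeFasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  GenomeRef(Biostrings::DNAStringSet(toupper(s)))
}

#' @rdname readGenomeFasta
#' @param genome a `GenomeRef`.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome@sequences, path, width = 70L)
  invisible(path)
}

# internal: contig sequence as one character string (bounds-checked)
.contigChar <- function(genome, contig) {
  if (!contig %in% names(genome@sequences)) stop("unknown contig: ", contig)
  as.character(genome@sequences[[contig]])
}

#' Reference base lookup (plus strand)
#'
#' @param genome a `GenomeRef`.
#' @param contig contig name (scalar).
#' @param pos 0-based position(s).
#' @return character vector of single bases.
#' @export
getBase <- function(genome, contig, pos) {
  len <- contigLengths(genome)[[contig]]
  if (any(pos < 0L | pos >= len)) stop("position out of range for contig ", contig)
  s <- .contigChar(genome, contig)
  substring(s, pos + 1L, pos + 1L)
}

#' Strand-aware base lookup
#'
#' Returns the reference base as read on the given strand: the plus-strand
#' base for `+`, its complement for `-`. The stranded upstream neighbour of
#' `(pos, +)` is `pos - 1`; of `(pos, -)` it is `pos + 1`.
#'
#' @inheritParams getBase
#' @param strand `"+"` or `"-"` (recycled against `pos`).
#' @export
strandedBase <- function(genome, contig, pos, strand) {
  b <- getBase(genome, contig, pos)
  neg <- strand == "-"
  if (any(neg)) b[neg] <- complementBases(b[neg])
  b
}

#' Strand-aware subsequence
#'
#' Extracts the 0-based half-open interval `[start, end)` from the plus
#' strand and reverse-complements it for minus-strand queries, so the
#' returned string reads 5' to 3' on the requested strand.
#'
#' @inheritParams getBase
#' @param start,end 0-based half-open interval (scalars or vectors).
#' @param strand `"+"` or `"-"`.
#' @export
strandedSeq <- function(genome, contig, start, end, strand) {
  len <- contigLengths(genome)[[contig]]
  if (any(start < 0L | end > len | start >= end)) stop("interval out of range for contig ", contig)
  s <- .contigChar(genome, contig)
  out <- substring(s, start + 1L, end)
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revComp(out[neg])
  out
}

# internal: overwrite genome bases (plus-strand string), 0-based start
.replaceSeq <- function(genome, contig, start, replacement) {
  s <- .contigChar(genome, contig)
  substr(s, start + 1L, start + nchar(replacement)) <- replacement
  seqs <- as.character(genome@sequences)
  seqs[[contig]] <- s
  GenomeRef(seqs)
}
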