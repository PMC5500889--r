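#' Known-SNP position set
#'
#' Strand-agnostic set of genomic positions (0-based) used to exclude
#' genetic variants from CIMS calls, in the role the DGRP catalogue plays
#' for real fly data. Membership queries are exact on (contig, position).
#'
#' @slot positions data.frame with columns `contig`, `pos` (0-based
#'   integer) and optionally `ref`, `alt`.
#' @export
setClass("SnpCatalog", representation(positions = "data.frame"))

setValidity("SnpCatalog", function(object) {
  p <- object@positions
  if (!all(c("contig", "pos") %in% names(p))) return("positions needs contig and pos columns")
  if (nrow(p) && anyDuplicated(paste0(p$contig, ":", p$pos))) return("duplicate SNP positions")
  TRUE
})

#' @rdname SnpCatalog-class
#' @param positions data.frame with `contig` and `pos` columns (0-based).
#' @export
SnpCatalog <- function(positions = data.frame(contig = character(0), pos = integer(0))) {
  positions$pos <- as.integer(positions$pos)
  positions <- positions[!duplicated(paste0(positions$contig, ":", positions$pos)), , drop = FALSE]
  rownames(positions) <- NULL
  methods::new("SnpCatalog", positions = positions)
}

#' @describeIn SnpCatalog-class number of SNP positions.
#' @param x a `SnpCatalog`.
#' @export
setMethod("length", "SnpCatalog", function(x) nrow(x@positions))

setMethod("show", "SnpCatalog", function(object) {
  cat("SnpCatalog with", nrow(object@positions), "position(s)\n")
})

#' Membership test against a SnpCatalog
#'
#' Vectorised and strand-agnostic: `TRUE` where `(contig[i], pos[i])` is a
#' known SNP position.
#'
#' @param snps a [SnpCatalog].
#' @param contig,pos character / 0-based integer vectors of equal length.
#' @export
snpContains <- function(snps, contig, pos) {
  paste0(contig, ":", pos) %in% paste0(snps@positions$contig, ":", snps@positions$pos)
}

#' Read / write a SNP position table
#'
#' Tab-delimited with a header line `contig  pos  ref  alt`; `pos` is
#' 0-based. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @export
readSnpTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  SnpCatalog(df)
}

#' @rdname readSnpTable
#' @param snps a [SnpCatalog].
#' @export
writeSnpTable <- function(snps, path) {
  utils::write.table(snps@positions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
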