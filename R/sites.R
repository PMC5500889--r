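#' Filtered CIMS site set
#'
#' Container for crosslink-induced mutation sites that survived the full
#' filter chain. Each row records the mutated cytosine (`cpos`, the C->T
#' transition position), the inferred methylated adenosine one stranded
#' nucleotide upstream (`apos`), the supporting counts `m` (unique tags
#' carrying the transition) and `k` (unique tags spanning the position),
#' the mutation ratio `m/k`, the 21-nt stranded sequence context centred
#' on the C, and the `m`-based stratum (`high` m>10, `medium` 5<=m<=10,
#' `low` m<5). Coordinates are 0-based.
#'
#' @slot sites data.frame with columns `contig`, `cpos`, `apos`, `strand`,
#'   `m`, `k`, `ratio`, `context`, `stratum`, `gene_id`.
#' @export
setClass("CimsSites", representation(sites = "data.frame"))

.SITE_COLS <- c("contig", "cpos", "apos", "strand", "m", "k", "ratio",
                "context", "stratum", "gene_id")

setValidity("CimsSites", function(object) {
  s <- object@sites
  if (!all(.SITE_COLS %in% names(s))) return("missing site columns")
  if (nrow(s) == 0L) return(TRUE)
  if (any(s$m > s$k)) return("m > k at some site")
  if (!all(s$strand %in% c("+", "-"))) return("bad strand")
  if (any(abs(s$apos - s$cpos) != 1L)) return("apos must be adjacent to cpos")
  TRUE
})

#' @rdname CimsSites-class
#' @param sites data.frame with the columns documented above; missing
#'   optional columns (`context`, `stratum`, `gene_id`) are filled with NA.
#' @export
CimsSites <- function(sites = NULL) {
  if (is.null(sites) || nrow(sites) == 0L) {
    sites <- data.frame(contig = character(0), cpos = integer(0), apos = integer(0),
                        strand = character(0), m = integer(0), k = integer(0),
                        ratio = numeric(0), context = character(0),
                        stratum = character(0), gene_id = character(0),
                        stringsAsFactors = FALSE)
  } else {
    for (col in c("context", "stratum", "gene_id"))
      if (is.null(sites[[col]])) sites[[col]] <- NA_character_
    sites <- sites[, .SITE_COLS]
    sites$cpos <- as.integer(sites$cpos); sites$apos <- as.integer(sites$apos)
    sites$m <- as.integer(sites$m); sites$k <- as.integer(sites$k)
    rownames(sites) <- NULL
  }
  methods::new("CimsSites", sites = sites)
}

#' @describeIn CimsSites-class underlying site data.frame.
#' @param x a `CimsSites`.
#' @export
sitesTable <- function(x) x@sites

#' @describeIn CimsSites-class number of sites.
#' @export
setMethod("length", "CimsSites", function(x) nrow(x@sites))

setMethod("show", "CimsSites", function(object) {
  s <- object@sites
  cat("CimsSites with", nrow(s), "site(s)")
  if (nrow(s)) cat("; strata:", paste(names(table(s$stratum)), table(s$stratum), collapse = ", "))
  cat("\n")
})

#' Write / read CIMS sites as BED6+
#'
#' One 0-based half-open row per site at the mutated C. Columns: chrom,
#' start, end, name (gene id or `.`), score (`m`), strand, then `k`,
#' `ratio`, `apos`, `context`, `stratum`. A header comment line documents
#' the layout; `readSitesBed` round-trips the file losslessly.
#'
#' @param sites a [CimsSites].
#' @param path output/input file.
#' @export
writeSitesBed <- function(sites, path) {
  s <- sitesTable(sites)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore_m\tstrand\tk\tratio\tapos\tcontext\tstratum", con)
  if (nrow(s)) {
    dot <- function(v) ifelse(is.na(v), ".", v)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%.10g\t%d\t%s\t%s",
                       s$contig, s$cpos, s$cpos + 1L, dot(s$gene_id), s$m, s$strand,
                       s$k, s$ratio, s$apos, dot(s$context), dot(s$stratum)), con)
  }
  invisible(path)
}

#' @rdname writeSitesBed
#' @export
readSitesBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(CimsSites())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  undot <- function(v) ifelse(v == ".", NA_character_, v)
  df <- data.frame(contig = f[, 1L], cpos = as.integer(f[, 2L]),
                   apos = as.integer(f[, 9L]), strand = f[, 6L],
                   m = as.integer(f[, 5L]), k = as.integer(f[, 7L]),
                   stringsAsFactors = FALSE)
  df$ratio <- df$m / df$k
  df$context <- undot(f[, 10L]); df$stratum <- undot(f[, 11L]); df$gene_id <- undot(f[, 4L])
  CimsSites(df)
}

#' Write peak clusters as BED
#'
#' @param peaks data.frame from [clusterPeaks()].
#' @param path output file.
#' @export
writePeaksBed <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\theight\tstrand\tn_tags", con)
  if (nrow(peaks)) {
    writeLines(sprintf("%s\t%d\t%d\tpeak_%d\t%d\t%s\t%d",
                       peaks$contig, peaks$start, peaks$end, seq_len(nrow(peaks)),
                       peaks$height, peaks$strand, peaks$n_tags), con)
  }
  invisible(path)
}
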