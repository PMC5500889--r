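# Small shared helpers: DNA alphabet, IUPAC matching, mass-conserving
# rebinning, deterministic sub-seeds.

.DNA <- c("A", "C", "G", "T")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Complement / reverse-complement of DNA character vectors
#'
#' Operates on plain character vectors in the DNA alphabet (A/C/G/T/N).
#' `complementBases()` complements per character element (each element a
#' single base); `revComp()` reverse-complements whole strings.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
complementBases <- function(x) {
  out <- .COMPLEMENT[x]
  if (anyNA(out)) stop("non-DNA base in input: ", paste(unique(x[is.na(out)]), collapse = ","))
  unname(out)
}

#' @rdname complementBases
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# IUPAC degenerate base -> allowed literal bases
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# vectorised: does each string in `x` match the IUPAC pattern (same nchar)?
.iupacMatch <- function(x, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, length(x))
  for (i in seq_along(pat)) {
    allowed <- .IUPAC[[pat[i]]]
    if (is.null(allowed)) stop("unknown IUPAC code: ", pat[i])
    ok <- ok & substr(x, i, i) %in% allowed
  }
  ok
}

#' Rebin a per-nucleotide signal to a fixed number of bins, conserving mass
#'
#' Each source nucleotide spreads its mass across the destination bins it
#' overlaps, proportionally to overlap length. Implemented via linear
#' interpolation of the cumulative sum, so `sum(rebinConserve(x, L))`
#' equals `sum(x)` up to floating-point error for any length ratio,
#' including upsampling (e.g. a 37-nt UTR onto 200 bins).
#'
#' @param x numeric vector of per-nucleotide values.
#' @param nbins target number of bins.
#' @return numeric vector of length `nbins`.
#' @export
rebinConserve <- function(x, nbins) {
  n <- length(x)
  if (n == 0L) stop("cannot rebin an empty vector")
  if (nbins < 1L) stop("nbins must be >= 1")
  cum <- c(0, cumsum(as.numeric(x)))
  edges <- seq(0, n, length.out = nbins + 1L)
  diff(stats::approx(0:n, cum, xout = edges)$y)
}

# Named deterministic sub-seed derived from a master seed; keeps results
# independent across stages while reproducible from one integer.
.subSeed <- function(seed, stage) {
  offs <- c(genome = 101L, plant = 211L, miclip = 307L, mrna = 401L,
            background = 503L, misc = 601L)
  o <- offs[[stage]]
  if (is.null(o)) stop("unknown seed stage: ", stage)
  (as.integer(seed) * 1009L + o) %% 2147483647L
}

# 0-based half-open interval intersection of one interval with a 2-col matrix
.intersectIntervals <- function(start, end, mat) {
  if (nrow(mat) == 0L) return(mat)
  s <- pmax(start, mat[, 1L]); e <- pmin(end, mat[, 2L])
  keep <- s < e
  cbind(s[keep], e[keep])
}

.emptyIntervals <- function() matrix(integer(0), ncol = 2L)

# point-in-intervals membership (0-based half-open), vectorised over pos
.inIntervals <- function(pos, mat) {
  if (nrow(mat) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(mat))) out <- out | (pos >= mat[i, 1L] & pos < mat[i, 2L])
  out
}
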