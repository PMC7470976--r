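#' @import data.table
#' @importFrom stats rlnorm runif setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Generators fan a single master seed out into independent per-component
#' seeds so that changing one component's configuration does not perturb the
#' random streams of the others.  Results stay below 2^31 - 1.
#'
#' @param seed master seed (integer)
#' @param k child index (integer >= 0)
#' @return an integer seed
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * (as.numeric(k) + 1)) %% 2147483587) + 1L
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)

#' Reverse complement of a DNA string
#'
#' Operates on plain character strings (the genome store used throughout is a
#' named character vector).  IUPAC bases beyond ACGTN are left untouched
#' except for complementation of ACGT.
#'
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## fetch genome bases [start, end) 0-based half-open from a named character vector
seq_fetch <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop2("chromosome '%s' not present in genome", chrom)
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L) stop2("interval [%d,%d) outside chromosome '%s' (length %d)", start, end, chrom, L)
  substr(genome[[chrom]], start + 1L, end)
}

## overwrite genome bases at [start, start+nchar(repl)) 0-based
seq_plant <- function(genome, chrom, start, repl) {
  s <- genome[[chrom]]
  substr(s, start + 1L, start + nchar(repl)) <- repl
  genome[[chrom]] <- s
  genome
}

## total overlap in bases of [s1,e1) with [s2,e2)
overlap_len <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

## union length of a set of 0-based half-open intervals (two-column matrix-like)
union_bases <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}
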