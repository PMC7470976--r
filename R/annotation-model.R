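## Domain containers for genomic annotation.
##
## All coordinates inside the package are 0-based half-open ([start, end)).
## GTF converts at the I/O boundary; BED passes through unchanged.  A single
## arithmetic convention avoids off-by-one drift between modules.

VALID_STRANDS <- c("+", "-", ".")

#' Construct an annotation from an exon table
#'
#' The central container of the toolkit.  An `Annotation` bundles
#' a transcript table, an exon table, optional per-sample FPKM values and
#' optional CDS segments.  Exons use 0-based half-open coordinates.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`.  Exons of one transcript must be on one
#'   chromosome and strand, sorted (any order is accepted and re-sorted) and
#'   pairwise disjoint.
#' @param fpkm optional data.frame with columns `transcript_id`, `sample`,
#'   `fpkm` (non-negative reals).  A transcript absent from the table has
#'   *unknown* (not zero) abundance; rules that need FPKM fail closed.
#' @param cds optional data.frame with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `strand`, `phase`; every CDS segment must be contained
#'   in an exon of its transcript.
#' @param source per-transcript source label, one of
#'   `"assembly"`, `"ensembl"`, `"refseq"`, `"novel"`; a single string is
#'   recycled.
#' @param provenance free-text label for the whole annotation.
#' @param validate set `FALSE` to skip invariant checks (internal fast path).
#' @return an object of class `Annotation`
#' @export
new_annotation <- function(exons, fpkm = NULL, cds = NULL, source = "assembly",
                           provenance = "unnamed", validate = TRUE) {
  ex <- data.table::as.data.table(exons)
  req <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  miss <- setdiff(req, names(ex))
  if (length(miss)) stop2("exon table lacks column(s): %s", paste(miss, collapse = ", "))
  ex <- ex[, req, with = FALSE]
  ex[, `:=`(start = as.integer(start), end = as.integer(end),
            chrom = as.character(chrom), strand = as.character(strand),
            transcript_id = as.character(transcript_id), gene_id = as.character(gene_id))]
  data.table::setorder(ex, transcript_id, start)

  tx <- if (nrow(ex)) {
    ex[, .(chrom = chrom[1L], strand = strand[1L], gene_id = gene_id[1L],
           n_exons = .N, start = min(start), end = max(end),
           length = sum(end - start)), by = transcript_id]
  } else {
    data.table::data.table(transcript_id = character(), chrom = character(),
                           strand = character(), gene_id = character(),
                           n_exons = integer(), start = integer(), end = integer(),
                           length = integer())
  }
  if (length(source) == 1L) source <- rep(source, nrow(tx))
  if (length(source) != nrow(tx)) stop2("source must be length 1 or one per transcript")
  tx[, source := source]

  fp <- if (is.null(fpkm)) {
    data.table::data.table(transcript_id = character(), sample = character(), fpkm = numeric())
  } else {
    f <- data.table::as.data.table(fpkm)[, .(transcript_id = as.character(transcript_id),
                                             sample = as.character(sample), fpkm = as.numeric(fpkm))]
    data.table::setorder(f, transcript_id, sample)
    f
  }
  cd <- if (is.null(cds)) {
    data.table::data.table(transcript_id = character(), chrom = character(),
                           start = integer(), end = integer(), strand = character(),
                           phase = integer())
  } else {
    d <- data.table::as.data.table(cds)[, .(transcript_id = as.character(transcript_id),
                                            chrom = as.character(chrom),
                                            start = as.integer(start), end = as.integer(end),
                                            strand = as.character(strand), phase = as.integer(phase))]
    data.table::setorder(d, transcript_id, start)
    d
  }

  a <- structure(list(tx = tx, exons = ex, fpkm = fp, cds = cd,
                      provenance = as.character(provenance)),
                 class = "Annotation")
  if (validate) validate_annotation(a)
  a
}

#' Validate the structural invariants of an annotation
#'
#' Checks coordinate sanity (`start >= 0`, `end > start`, strand in
#' `+ - .`), per-transcript consistency (single chromosome and strand,
#' disjoint exons), uniqueness of transcript ids, non-negative FPKM, and CDS
#' containment within exons.
#'
#' @param a an `Annotation`
#' @return `a`, invisibly; errors describe the first violation found
#' @export
validate_annotation <- function(a) {
  ex <- a$exons
  if (nrow(ex)) {
    if (any(ex$start < 0L)) stop2("exon with negative start")
    if (any(ex$end <= ex$start)) stop2("exon with end <= start (transcript %s)",
                                       ex$transcript_id[which(ex$end <= ex$start)[1L]])
    if (!all(ex$strand %in% VALID_STRANDS)) stop2("invalid strand value")
    bad <- ex[, .(ok = data.table::uniqueN(chrom) == 1L && data.table::uniqueN(strand) == 1L),
              by = transcript_id][ok == FALSE]
    if (nrow(bad)) stop2("transcript %s spans several chromosomes or strands", bad$transcript_id[1L])
    dis <- ex[, .(ok = .N < 2L || all(start[-1L] >= end[-.N])), by = transcript_id][ok == FALSE]
    if (nrow(dis)) stop2("transcript %s has overlapping exons", dis$transcript_id[1L])
  }
  if (anyDuplicated(a$tx$transcript_id)) stop2("duplicate transcript_id")
  if (nrow(a$fpkm) && any(a$fpkm$fpkm < 0)) stop2("negative FPKM")
  if (nrow(a$cds)) {
    m <- merge(a$cds, a$exons, by = "transcript_id", allow.cartesian = TRUE,
               suffixes = c("", ".ex"))
    cov <- m[start >= start.ex & end <= end.ex & chrom == chrom.ex,
             unique(paste(transcript_id, start, end))]
    all_seg <- unique(paste(a$cds$transcript_id, a$cds$start, a$cds$end))
    if (!all(all_seg %in% cov)) stop2("CDS segment not contained in any exon")
  }
  invisible(a)
}

#' @export
print.Annotation <- function(x, ...) {
  cat(sprintf("Annotation '%s': %d genes, %d transcripts, %d exon records\n",
              x$provenance, data.table::uniqueN(x$tx$gene_id), nrow(x$tx), nrow(x$exons)))
  invisible(x)
}

#' Number of transcripts in an annotation
#' @param a an `Annotation`
#' @return integer count
#' @export
n_transcripts <- function(a) nrow(a$tx)

#' Transcript table of an annotation
#' @param a an `Annotation`
#' @return data.table with one row per transcript (id, gene, chrom, strand,
#'   exon count, span, length, source)
#' @export
transcripts <- function(a) data.table::copy(a$tx)

#' Per-transcript FPKM for one sample
#' @param a an `Annotation`
#' @param sample sample id
#' @return named numeric vector over all transcripts; `NA` where the sample
#'   has no recorded value (unknown, not zero)
#' @export
fpkm_of <- function(a, sample) {
  v <- setNames(rep(NA_real_, nrow(a$tx)), a$tx$transcript_id)
  f <- a$fpkm[sample, on = "sample", nomatch = NULL]
  v[f$transcript_id] <- f$fpkm
  v
}

## ---- intron chains ---------------------------------------------------------

#' Intron chain of one transcript
#'
#' For exons e1..en the introns are `[end(ei), start(ei+1))`; a mono-exon
#' transcript has an empty chain.  The chain is the identity key used for
#' transcript matching across replicates and annotations.
#'
#' @param a an `Annotation`
#' @param transcript_id transcript to extract
#' @return data.table with columns `chrom`, `start`, `end`, `strand`
#'   (zero rows for a mono-exon transcript)
#' @export
intron_chain <- function(a, transcript_id) {
  ex <- a$exons[transcript_id, on = "transcript_id", nomatch = NULL]
  if (!nrow(ex)) stop2("unknown transcript '%s'", transcript_id)
  if (nrow(ex) == 1L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character()))
  data.table::data.table(chrom = ex$chrom[1L],
                         start = ex$end[-nrow(ex)],
                         end = ex$start[-1L],
                         strand = ex$strand[1L])
}

#' Intron table for all multi-exon transcripts
#' @param a an `Annotation`
#' @return data.table with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `index` (1-based intron index along the genome axis)
#' @export
introns_of <- function(a) {
  empty <- data.table::data.table(transcript_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), index = integer())
  ex <- a$exons
  if (!nrow(ex)) return(empty)
  out <- ex[, {
    if (.N < 2L) NULL else list(chrom = chrom[1L], start = end[-.N], end = start[-1L],
                                strand = strand[1L], index = seq_len(.N - 1L))
  }, by = transcript_id]
  if (!nrow(out)) empty else out
}

#' Intron-chain keys for all transcripts
#'
#' The key is `chrom:strand:s1-e1,s2-e2,...` over the ordered introns;
#' mono-exon transcripts get `NA` (they are matched by overlap clustering
#' instead).
#'
#' @param a an `Annotation`
#' @return named character vector (names = transcript ids)
#' @export
chain_keys <- function(a) {
  keys <- setNames(rep(NA_character_, nrow(a$tx)), a$tx$transcript_id)
  intr <- introns_of(a)
  if (nrow(intr)) {
    k <- intr[, .(key = paste0(chrom[1L], ":", strand[1L], ":",
                               paste0(start, "-", end, collapse = ","))),
              by = transcript_id]
    keys[k$transcript_id] <- k$key
  }
  keys
}

## subset an Annotation to a set of transcript ids (order of tx table kept)
subset_annotation <- function(a, ids) {
  new_annotation(a$exons[transcript_id %in% ids],
                 fpkm = a$fpkm[transcript_id %in% ids],
                 cds = if (nrow(a$cds)) a$cds[transcript_id %in% ids] else NULL,
                 source = a$tx[transcript_id %in% ids]$source,
                 provenance = a$provenance, validate = FALSE)
}

#' Gene table of an annotation
#'
#' Genes are containers of transcripts; the span covers all member
#' transcripts (`[min start, max end)`).
#'
#' @param a an `Annotation`
#' @return data.table with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `n_transcripts`
#' @export
genes <- function(a) {
  a$tx[, .(chrom = chrom[1L], strand = strand[1L], start = min(start),
           end = max(end), n_transcripts = .N), by = gene_id]
}
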