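## Readers/writers for the three carrier formats.  GTF is 1-based inclusive
## on disk and converted to the internal 0-based half-open convention at the
## boundary; BED is already 0-based half-open and passes through.

#' Read a GTF file into an Annotation
#'
#' Accepts the common Ensembl-style dialect: tab-separated records whose
#' attribute field carries `gene_id` and `transcript_id`, with `exon` and
#' (optionally) `CDS` features.  An `FPKM` attribute, when present, is
#' recorded under the given sample id.
#'
#' @param path GTF file path
#' @param sample sample id under which to record FPKM attributes; default is
#'   the file name without extension
#' @param source source label for all transcripts (see [new_annotation()])
#' @param provenance provenance label; defaults to `sample`
#' @return an `Annotation`; GTF 1-based inclusive coordinates are converted
#'   to 0-based half-open
#' @export
read_gtf <- function(path, sample = NULL, source = "assembly", provenance = NULL) {
  if (!file.exists(path)) stop2("no such file: %s", path)
  sample <- sample %||% sub("\\.[^.]*$", "", basename(path))
  provenance <- provenance %||% sample
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(new_annotation(data.frame(chrom = character(), start = integer(), end = integer(),
                                     strand = character(), transcript_id = character(),
                                     gene_id = character()),
                          provenance = provenance))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) stop2("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                           lineno[which(nf != 9L)[1L]], nf[which(nf != 9L)[1L]])
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  feat <- m[, 3L]
  sel <- feat %in% c("exon", "CDS")
  if (!any(sel)) stop2("GTF file %s contains no exon features", path)
  m <- m[sel, , drop = FALSE]; lineno <- lineno[sel]; feat <- feat[sel]
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1))
    stop2("malformed GTF line %d: non-numeric coordinate", lineno[which(is.na(start1) | is.na(end1))[1L]])
  if (any(end1 < start1))
    stop2("GTF line %d: end < start", lineno[which(end1 < start1)[1L]])
  attr_field <- m[, 9L]
  get_attr <- function(key) {
    v <- regmatches(attr_field, regexpr(paste0(key, '\\s+"([^"]*)"'), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- grepl(paste0(key, '\\s+"'), attr_field)
    out[hit] <- sub(paste0('.*', key, '\\s+"([^"]*)".*'), "\\1", attr_field[hit])
    out
  }
  gid <- get_attr("gene_id"); tid <- get_attr("transcript_id")
  if (anyNA(tid)) stop2("GTF line %d: missing transcript_id attribute", lineno[which(is.na(tid))[1L]])
  if (anyNA(gid)) stop2("GTF line %d: missing gene_id attribute", lineno[which(is.na(gid))[1L]])
  fpkm_attr <- suppressWarnings(as.numeric(get_attr("FPKM")))

  rec <- data.table::data.table(chrom = m[, 1L], start = start1 - 1L, end = end1,
                                strand = m[, 7L], transcript_id = tid, gene_id = gid,
                                feature = feat, frame = m[, 8L], fpkm = fpkm_attr)
  ex <- rec[feature == "exon"]
  chk <- ex[, data.table::uniqueN(chrom), by = transcript_id][V1 > 1L]
  if (nrow(chk)) stop2("transcript %s spans two chromosomes", chk$transcript_id[1L])
  fp <- ex[!is.na(fpkm), .(fpkm = fpkm[1L]), by = transcript_id]
  fp <- if (nrow(fp)) data.table::data.table(transcript_id = fp$transcript_id,
                                             sample = sample, fpkm = fp$fpkm) else NULL
  cd <- rec[feature == "CDS"]
  cds <- if (nrow(cd)) cd[, .(transcript_id, chrom, start, end, strand,
                              phase = suppressWarnings(as.integer(frame)))] else NULL
  new_annotation(ex[, .(chrom, start, end, strand, transcript_id, gene_id)],
                 fpkm = fp, cds = cds, source = source, provenance = provenance)
}

#' Write an Annotation as canonical GTF
#'
#' One `exon` feature per exon (plus `CDS` features when present), attributes
#' `gene_id`, `transcript_id` and — when the annotation carries exactly one
#' FPKM sample for a transcript — `FPKM`.  Records are sorted by chromosome,
#' start and transcript id, so two writes of the same annotation are
#' byte-identical.
#'
#' @param a an `Annotation`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gtf <- function(a, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("## canonical GTF written by retra; provenance=%s", a$provenance), con)
  if (!nrow(a$exons)) return(invisible(path))
  fpmap <- setNames(numeric(), character())
  if (nrow(a$fpkm)) {
    fp1 <- a$fpkm[, if (.N == 1L) .(fpkm = fpkm) else NULL, by = transcript_id]
    if (nrow(fp1)) fpmap <- setNames(fp1$fpkm, fp1$transcript_id)
  }
  ex <- data.table::copy(a$exons)
  data.table::setorder(ex, chrom, start, transcript_id)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id, ex$transcript_id)
  f <- fpmap[ex$transcript_id]
  has <- !is.na(f)
  attrs[has] <- paste0(attrs[has], sprintf(' FPKM "%s";', format(f[has], trim = TRUE, scientific = FALSE)))
  writeLines(paste(ex$chrom, "retra", "exon", ex$start + 1L, ex$end, ".",
                   ex$strand, ".", attrs, sep = "\t"), con)
  if (nrow(a$cds)) {
    cd <- data.table::copy(a$cds)
    gi <- setNames(a$tx$gene_id, a$tx$transcript_id)
    data.table::setorder(cd, chrom, start, transcript_id)
    writeLines(paste(cd$chrom, "retra", "CDS", cd$start + 1L, cd$end, ".", cd$strand,
                     cd$phase, sprintf('gene_id "%s"; transcript_id "%s";',
                                       gi[cd$transcript_id], cd$transcript_id), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a FASTA file into a sequence store
#'
#' @param path FASTA file
#' @return named character vector of upper-cased sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) stop2("duplicate sequence name '%s' in %s", nm[duplicated(nm)][1L], path)
  setNames(toupper(as.character(x)), nm)
}

#' Write a sequence store as FASTA
#' @param genome named character vector of sequences
#' @param path output path
#' @param width line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' BED is 0-based half-open on disk and is kept as-is.
#'
#' @param path BED file
#' @return data.table with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop2("no such file: %s", path)
  b <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(b) < 3L) stop2("BED file %s has fewer than 3 columns", path)
  cn <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(b, seq_len(min(ncol(b), 6L)), cn[seq_len(min(ncol(b), 6L))])
  b[, `:=`(start = as.integer(start), end = as.integer(end), chrom = as.character(chrom))]
  if (any(b$start >= b$end)) stop2("BED interval with start >= end at row %d", which(b$start >= b$end)[1L])
  if (any(b$start < 0L)) stop2("BED interval with negative start")
  b[]
}

#' Write intervals as BED
#' @param b data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(b, path) {
  b <- data.table::as.data.table(b)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(b))
  data.table::fwrite(b[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}
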