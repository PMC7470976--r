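## Consensus coding-potential classification from three evidence channels:
## a coding score (CPAT-style), protein-domain hits (Pfam-style) and
## protein-database alignment hits (BLASTx-style tabular output).
##
## A transcript is coding with high confidence iff it passes all three
## tests simultaneously; noncoding with high confidence iff it fails all
## three; anything else is ambiguous.

#' Load coding-potential evidence tables
#'
#' @param cpat_table TSV with columns `transcript_id`, `coding_score`
#' @param domain_table TSV with a `transcript_id` column; a transcript is
#'   considered to have a domain iff it appears here at least once
#' @param hits_table tabular alignment hits in the standard 12-column
#'   format (`qseqid sseqid pident length mismatch gapopen qstart qend
#'   sstart send evalue bitscore`), no header; the best hit per transcript
#'   is the lowest e-value row.  A subject id ending in `_SPECIES`
#'   (Swiss-Prot convention, e.g. `P12345_MOUSE`) yields the species label.
#' @param transcript_ids optional universe of transcript ids; transcripts
#'   missing from a table get that channel recorded as unknown/fail
#' @return data.table with one row per transcript: `transcript_id`,
#'   `cpat_score`, `has_domain`, `hit_subject`, `hit_species`,
#'   `hit_evalue`, `hit_identity`
#' @export
load_evidence <- function(cpat_table, domain_table, hits_table, transcript_ids = NULL) {
  read_tab <- function(path, what, expect) {
    if (is.null(path)) return(NULL)
    x <- tryCatch(data.table::fread(path, sep = "\t", header = expect),
                  error = function(e) stop2("cannot parse %s table '%s': %s", what, path, conditionMessage(e)))
    x
  }
  cp <- read_tab(cpat_table, "coding-score", TRUE)
  if (!is.null(cp)) {
    if (!all(c("transcript_id", "coding_score") %in% names(cp)))
      stop2("coding-score table must have columns transcript_id, coding_score")
    bad <- which(is.na(suppressWarnings(as.numeric(cp$coding_score))))
    if (length(bad)) stop2("coding-score table row %d: non-numeric score", bad[1L])
    cp <- cp[, .(transcript_id = as.character(transcript_id), cpat_score = as.numeric(coding_score))]
  }
  dom <- read_tab(domain_table, "domain", TRUE)
  dom_ids <- if (is.null(dom)) character() else as.character(dom$transcript_id)
  ht <- read_tab(hits_table, "alignment-hit", FALSE)
  best <- NULL
  if (!is.null(ht) && nrow(ht)) {
    if (ncol(ht) < 12L) stop2("alignment-hit table must have 12 columns (found %d)", ncol(ht))
    data.table::setnames(ht, 1:12, c("qseqid", "sseqid", "pident", "length", "mismatch",
                                     "gapopen", "qstart", "qend", "sstart", "send",
                                     "evalue", "bitscore"))
    bad <- which(is.na(suppressWarnings(as.numeric(ht$evalue))))
    if (length(bad)) stop2("alignment-hit table row %d: non-numeric e-value", bad[1L])
    ht[, evalue := as.numeric(evalue)]
    best <- ht[order(evalue, sseqid), .SD[1L], by = qseqid][
      , .(transcript_id = as.character(qseqid), hit_subject = as.character(sseqid),
          hit_evalue = evalue, hit_identity = as.numeric(pident))]
    best[, hit_species := ifelse(grepl("_[A-Za-z]+$", hit_subject),
                                 sub(".*_([A-Za-z]+)$", "\\1", hit_subject), NA_character_)]
  }
  ids <- unique(c(transcript_ids, if (!is.null(cp)) cp$transcript_id, dom_ids,
                  if (!is.null(best)) best$transcript_id))
  ev <- data.table::data.table(transcript_id = sort(ids))
  ev[, cpat_score := if (is.null(cp)) NA_real_ else cp$cpat_score[match(transcript_id, cp$transcript_id)]]
  ev[, has_domain := transcript_id %in% dom_ids]
  if (is.null(best)) {
    ev[, `:=`(hit_subject = NA_character_, hit_species = NA_character_,
              hit_evalue = NA_real_, hit_identity = NA_real_)]
  } else {
    m <- match(ev$transcript_id, best$transcript_id)
    ev[, `:=`(hit_subject = best$hit_subject[m], hit_species = best$hit_species[m],
              hit_evalue = best$hit_evalue[m], hit_identity = best$hit_identity[m])]
  }
  ev[]
}

#' Consensus coding classification
#'
#' Test 1: coding score strictly greater than `cpat_cutoff` (an unknown
#' score fails closed).  Test 2: at least one domain hit.  Test 3: a best
#' alignment hit with e-value strictly below `evalue_max`.  Verdict:
#' `coding_high_confidence` iff all three pass; `noncoding_high_confidence`
#' iff all three fail; otherwise `ambiguous`.
#'
#' @param evidence data.table as returned by [load_evidence()]
#' @param cpat_cutoff coding-score cutoff; no universal value exists — the
#'   package default of 0.364 is a published convention and is echoed in the
#'   output so it is never applied silently
#' @param evalue_max e-value threshold (strict `<`), default `1e-5`
#' @return data.table with `transcript_id`, `pass_score`, `pass_domain`,
#'   `pass_hit`, `verdict`, plus attributes `cpat_cutoff` and `evalue_max`
#' @export
classify_coding <- function(evidence, cpat_cutoff = 0.364, evalue_max = 1e-5) {
  stopifnot(cpat_cutoff > 0, cpat_cutoff < 1)
  ev <- data.table::as.data.table(evidence)
  out <- ev[, .(transcript_id,
                pass_score = !is.na(cpat_score) & cpat_score > cpat_cutoff,
                pass_domain = has_domain %in% TRUE,
                pass_hit = !is.na(hit_evalue) & hit_evalue < evalue_max)]
  out[, verdict := ifelse(pass_score & pass_domain & pass_hit, "coding_high_confidence",
                          ifelse(!pass_score & !pass_domain & !pass_hit,
                                 "noncoding_high_confidence", "ambiguous"))]
  data.table::setattr(out, "cpat_cutoff", cpat_cutoff)
  data.table::setattr(out, "evalue_max", evalue_max)
  out[]
}

#' Longest open reading frame over the three forward frames
#'
#' Scans ATG..stop ORFs; the length is counted in non-stop codons and the
#' span includes the stop codon.  Ties are broken by the leftmost start.
#'
#' @param sequence nucleotide string over `A C G T N`
#' @return list with `start`, `end` (0-based half-open span including the
#'   stop codon) and `codons` (ORF length in codons excluding the stop), or
#'   `NULL` when no complete ORF exists
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) stop2("sequence contains characters outside A/C/G/T/N")
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    i <- frame
    open_at <- NA_integer_
    while (i + 3L <= n) {
      cod <- substr(s, i + 1L, i + 3L)
      if (is.na(open_at)) {
        if (cod == "ATG") open_at <- i
      } else if (cod %in% stops) {
        codons <- (i - open_at) %/% 3L
        if (is.null(best) || codons > best$codons ||
            (codons == best$codons && open_at < best$start)) {
          best <- list(start = open_at, end = i + 3L, codons = codons)
        }
        open_at <- NA_integer_
      }
      i <- i + 3L
    }
  }
  best
}

#' Tally best-hit subject species
#'
#' @param evidence data.table from [load_evidence()]
#' @return named integer vector of best-hit counts per species label
#'   (transcripts without a hit are skipped); empty when no hits exist
#' @export
species_tally <- function(evidence) {
  ev <- data.table::as.data.table(evidence)
  sp <- ev$hit_species[!is.na(ev$hit_species)]
  if (!length(sp)) return(setNames(integer(), character()))
  tb <- table(sp)
  setNames(as.integer(tb), names(tb))
}
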