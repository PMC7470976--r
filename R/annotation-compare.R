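## Transcript-level comparison between annotations: match classification,
## precision, dataset summary statistics and isoforms-per-gene distributions.

MATCH_CLASSES <- c("exact", "contained", "novel_isoform", "other")

#' Classify every query transcript against a reference annotation
#'
#' Classes, in precedence order:
#' \describe{
#'   \item{exact}{identical intron chain (multi-exon); for a mono-exon query,
#'     containment within the span of a reference transcript on the same
#'     strand that overlaps the query exonically}
#'   \item{contained}{the query chain is a contiguous sub-chain of a
#'     reference chain}
#'   \item{novel_isoform}{the query shares at least one splice junction with
#'     a reference transcript}
#'   \item{other}{no structural relation (intergenic or exonic-overlap only)}
#' }
#'
#' @param query `Annotation` of predicted transcripts
#' @param reference reference `Annotation`
#' @return named character vector (names = query transcript ids) with one
#'   class per transcript
#' @export
classify_transcripts <- function(query, reference) {
  qk <- chain_keys(query)
  rk <- chain_keys(reference)
  rk_set <- unique(rk[!is.na(rk)])
  out <- setNames(rep("other", nrow(query$tx)), query$tx$transcript_id)

  ## --- multi-exon queries -------------------------------------------------
  multi_ids <- names(qk)[!is.na(qk)]
  if (length(multi_ids)) {
    ## exact
    out[multi_ids[qk[multi_ids] %in% rk_set]] <- "exact"
    todo <- multi_ids[out[multi_ids] == "other"]
    if (length(todo)) {
      ## contained: contiguous sub-chain, same chrom+strand ("," delimited
      ## string containment on intron lists)
      split_key <- function(k) {
        m <- regmatches(k, regexec("^([^:]+:[^:]+):(.*)$", k))
        list(prefix = vapply(m, `[`, "", 2L), list = vapply(m, `[`, "", 3L))
      }
      rs <- split_key(rk_set); qs <- split_key(qk[todo])
      contained <- vapply(seq_along(todo), function(i) {
        same <- rs$prefix == qs$prefix[i]
        any(grepl(paste0(",", qs$list[i], ","), paste0(",", rs$list[same], ","), fixed = TRUE))
      }, logical(1))
      out[todo[contained]] <- "contained"
      todo <- todo[!contained]
    }
    if (length(todo)) {
      ## novel isoform: shares >= 1 junction with a reference transcript
      ri <- introns_of(reference)
      if (nrow(ri)) {
        rset <- unique(paste(ri$chrom, ri$strand, ri$start, ri$end))
        qi <- introns_of(query)[transcript_id %in% todo]
        hit <- qi[paste(chrom, strand, start, end) %in% rset, unique(transcript_id)]
        out[hit] <- "novel_isoform"
      }
    }
  }

  ## --- mono-exon queries --------------------------------------------------
  mono_ids <- names(qk)[is.na(qk)]
  if (length(mono_ids) && nrow(reference$tx)) {
    qtx <- query$tx[transcript_id %in% mono_ids]
    rtx <- reference$tx
    rex <- reference$exons
    for (i in seq_len(nrow(qtx))) {
      cand <- rtx[chrom == qtx$chrom[i] & strand == qtx$strand[i] &
                    start <= qtx$start[i] & end >= qtx$end[i]]
      if (!nrow(cand)) next
      ov <- rex[transcript_id %in% cand$transcript_id &
                  start < qtx$end[i] & end > qtx$start[i]]
      if (nrow(ov)) out[qtx$transcript_id[i]] <- "exact"
    }
  }
  out
}

#' Classify one transcript
#' @param query `Annotation` containing the transcript
#' @param transcript_id id of the transcript to classify
#' @param reference reference `Annotation`
#' @return a single class label (see [classify_transcripts()])
#' @export
classify_transcript <- function(query, transcript_id, reference) {
  classify_transcripts(subset_annotation(query, transcript_id), reference)[[transcript_id]]
}

#' Precision of a predicted annotation against a reference
#'
#' Fraction of predicted transcripts whose match class falls in `match`
#' (default: exact structural matches only).
#'
#' @param predicted predicted `Annotation` (must be non-empty)
#' @param reference reference `Annotation`
#' @param match set of accepted classes
#' @return a real in `[0, 1]`
#' @export
precision <- function(predicted, reference, match = "exact") {
  if (!nrow(predicted$tx)) stop2("precision is undefined for an empty predicted annotation")
  cls <- classify_transcripts(predicted, reference)
  mean(cls %in% match)
}

#' Summary statistics of an annotation
#'
#' Transcribed region = union of full transcript spans (introns included);
#' exon region = union of exon intervals; both unions are strand-blind so
#' shared bases count once.  Exon number counts distinct
#' (chrom, start, end, strand) coordinates by default.
#'
#' @param a an `Annotation`
#' @param genome_length total genome length in bases (> 0)
#' @param distinct_exons count distinct exon coordinates (`TRUE`, default)
#'   or exon records (`FALSE`)
#' @return list with `genes`, `transcripts`, `transcribed_bases`,
#'   `transcribed_ratio`, `exon_number`, `exon_bases`, `exon_ratio`
#' @export
summarize_annotation <- function(a, genome_length, distinct_exons = TRUE) {
  stopifnot(genome_length > 0)
  tx <- a$tx; ex <- a$exons
  span_bases <- if (nrow(tx)) sum(vapply(split(seq_len(nrow(tx)), tx$chrom), function(i)
    union_bases(tx$start[i], tx$end[i]), numeric(1))) else 0
  exon_bases <- if (nrow(ex)) sum(vapply(split(seq_len(nrow(ex)), ex$chrom), function(i)
    union_bases(ex$start[i], ex$end[i]), numeric(1))) else 0
  n_exons <- if (distinct_exons) nrow(unique(ex[, .(chrom, start, end, strand)])) else nrow(ex)
  list(genes = data.table::uniqueN(tx$gene_id),
       transcripts = nrow(tx),
       transcribed_bases = as.numeric(span_bases),
       transcribed_ratio = as.numeric(span_bases) / genome_length,
       exon_number = n_exons,
       exon_bases = as.numeric(exon_bases),
       exon_ratio = as.numeric(exon_bases) / genome_length)
}

#' Isoforms-per-gene distribution
#'
#' @param a an `Annotation`
#' @param max_k histogram cap: genes with `>= max_k` isoforms share one bin
#' @return list with `histogram` (named counts `1, 2, ..., >=max_k`),
#'   `multi_isoform_fraction` (genes with > 1 isoform) and
#'   `mean_isoforms_multi` (mean isoform count over multi-isoform genes;
#'   `NA` when there are none)
#' @export
isoform_distribution <- function(a, max_k = 5L) {
  n <- a$tx[, .N, by = gene_id]$N
  if (!length(n)) return(list(histogram = integer(), multi_isoform_fraction = NA_real_,
                              mean_isoforms_multi = NA_real_))
  bins <- pmin(n, max_k)
  hist <- tabulate(bins, nbins = max_k)
  names(hist) <- c(as.character(seq_len(max_k - 1L)), paste0(">=", max_k))
  multi <- n[n >= 2L]
  list(histogram = hist,
       multi_isoform_fraction = mean(n > 1L),
       mean_isoforms_multi = if (length(multi)) mean(multi) else NA_real_)
}
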