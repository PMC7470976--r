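## Position-anchored signal analyses: TSS peak-coverage metaprofile,
## TTS polyA hexamer scan, canonical splice-signature tally and
## transposable-element / exon overlap fractions.

## 5'-most base of each transcript in transcript orientation (0-based)
.tss_table <- function(a) {
  tx <- a$tx
  nostrand <- tx$strand == "."
  if (any(nostrand)) {
    warn2("%d unstranded transcripts excluded from strand-dependent analysis", sum(nostrand))
    tx <- tx[!nostrand]
  }
  tx[, .(transcript_id, chrom, strand, pos = ifelse(strand == "+", start, end - 1L))]
}

## 3'-most base of each transcript in transcript orientation (0-based)
.tts_table <- function(a) {
  tx <- a$tx
  tx <- tx[strand != "."]
  tx[, .(transcript_id, chrom, strand, pos = ifelse(strand == "+", end - 1L, start))]
}

## binary in-peak indicator lookup per chromosome (1-based index into vec)
.peak_cover <- function(peaks, upto) {
  covs <- list()
  for (cn in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == cn, ]
    L <- max(upto[[cn]] %||% 0L, max(p$end))
    v <- logical(L)
    for (i in seq_len(nrow(p))) v[(p$start[i] + 1L):p$end[i]] <- TRUE
    covs[[cn]] <- v
  }
  covs
}

#' TSS peak-coverage metaprofile
#'
#' Builds the per-offset fraction of expressed, deduplicated TSS windows
#' whose base lies inside at least one peak.  TSS positions are
#' deduplicated by (chrom, position, strand); transcripts below the
#' expression threshold are removed; minus-strand windows are flipped so
#' positive offsets point downstream of transcription.  Coverage is binary
#' per base (inside >= 1 peak), matching peak-file semantics.
#'
#' @param a an `Annotation`
#' @param expr named numeric vector of per-transcript FPKM (e.g.
#'   `fpkm_of(a, sample)`); transcripts with `FPKM >= min_fpkm` are kept
#' @param peaks data.frame of peak intervals (`chrom`, `start`, `end`,
#'   0-based half-open)
#' @param flank window half-width in bases (default 10000)
#' @param min_fpkm expression threshold (keep `>=`, default 0.5)
#' @return list of class `MetaProfile`: `anchor = "TSS"`, `offsets`
#'   (`-flank..flank`), `values` (fractions in `[0,1]`), `n_anchors`
#' @export
tss_profile <- function(a, expr, peaks, flank = 10000L, min_fpkm = 0.5) {
  tss <- .tss_table(a)
  keep <- names(expr)[!is.na(expr) & expr >= min_fpkm]
  tss <- tss[transcript_id %in% keep]
  tss <- unique(tss[, .(chrom, strand, pos)])
  if (!nrow(tss)) stop2("no expressed TSS at FPKM >= %g", min_fpkm)
  peaks <- data.table::as.data.table(peaks)
  offsets <- seq.int(-flank, flank)
  acc <- numeric(length(offsets))
  cov <- .peak_cover(peaks, upto = list())
  for (i in seq_len(nrow(tss))) {
    v <- cov[[tss$chrom[i]]]
    if (is.null(v)) next
    base <- if (tss$strand[i] == "+") tss$pos[i] + offsets else tss$pos[i] - offsets
    idx <- base + 1L
    ok <- idx >= 1L & idx <= length(v)
    hit <- logical(length(offsets)); hit[ok] <- v[idx[ok]]
    acc <- acc + hit
  }
  structure(list(anchor = "TSS", offsets = offsets, values = acc / nrow(tss),
                 n_anchors = nrow(tss)), class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile at %s: %d offsets [%d..%d], %d anchors, max %.3f\n",
              x$anchor, length(x$offsets), min(x$offsets), max(x$offsets),
              x$n_anchors, max(x$values)))
  invisible(x)
}

#' Randomly shuffle anchor positions within their chromosomes
#'
#' Each anchor gets a uniform random position on its own chromosome; the
#' strand is preserved and the result is reproducible by seed.
#'
#' @param anchors data.frame with `chrom`, `pos`, `strand`
#' @param genome_lengths named integer vector of chromosome lengths
#' @param seed RNG seed (required)
#' @return data.table of the same shape with shuffled `pos`
#' @export
shuffle_anchors <- function(anchors, genome_lengths, seed) {
  stopifnot(!missing(seed))
  anchors <- data.table::as.data.table(anchors)
  out <- data.table::copy(anchors)
  set.seed(seed)
  for (cn in unique(out$chrom)) {
    n <- sum(out$chrom == cn)
    out[chrom == cn, pos := sample.int(genome_lengths[[cn]], n, replace = TRUE) - 1L]
  }
  out[]
}

#' PolyA hexamer scan upstream of transcription termination sites
#'
#' Scans the `window` genomic bases immediately upstream (in transcript
#' orientation) of each TTS for occurrences of the polyA signal hexamers.
#' Offsets are relative to the TTS: `-window .. -1`, with a hexamer
#' reported at the offset of its first base (so hits fall in
#' `-window .. -6`).
#'
#' @param a an `Annotation`
#' @param genome named character vector of chromosome sequences
#' @param window upstream window width (default 100)
#' @param hexamers signal hexamers (default `AATAAA`, `ATTAAA`)
#' @return list with `profile` (a `MetaProfile`: fraction of transcripts
#'   with a hexamer starting at each offset) and `hits` (data.table
#'   `transcript_id`, `offset`, `hexamer`, `truncated`)
#' @export
tts_polya_scan <- function(a, genome, window = 100L, hexamers = c("AATAAA", "ATTAAA")) {
  tts <- .tts_table(a)
  offsets <- seq.int(-window, -1L)
  acc <- numeric(length(offsets))
  hits <- list()
  for (i in seq_len(nrow(tts))) {
    cn <- tts$chrom[i]; p <- tts$pos[i]; st <- tts$strand[i]
    L <- nchar(genome[[cn]])
    if (st == "+") { lo <- p - window; hi <- p; trunc <- lo < 0L; lo <- max(0L, lo) }
    else { lo <- p + 1L; hi <- p + 1L + window; trunc <- hi > L; hi <- min(L, hi) }
    s <- seq_fetch(genome, cn, lo, hi)
    if (st == "-") s <- revcomp(s)
    w <- nchar(s)                       # may be < window when truncated
    found <- integer()
    hx_found <- character()
    for (hx in hexamers) {
      m <- gregexpr(hx, s, fixed = TRUE)[[1L]]
      if (m[1L] != -1L) { found <- c(found, as.integer(m)); hx_found <- c(hx_found, rep(hx, length(m))) }
    }
    if (length(found)) {
      off <- -w + found - 1L            # string pos p0 (1-based) -> offset
      sel <- !duplicated(off)
      idx <- match(off[sel], offsets)
      acc[idx] <- acc[idx] + 1L
      hits[[length(hits) + 1L]] <- data.table::data.table(
        transcript_id = tts$transcript_id[i], offset = off, hexamer = hx_found,
        truncated = trunc)
    } else if (trunc) {
      hits[[length(hits) + 1L]] <- data.table::data.table(
        transcript_id = tts$transcript_id[i], offset = integer(), hexamer = character(),
        truncated = logical())
    }
  }
  prof <- structure(list(anchor = "TTS", offsets = offsets,
                         values = if (nrow(tts)) acc / nrow(tts) else acc,
                         n_anchors = nrow(tts)), class = "MetaProfile")
  list(profile = prof, hits = data.table::rbindlist(hits))
}

#' Splice-signature tally over unique junctions
#'
#' For every unique junction the donor dinucleotide (first two intronic
#' bases) and acceptor dinucleotide (last two), strand-corrected to
#' transcript orientation, are read from the genome and tallied into the
#' canonical GT-AG, the minor GC-AG and AT-AC classes, and "other".
#'
#' @param a an `Annotation`
#' @param genome named character vector of chromosome sequences
#' @return list with `junctions` (per unique junction: `chrom`, `strand`,
#'   `start`, `end`, `signature`), `counts` and `fractions` (named over
#'   `GT-AG`, `GC-AG`, `AT-AC`, `other`; fractions sum to 1)
#' @export
splice_signature_stats <- function(a, genome) {
  intr <- unique(introns_of(a)[, .(chrom, strand, start, end)])
  if (!nrow(intr)) {
    z <- setNames(numeric(4), c("GT-AG", "GC-AG", "AT-AC", "other"))
    return(list(junctions = intr, counts = z, fractions = z))
  }
  sig <- vapply(seq_len(nrow(intr)), function(i) {
    s <- intr$start[i]; e <- intr$end[i]; cn <- intr$chrom[i]
    first2 <- seq_fetch(genome, cn, s, s + 2L)
    last2 <- seq_fetch(genome, cn, e - 2L, e)
    if (intr$strand[i] == "-") paste0(revcomp(last2), "-", revcomp(first2))
    else paste0(first2, "-", last2)
  }, character(1))
  intr[, signature := sig]
  cls <- ifelse(sig %in% c("GT-AG", "GC-AG", "AT-AC"), sig, "other")
  counts <- setNames(numeric(4), c("GT-AG", "GC-AG", "AT-AC", "other"))
  tb <- table(factor(cls, levels = names(counts)))
  counts[] <- as.numeric(tb)
  list(junctions = intr[], counts = counts, fractions = counts / sum(counts))
}

#' Flag RepeatMasker records that are transposable elements
#'
#' Low-complexity, satellite and simple repeats are not TEs and are
#' removed from overlap analyses.
#'
#' @param repeat_class character vector of repeat class/family strings
#'   (e.g. `"LINE/L1"`, `"Simple_repeat"`)
#' @return logical vector, `TRUE` for TE records
#' @export
is_te <- function(repeat_class) {
  !grepl("Low_complexity|Satellite|Simple_repeat", repeat_class)
}

## per-transcript exonic overlap (bases) with a reduced interval set
.exon_overlap_bases <- function(exons, intervals) {
  total <- setNames(numeric(data.table::uniqueN(exons$transcript_id)),
                    unique(exons$transcript_id))
  for (cn in intersect(unique(exons$chrom), unique(intervals$chrom))) {
    ex <- exons[chrom == cn]
    iv <- intervals[intervals$chrom == cn, ]
    ir_ex <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    ir_iv <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
    hits <- IRanges::findOverlaps(ir_ex, ir_iv)
    if (!length(hits)) next
    w <- IRanges::width(IRanges::pintersect(ir_ex[S4Vectors::queryHits(hits)],
                                            ir_iv[S4Vectors::subjectHits(hits)]))
    dt <- data.table::data.table(tid = ex$transcript_id[S4Vectors::queryHits(hits)], w = w)
    agg <- dt[, .(w = sum(w)), by = tid]
    total[agg$tid] <- total[agg$tid] + agg$w
  }
  total
}

#' Exonic overlap between transcript classes and transposable elements
#'
#' Non-TE repeat records (low complexity, satellite, simple repeats) are
#' removed first.  For each transcript class the fraction is the summed
#' base overlap between its transcripts' exons and the TE union, divided by
#' the total transcript length (sum of exon bases) of the class; per-family
#' fractions use the same denominator.
#'
#' @param classes named list of `Annotation` values (one per transcript
#'   class), or a single `Annotation`
#' @param repeats data.frame with `chrom`, `start`, `end`, `name` (repeat
#'   class/family string)
#' @return data.table with columns `class`, `family` (`"all_TE"` plus each
#'   family), `overlap_bases`, `total_bases`, `fraction`
#' @export
te_overlap <- function(classes, repeats) {
  if (inherits(classes, "Annotation")) classes <- list(all = classes)
  repeats <- data.table::as.data.table(repeats)
  te <- repeats[is_te(name)]
  out <- list()
  for (cl in names(classes)) {
    a <- classes[[cl]]
    denom <- sum(a$tx$length)
    fams <- c("all_TE", sort(unique(te$name)))
    for (fam in fams) {
      iv <- if (fam == "all_TE") te else te[name == fam]
      ov <- if (nrow(iv) && nrow(a$exons)) sum(.exon_overlap_bases(a$exons, iv)) else 0
      out[[length(out) + 1L]] <- data.table::data.table(
        class = cl, family = fam, overlap_bases = ov, total_bases = denom,
        fraction = if (denom > 0) ov / denom else NA_real_)
    }
  }
  data.table::rbindlist(out)
}
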