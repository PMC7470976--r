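## Seven-way classification of alternative-splicing events between isoform
## pairs of a gene: skipped exon (SE), intron retention (IR), alternative
## 5'/3' splice site (A5SS/A3SS), alternative first/last exon (AFE/ALE) and
## mutually exclusive exons (MXE).  The comparison is a bubble
## decomposition: the genome axis is split at splice sites shared by both
## isoforms, and every segment where the two intron chains disagree becomes
## a variation bubble that is matched against the structural patterns.
## Bubbles that fit none of the seven patterns are labelled "complex" and
## excluded from the seven-way tally; pure 5'/3'-end length differences are
## not events.

AS_TYPES <- c("SE", "IR", "A5SS", "A3SS", "AFE", "ALE", "MXE")

.intron_mat <- function(a, tid) {
  ic <- intron_chain(a, tid)
  if (!nrow(ic)) matrix(integer(), ncol = 2L) else cbind(ic$start, ic$end)
}

## introns (rows of 2-col matrix) lying within [lo, hi]
.in_seg <- function(im, lo, hi) im[im[, 1L] >= lo & im[, 2L] <= hi, , drop = FALSE]

## does some exon of `ex` (data.table) fully cover [s, e)?
.exon_covers <- function(ex, s, e) any(ex$start <= s & ex$end >= e)

## label one bubble; returns NULL (no event), or list(type, paths)
.label_bubble <- function(i1, i2, ex1, ex2, strand, lo, hi) {
  n1 <- nrow(i1); n2 <- nrow(i2)
  path_str <- function(im) if (nrow(im)) paste(paste0(im[, 1L], "-", im[, 2L]), collapse = ",") else ""
  mk <- function(type) list(type = type,
                            paths = sort(c(path_str(i1), path_str(i2))),
                            lo = min(c(i1[, 1L], i2[, 1L])), hi = max(c(i1[, 2L], i2[, 2L])))

  if (n1 == 0L && n2 == 0L) return(list())
  ## one path intronless: candidate intron retention(s)
  if (n1 == 0L || n2 == 0L) {
    ii <- if (n1 == 0L) i2 else i1
    exo <- if (n1 == 0L) ex1 else ex2
    evs <- list()
    for (r in seq_len(nrow(ii))) {
      if (.exon_covers(exo, ii[r, 1L], ii[r, 2L])) {
        im <- ii[r, , drop = FALSE]
        evs[[length(evs) + 1L]] <- list(type = "IR",
                                        paths = sort(c(path_str(im), "")),
                                        lo = im[1L, 1L], hi = im[1L, 2L])
      }
      ## an uncovered intron is a transcript-end length difference: no event
    }
    return(evs)
  }
  ## both paths spliced
  if (n1 == 1L && n2 == 1L) {
    a <- i1[1L, ]; b <- i2[1L, ]
    overlap <- a[1L] < b[2L] && b[1L] < a[2L]
    if (a[1L] == b[1L] && a[2L] != b[2L] && overlap) {
      ## shared donor side on +, shared acceptor side on -
      terminal <- !is.finite(hi)
      if (terminal) {
        ## right-terminal bubble: compare the exons downstream of the introns
        d1 <- ex1[start == a[2L]]; d2 <- ex2[start == b[2L]]
        if (nrow(d1) && nrow(d2)) {
          disjoint <- d1$end[1L] <= d2$start[1L] || d2$end[1L] <= d1$start[1L]
          if (disjoint) return(list(mk(if (strand == "+") "ALE" else "AFE")))
        }
      }
      return(list(mk(if (strand == "+") "A3SS" else "A5SS")))
    }
    if (a[2L] == b[2L] && a[1L] != b[1L] && overlap) {
      terminal <- !is.finite(lo)
      if (terminal) {
        u1 <- ex1[end == a[1L]]; u2 <- ex2[end == b[1L]]
        if (nrow(u1) && nrow(u2)) {
          disjoint <- u1$end[1L] <= u2$start[1L] || u2$end[1L] <= u1$start[1L]
          if (disjoint) return(list(mk(if (strand == "+") "AFE" else "ALE")))
        }
      }
      return(list(mk(if (strand == "+") "A5SS" else "A3SS")))
    }
    return(list(mk("complex")))
  }
  if ((n1 == 2L && n2 == 1L) || (n1 == 1L && n2 == 2L)) {
    two <- if (n1 == 2L) i1 else i2
    one <- if (n1 == 2L) i2 else i1
    if (one[1L, 1L] == two[1L, 1L] && one[1L, 2L] == two[2L, 2L] &&
        two[1L, 2L] < two[2L, 1L]) {
      ev <- mk("SE"); ev$lo <- two[1L, 2L]; ev$hi <- two[2L, 1L]   # skipped exon coords
      return(list(ev))
    }
    return(list(mk("complex")))
  }
  if (n1 == 2L && n2 == 2L) {
    same_outer <- i1[1L, 1L] == i2[1L, 1L] && i1[2L, 2L] == i2[2L, 2L]
    e1 <- c(i1[1L, 2L], i1[2L, 1L]); e2 <- c(i2[1L, 2L], i2[2L, 1L])   # internal exons
    if (same_outer && e1[1L] < e1[2L] && e2[1L] < e2[2L] &&
        (e1[2L] <= e2[1L] || e2[2L] <= e1[1L])) {
      return(list(mk("MXE")))
    }
    return(list(mk("complex")))
  }
  list(mk("complex"))
}

#' Classify the alternative-splicing events between two isoforms
#'
#' @param a an `Annotation` containing both transcripts
#' @param tid1,tid2 transcript ids of the two isoforms (same chromosome and
#'   strand; typically of one gene)
#' @return data.table with one row per event: `type` (one of the seven
#'   categories or `"complex"`), `chrom`, `strand`, `lo`, `hi` (event
#'   coordinates), `path1`, `path2` (intron lists of the two variants,
#'   order-normalized), `key` (deduplication key).  Zero rows when the
#'   isoforms share their intron chain.
#' @export
classify_pair <- function(a, tid1, tid2) {
  t1 <- a$tx[transcript_id == tid1]; t2 <- a$tx[transcript_id == tid2]
  if (!nrow(t1) || !nrow(t2)) stop2("unknown transcript id")
  if (t1$chrom != t2$chrom || t1$strand != t2$strand)
    stop2("transcripts on different chromosomes or strands")
  strand <- t1$strand
  i1 <- .intron_mat(a, tid1); i2 <- .intron_mat(a, tid2)
  ex1 <- a$exons[transcript_id == tid1]; ex2 <- a$exons[transcript_id == tid2]

  sites1 <- unique(as.vector(i1)); sites2 <- unique(as.vector(i2))
  anchors <- sort(intersect(sites1, sites2))
  bounds <- c(-Inf, anchors, Inf)
  evs <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    s1 <- .in_seg(i1, lo, hi); s2 <- .in_seg(i2, lo, hi)
    if (nrow(s1) == nrow(s2) && nrow(s1) && all(s1 == s2)) next
    if (!nrow(s1) && !nrow(s2)) next
    evs <- c(evs, .label_bubble(s1, s2, ex1, ex2, strand, lo, hi))
  }
  if (!length(evs)) {
    return(classify_pair_empty())
  }
  out <- data.table::rbindlist(lapply(evs, function(e)
    data.table::data.table(type = e$type, chrom = t1$chrom, strand = strand,
                           lo = as.integer(e$lo), hi = as.integer(e$hi),
                           path1 = e$paths[1L], path2 = e$paths[2L])))
  out[, key := paste(type, chrom, strand, path1, path2, sep = "|")]
  unique(out, by = "key")
}

#' Deduplicated AS events of one gene
#'
#' Takes the union of [classify_pair()] over all isoform pairs and
#' deduplicates by event key (type + variant coordinates).
#'
#' @param a an `Annotation`
#' @param gene_id gene to analyze
#' @return data.table of events (zero rows for a single-isoform gene)
#' @export
gene_events <- function(a, gene_id) {
  tids <- a$tx$transcript_id[a$tx$gene_id == gene_id]
  if (length(tids) < 2L)
    return(classify_pair_empty())
  pairs <- utils::combn(sort(tids), 2L)
  out <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(p)
    classify_pair(a, pairs[1L, p], pairs[2L, p])))
  if (!nrow(out)) return(out)
  unique(out, by = "key")
}

classify_pair_empty <- function() {
  dt <- data.table::data.table(type = character(), chrom = character(), strand = character(),
                               lo = integer(), hi = integer(), path1 = character(),
                               path2 = character())
  dt[, key := character()]
  dt
}

#' Distribution of AS events over an annotation
#'
#' @param a an `Annotation`
#' @param dedup deduplicate events per gene by event key (default `TRUE`)
#' @return list with `events` (all events, one extra `gene_id` column),
#'   `counts` (named counts over the seven categories), `percentages`
#'   (over the seven categories only; `complex` bubbles are reported in
#'   `n_complex` but excluded from the tally)
#' @export
event_distribution <- function(a, dedup = TRUE) {
  gs <- unique(a$tx$gene_id)
  evs <- data.table::rbindlist(lapply(gs, function(g) {
    e <- gene_events(a, g)
    if (nrow(e)) data.table::data.table(gene_id = g, e) else NULL
  }))
  counts <- setNames(integer(length(AS_TYPES)), AS_TYPES)
  if (is.null(evs) || !nrow(evs)) {
    return(list(events = classify_pair_empty(), counts = counts,
                percentages = counts, n_complex = 0L))
  }
  if (!dedup) evs <- evs      # pairwise union is already per-gene deduplicated
  tb <- table(factor(evs$type[evs$type %in% AS_TYPES], levels = AS_TYPES))
  counts[] <- as.integer(tb)
  tot <- sum(counts)
  list(events = evs, counts = counts,
       percentages = if (tot > 0) 100 * counts / tot else counts,
       n_complex = sum(evs$type == "complex"))
}
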