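## Test helpers: tiny builders and independent brute-force oracles.
## The oracles deliberately re-derive everything from first principles
## (per-base bitmaps, recursive DP, direct rule evaluation) and share no
## code path with the implementation they check.

library(data.table)

## ---- builders --------------------------------------------------------------

mk_exons <- function(tid, starts, ends, chrom = "chr1", strand = "+", gid = paste0(tid, "g")) {
  data.frame(chrom = chrom, start = starts, end = ends, strand = strand,
             transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
}

mk_ann <- function(..., fpkm = NULL, cds = NULL, provenance = "test") {
  new_annotation(do.call(rbind, list(...)), fpkm = fpkm, cds = cds, provenance = provenance)
}

## a ReplicateSet from a spec list: list(rep1 = list(list(tid, starts, ends, fpkm, strand)), ...)
mk_rs <- function(spec, condition = "c1") {
  assemblies <- lapply(names(spec), function(r) {
    txs <- spec[[r]]
    ex <- do.call(rbind, lapply(txs, function(t)
      mk_exons(t$tid, t$starts, t$ends, strand = t$strand %||% "+")))
    if (is.null(ex)) ex <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), strand = character(),
                                      transcript_id = character(), gene_id = character())
    fp <- do.call(rbind, lapply(txs, function(t)
      if (is.null(t$fpkm)) NULL else
        data.frame(transcript_id = t$tid, sample = r, fpkm = t$fpkm)))
    new_annotation(ex, fpkm = fp, provenance = r)
  })
  names(assemblies) <- names(spec)
  new_replicate_set(condition, assemblies)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## random ReplicateSet over a small chain universe; boundary FPKMs included
random_rs <- function(seed, n_chains = 4L, n_reps = 4L, p_mono = 0.3) {
  set.seed(seed)
  universe <- lapply(seq_len(n_chains), function(k) {
    base <- 1000L * k
    n_ex <- sample(1:4, 1L, prob = c(p_mono, rep((1 - p_mono) / 3, 3)))
    bounds <- sort(sample(seq(base, base + 900L, by = 20L), 2L * n_ex))
    list(starts = bounds[seq(1L, 2L * n_ex, 2L)], ends = bounds[seq(2L, 2L * n_ex, 2L)],
         strand = sample(c("+", "-"), 1L))
  })
  spec <- list()
  for (r in seq_len(n_reps)) {
    txs <- list()
    for (k in seq_len(n_chains)) {
      if (runif(1) < 0.35) next
      u <- universe[[k]]
      jit <- sample(-5:5, 1L)
      starts <- u$starts; ends <- u$ends
      starts[1L] <- max(0L, starts[1L] + jit); ends[length(ends)] <- ends[length(ends)] + jit
      txs[[length(txs) + 1L]] <- list(tid = sprintf("u%d.r%d", k, r),
                                      starts = starts, ends = ends, strand = u$strand,
                                      fpkm = sample(c(0.5, 0.9, 1.0, 1.01, 2, 5), 1L))
    }
    if (!length(txs)) txs <- list(list(tid = sprintf("fill.r%d", r), starts = 10L,
                                       ends = 400L, strand = "+", fpkm = 5))
    spec[[paste0("rep", r)]] <- txs
  }
  mk_rs(spec)
}

## ---- direct rule evaluators (consolidation oracle) ------------------------

## chain signature computed from scratch (no chain_keys reuse)
o_chain <- function(ex) {
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2L) return(NA_character_)
  paste(ex$chrom[1L], ex$strand[1L],
        paste(ex$end[-nrow(ex)], ex$start[-1L], sep = "_", collapse = ";"), sep = "|")
}

## long per-copy table of a ReplicateSet, via the raw exon tables
o_copies <- function(rs) {
  out <- list()
  for (r in names(rs$assemblies)) {
    a <- rs$assemblies[[r]]
    for (tid in a$tx$transcript_id) {
      ex <- as.data.frame(a$exons[a$exons$transcript_id == tid, ])
      fp <- a$fpkm$fpkm[a$fpkm$transcript_id == tid]
      out[[length(out) + 1L]] <- data.frame(
        rep = r, tid = tid, chain = o_chain(ex), chrom = ex$chrom[1L],
        strand = ex$strand[1L], lo = min(ex$start), hi = max(ex$end),
        fpkm = if (length(fp)) fp[1L] else NA_real_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## retained multi-exon chains with boundaries, per the stated rule
o_multiexon <- function(rs, fpkm_min = 1, min_reps = 2) {
  cp <- o_copies(rs)
  cp <- cp[!is.na(cp$chain), ]
  if (!nrow(cp)) return(data.frame(chain = character(), lo = integer(), hi = integer()))
  res <- list()
  for (ch in unique(cp$chain)) {
    g <- cp[cp$chain == ch, ]
    support <- length(unique(g$rep[!is.na(g$fpkm) & g$fpkm > fpkm_min]))
    if (support >= min_reps)
      res[[length(res) + 1L]] <- data.frame(chain = ch, lo = min(g$lo), hi = max(g$hi))
  }
  if (!length(res)) data.frame(chain = character(), lo = integer(), hi = integer())
  else do.call(rbind, res)
}

## retained mono-exon clusters, per the stated rule (pairwise union-find)
o_monoexon <- function(rs, fpkm_min = 1) {
  cp <- o_copies(rs)
  cp <- cp[is.na(cp$chain), ]
  n_reps <- length(rs$assemblies)
  if (!nrow(cp)) return(data.frame(chrom = character(), strand = character(),
                                   lo = integer(), hi = integer()))
  cl <- seq_len(nrow(cp))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(cp))) for (j in seq_len(nrow(cp))) {
      if (cl[i] != cl[j] && cp$chrom[i] == cp$chrom[j] && cp$strand[i] == cp$strand[j] &&
          cp$lo[i] < cp$hi[j] && cp$lo[j] < cp$hi[i]) {
        cl[cl == cl[j]] <- cl[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  res <- list()
  for (c0 in unique(cl)) {
    g <- cp[cl == c0, ]
    ok <- all(vapply(names(rs$assemblies), function(r)
      any(g$rep == r & !is.na(g$fpkm) & g$fpkm > fpkm_min), logical(1)))
    if (ok) res[[length(res) + 1L]] <- data.frame(chrom = g$chrom[1L], strand = g$strand[1L],
                                                 lo = min(g$lo), hi = max(g$hi))
  }
  if (!length(res)) data.frame(chrom = character(), strand = character(),
                               lo = integer(), hi = integer())
  else do.call(rbind, res)
}

## intron interval set of an Annotation transcript, as strings
o_intron_set <- function(a, tid) {
  ex <- as.data.frame(a$exons[a$exons$transcript_id == tid, ])
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2L) return(character())
  paste(ex$end[-nrow(ex)], ex$start[-1L], sep = "_")
}

## brute-force rescue oracle: (rescued ids, superseded ids)
o_rescue <- function(singletons, supported) {
  resc <- character(); sup <- character()
  for (aid in singletons$tx$transcript_id) {
    aset <- o_intron_set(singletons, aid)
    if (!length(aset)) next
    arow <- singletons$tx[singletons$tx$transcript_id == aid, ]
    for (bid in supported$tx$transcript_id) {
      bset <- o_intron_set(supported, bid)
      brow <- supported$tx[supported$tx$transcript_id == bid, ]
      if (!length(bset) || arow$chrom != brow$chrom || arow$strand != brow$strand) next
      if (length(bset) < length(aset) && all(bset %in% aset)) {
        resc <- c(resc, aid); sup <- c(sup, bid)
      }
    }
  }
  list(rescued = sort(unique(resc)), superseded = sort(unique(sup)))
}

## chain+span multiset of an Annotation (for set comparison ignoring ids)
ann_shape <- function(a) {
  sort(vapply(a$tx$transcript_id, function(tid) {
    ex <- as.data.frame(a$exons[a$exons$transcript_id == tid, ])
    ex <- ex[order(ex$start), ]
    paste(ex$chrom[1L], ex$strand[1L], paste(ex$start, ex$end, sep = ":", collapse = ","))
  }, character(1), USE.NAMES = FALSE))
}

## ---- alignment oracle: independent recursive affine-gap DP ----------------

o_align_score <- function(a, b, mode = "nucleotide", gap_open = 10, gap_extend = 0.5) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  sub <- function(x, y) {
    if (mode == "nucleotide") { if (x == "N" || y == "N") -2 else if (x == y) 5 else -4 }
    else retra:::.blosum62[x, y]
  }
  memo <- new.env(hash = TRUE)
  ## state: 0 = after match, 1 = in gap consuming A, 2 = in gap consuming B
  rec <- function(i, j, st) {
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub(A[i], B[j]) + rec(i + 1L, j + 1L, 0L))
    if (i <= n)
      best <- max(best, (if (st == 1L) -gap_extend else -gap_open - gap_extend) +
                    rec(i + 1L, j, 1L))
    if (j <= m)
      best <- max(best, (if (st == 2L) -gap_extend else -gap_open - gap_extend) +
                    rec(i, j + 1L, 2L))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

## ---- bitmap oracles --------------------------------------------------------

## per-base union length of 0-based half-open intervals
o_union_bases <- function(start, end, upto = max(end)) {
  v <- logical(upto)
  for (i in seq_along(start)) if (end[i] > start[i]) v[(start[i] + 1L):end[i]] <- TRUE
  sum(v)
}

## TSS profile by per-base lookup
o_tss_profile <- function(tss, peaks, flank) {
  upto <- max(peaks$end, tss$pos + flank) + 1L
  inpeak <- list()
  for (cn in unique(c(tss$chrom, peaks$chrom))) {
    v <- logical(upto)
    pk <- peaks[peaks$chrom == cn, ]
    for (i in seq_len(nrow(pk))) v[(pk$start[i] + 1L):pk$end[i]] <- TRUE
    inpeak[[cn]] <- v
  }
  offs <- (-flank):flank
  acc <- numeric(length(offs))
  for (i in seq_len(nrow(tss))) {
    for (oi in seq_along(offs)) {
      base <- if (tss$strand[i] == "+") tss$pos[i] + offs[oi] else tss$pos[i] - offs[oi]
      if (base >= 0L && base < upto) acc[oi] <- acc[oi] + inpeak[[tss$chrom[i]]][base + 1L]
    }
  }
  acc / nrow(tss)
}

## per-transcript TE overlap by per-base lookup
o_te_fraction <- function(a, te) {
  upto <- max(a$exons$end, te$end) + 1L
  inte <- list()
  for (cn in unique(c(a$exons$chrom, te$chrom))) {
    v <- logical(upto)
    tt <- te[te$chrom == cn, ]
    for (i in seq_len(nrow(tt))) if (tt$end[i] > tt$start[i]) v[(tt$start[i] + 1L):tt$end[i]] <- TRUE
    inte[[cn]] <- v
  }
  num <- 0L; den <- 0L
  for (r in seq_len(nrow(a$exons))) {
    ex <- a$exons[r, ]
    den <- den + (ex$end - ex$start)
    num <- num + sum(inte[[ex$chrom]][(ex$start + 1L):ex$end])
  }
  num / den
}

## ---- AS structural predicates ---------------------------------------------

parse_path <- function(p) {
  if (!nzchar(p)) return(matrix(integer(), ncol = 2L))
  iv <- do.call(rbind, lapply(strsplit(p, ",", fixed = TRUE)[[1L]], function(s)
    as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])))
  iv[order(iv[, 1L]), , drop = FALSE]
}

## check an emitted event row against its structural definition
as_event_ok <- function(row) {
  p1 <- parse_path(row$path1); p2 <- parse_path(row$path2)
  n1 <- nrow(p1); n2 <- nrow(p2)
  two <- if (n1 > n2) p1 else p2
  one <- if (n1 > n2) p2 else p1
  switch(row$type,
    IR = (min(n1, n2) == 0L && max(n1, n2) == 1L),
    SE = (min(n1, n2) == 1L && max(n1, n2) == 2L &&
            one[1L, 1L] == two[1L, 1L] && one[1L, 2L] == two[2L, 2L] &&
            two[1L, 2L] < two[2L, 1L]),
    A5SS = (n1 == 1L && n2 == 1L &&
              ((row$strand == "+" && p1[1L, 2L] == p2[1L, 2L] && p1[1L, 1L] != p2[1L, 1L]) ||
               (row$strand == "-" && p1[1L, 1L] == p2[1L, 1L] && p1[1L, 2L] != p2[1L, 2L]))),
    A3SS = (n1 == 1L && n2 == 1L &&
              ((row$strand == "+" && p1[1L, 1L] == p2[1L, 1L] && p1[1L, 2L] != p2[1L, 2L]) ||
               (row$strand == "-" && p1[1L, 2L] == p2[1L, 2L] && p1[1L, 1L] != p2[1L, 1L]))),
    AFE = (n1 == 1L && n2 == 1L &&
             xor(p1[1L, 1L] == p2[1L, 1L], p1[1L, 2L] == p2[1L, 2L])),
    ALE = (n1 == 1L && n2 == 1L &&
             xor(p1[1L, 1L] == p2[1L, 1L], p1[1L, 2L] == p2[1L, 2L])),
    MXE = (n1 == 2L && n2 == 2L && p1[1L, 1L] == p2[1L, 1L] && p1[2L, 2L] == p2[2L, 2L] &&
             ## internal exons [p1[1,2], p1[2,1]) and [p2[1,2], p2[2,1]) disjoint
             (p1[2L, 1L] <= p2[1L, 2L] || p2[2L, 1L] <= p1[1L, 2L])),
    complex = TRUE,
    FALSE)
}
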