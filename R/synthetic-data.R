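## Deterministic, seeded generators for every input the toolkit consumes,
## with planted ground truth: genome, annotation (with planted splice
## signatures, ORFs/CDS, polyA signals and AS events), per-replicate
## assemblies, expression matrices, homolog junction contexts, peaks,
## repeats and coding-evidence tables.
##
## The master seed fans out into per-component child seeds (child_seed) so
## individual fixtures are stable under unrelated configuration changes.

TE_FAMILIES <- c("LINE/L1", "LINE/L2", "SINE/Alu", "SINE/B2", "SINE/MIR", "LTR/ERVL-MaLR")
NON_TE_CLASSES <- c("Simple_repeat", "Low_complexity", "Satellite")

## sample() guards against R's scalar surprise (sample(4) == sample(1:4))
.rint <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}
.shuffle <- function(x) if (length(x) <= 1L) x else sample(x)

#' Generate a random genome
#'
#' Uniform base composition, deterministic by seed.
#'
#' @param seed RNG seed
#' @param n_chroms number of chromosomes
#' @param chrom_len chromosome length in bases (>= 10000; recycled)
#' @return named character vector (`chr1`, `chr2`, ...)
#' @export
make_genome <- function(seed, n_chroms = 2L, chrom_len = 50000L) {
  chrom_len <- rep_len(as.integer(chrom_len), n_chroms)
  if (any(chrom_len < 10000L)) stop2("chromosome lengths must be >= 10 kb")
  set.seed(seed)
  g <- vapply(chrom_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), character(1))
  setNames(g, paste0("chr", seq_len(n_chroms)))
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

## transcript-position -> genomic-position map (0-based), transcript orientation
.tx_gpos <- function(exons, strand) {
  g <- unlist(lapply(seq_len(nrow(exons)), function(i) exons$start[i]:(exons$end[i] - 1L)))
  if (strand == "-") rev(g) else g
}

## write `s` (transcript orientation) into the char-vector genome at
## transcript positions tx_from..(tx_from + nchar(s) - 1)
.plant_tx <- function(gchar, chrom, gpos, strand, tx_from, s) {
  bases <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  idx <- gpos[(tx_from + 1L):(tx_from + length(bases))] + 1L
  gchar[[chrom]][idx] <- bases
  gchar
}

## genomic segments (and GTF phases) of the CDS spanning transcript
## positions [cds_from, cds_to) on the given exon structure
.cds_segments <- function(exons, strand, gpos, cds_from, cds_to) {
  g <- gpos[(cds_from + 1L):cds_to]
  if (strand == "-") g <- rev(g)                # ascending genomic order
  brk <- c(0L, which(diff(g) != 1L), length(g))
  segs <- data.table::data.table(start = g[brk[-length(brk)] + 1L], end = g[brk[-1L]] + 1L)
  ## phases in transcript order
  segs_tx <- if (strand == "-") segs[rev(seq_len(nrow(segs)))] else segs
  cum <- cumsum(c(0L, (segs_tx$end - segs_tx$start)[-nrow(segs_tx)]))
  segs_tx[, phase := (3L - cum %% 3L) %% 3L]
  segs_tx
}

## one AS variant of a base exon structure; returns exon table or NULL
.apply_event <- function(exons, type, j, strand, lead_lo, trail_hi, shift = 18L,
                         alt_len = 60L, alt_gap = 30L) {
  ex <- data.table::copy(exons)
  n <- nrow(ex)
  switch(type,
    SE = if (j >= 2L && j <= n - 1L) ex[-j] else NULL,
    IR = if (j <= n - 1L) {
      ex$end[j] <- ex$end[j + 1L]; ex[-(j + 1L)]
    } else NULL,
    A5SS = if (j <= n - 1L) {
      if (strand == "+") { ex$end[j] <- ex$end[j] - shift }
      else { ex$start[j + 1L] <- ex$start[j + 1L] + shift }
      ex
    } else NULL,
    A3SS = if (j <= n - 1L) {
      if (strand == "+") { ex$start[j + 1L] <- ex$start[j + 1L] + shift }
      else { ex$end[j] <- ex$end[j] - shift }
      ex
    } else NULL,
    MXE = if (j >= 2L && j <= n - 1L &&
              ex$start[j + 1L] - ex$end[j] >= alt_len + 2L * alt_gap) {
      ex$start[j] <- ex$end[j] + alt_gap
      ex$end[j] <- ex$start[j] + alt_len
      ex
    } else NULL,
    AFE = {  # alternative transcript-first exon
      if (n < 2L) return(NULL)
      if (strand == "+") {
        alt_end <- lead_lo + alt_len
        if (alt_end + alt_gap > ex$start[1L]) return(NULL)
        ex$start[1L] <- lead_lo; ex$end[1L] <- alt_end; ex
      } else {
        alt_start <- trail_hi - alt_len
        if (ex$end[n] + alt_gap > alt_start) return(NULL)
        ex$start[n] <- alt_start; ex$end[n] <- trail_hi; ex
      }
    },
    ALE = {  # alternative transcript-last exon
      if (n < 2L) return(NULL)
      if (strand == "+") {
        alt_start <- trail_hi - alt_len
        if (ex$end[n] + alt_gap > alt_start) return(NULL)
        ex$start[n] <- alt_start; ex$end[n] <- trail_hi; ex
      } else {
        alt_end <- lead_lo + alt_len
        if (alt_end + alt_gap > ex$start[1L]) return(NULL)
        ex$start[1L] <- lead_lo; ex$end[1L] <- alt_end; ex
      }
    },
    NULL)
}

## intron slots an event occupies (for anchor separation between events)
.event_slots <- function(type, j, n, strand) {
  switch(type,
    SE = c(j - 1L, j), MXE = c(j - 1L, j),
    IR = j, A5SS = j, A3SS = j,
    AFE = if (strand == "+") 1L else n - 1L,
    ALE = if (strand == "+") n - 1L else 1L)
}

#' Generate a truth annotation on a genome
#'
#' Genes are laid out without overlap; each gene gets 1..k isoforms where
#' every extra isoform differs from the base isoform by exactly one planted
#' AS event (SE, IR, A5SS, A3SS, MXE, AFE or ALE) at a position chosen so
#' that events of one gene occupy separated intron slots.  The requested
#' fraction of splice junctions is written with the canonical GT..AG
#' dinucleotides (the rest GC..AG); coding genes carry a planted ORF
#' (>= 100 codons) with CDS records on the base isoform; a polyA hexamer is
#' planted upstream of each distinct TTS with the configured probability.
#' The genome is edited in place and returned alongside the annotation.
#'
#' @param genome named character vector from [make_genome()]
#' @param seed RNG seed
#' @param n_genes number of genes to place
#' @param isoform_dist probabilities of 1, 2, ..., k isoforms per gene
#' @param gtag_fraction fraction of junctions written GT..AG (default 0.97)
#' @param coding_fraction fraction of multi-exon genes made coding
#' @param mono_fraction fraction of genes made mono-exon
#' @param n_exons_range,exon_len_range,intron_len_range structure ranges of
#'   the base isoform
#' @param polya_prob probability of planting a polyA hexamer per distinct
#'   TTS
#' @param polya_offset_range offset range (relative to the TTS, negative)
#'   of the planted hexamer start
#' @param event_types AS event types available to the isoform generator
#' @return list of class `SyntheticTruth` with `genome` (edited),
#'   `annotation`, `labels` (`transcript_id`, `label`), `events` (planted
#'   events: `gene_id`, `transcript_id`, `type`), `signatures` (`n_gt`,
#'   `n_junctions`, `fraction`), `polya` (planted hexamer offsets),
#'   `free_from` (per-chrom first unused coordinate), `seed`
#' @export
make_annotation <- function(genome, seed, n_genes = 40L,
                            isoform_dist = c(0.55, 0.3, 0.15),
                            gtag_fraction = 0.97, coding_fraction = 0.5,
                            mono_fraction = 0.1,
                            n_exons_range = c(3L, 6L),
                            exon_len_range = c(120L, 300L),
                            intron_len_range = c(200L, 500L),
                            polya_prob = 0.9, polya_offset_range = c(-40L, -10L),
                            event_types = AS_TYPES) {
  set.seed(child_seed(seed, 1L))
  gchar <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  chroms <- names(genome)
  cursor <- setNames(rep(200L, length(chroms)), chroms)
  lead <- 100L; trail <- 100L; intergenic <- 300L

  exon_rows <- list(); cds_rows <- list(); labels <- list(); events <- list()
  polya_rows <- list()

  for (gi in seq_len(n_genes)) {
    gene_id <- sprintf("SYNG%03d", gi)
    chrom <- chroms[(gi - 1L) %% length(chroms) + 1L]
    strand <- sample(c("+", "-"), 1L)
    mono <- runif(1) < mono_fraction
    if (mono) {
      len <- .rint(220L, 400L)
      n_ex <- 1L
      ex_lens <- len
      in_lens <- integer()
    } else {
      n_ex <- .rint(n_exons_range[1L], n_exons_range[2L])
      ex_lens <- .rint(exon_len_range[1L], exon_len_range[2L], n_ex)
      in_lens <- .rint(intron_len_range[1L], intron_len_range[2L], max(0L, n_ex - 1L))
    }
    coding <- !mono && runif(1) < coding_fraction
    if (coding) while (sum(ex_lens) < 480L) ex_lens[which.max(ex_lens)] <- ex_lens[which.max(ex_lens)] + 100L

    span <- sum(ex_lens) + sum(in_lens)
    lead_lo <- cursor[[chrom]]
    gstart <- lead_lo + lead
    trail_hi <- gstart + span + trail
    if (trail_hi + intergenic > nchar(genome[[chrom]])) {
      cand <- chroms[vapply(chroms, function(cn)
        cursor[[cn]] + lead + span + trail + intergenic <= nchar(genome[[cn]]), logical(1))]
      if (!length(cand)) stop2("infeasible packing: %d genes do not fit on the genome", n_genes)
      chrom <- cand[1L]
      lead_lo <- cursor[[chrom]]; gstart <- lead_lo + lead; trail_hi <- gstart + span + trail
    }
    cursor[[chrom]] <- trail_hi + intergenic

    starts <- gstart + cumsum(c(0L, head(ex_lens, -1L) + in_lens))
    base_ex <- data.table::data.table(start = starts, end = starts + ex_lens)

    ## isoform count and planted events
    k <- sample.int(length(isoform_dist), 1L, prob = isoform_dist)
    if (mono || n_ex < 2L) k <- 1L
    iso_exons <- list(base_ex)
    blocked <- integer()
    if (k > 1L) {
      for (extra in seq_len(k - 1L)) {
        placed <- FALSE
        for (type in .shuffle(event_types)) {
          n_intr <- n_ex - 1L
          js <- switch(type,
                       SE = , MXE = if (n_ex >= 3L) 2:(n_ex - 1L) else integer(),
                       IR = , A5SS = , A3SS = seq_len(n_intr),
                       AFE = , ALE = 1L)
          js <- .shuffle(js)
          for (j in js) {
            slots <- .event_slots(type, j, n_ex, strand)
            if (any(c(slots - 1L, slots, slots + 1L) %in% blocked)) next
            ex2 <- .apply_event(base_ex, type, j, strand, lead_lo, trail_hi)
            if (is.null(ex2)) next
            iso_exons[[length(iso_exons) + 1L]] <- ex2
            blocked <- c(blocked, slots)
            events[[length(events) + 1L]] <- data.table::data.table(
              gene_id = gene_id, transcript_id = sprintf("%s.%d", gene_id, length(iso_exons)),
              type = type, j = j)
            placed <- TRUE
            break
          }
          if (placed) break
        }
        if (!placed) break
      }
    }

    for (ii in seq_along(iso_exons)) {
      tid <- sprintf("%s.%d", gene_id, ii)
      exi <- iso_exons[[ii]]
      exon_rows[[length(exon_rows) + 1L]] <- data.table::data.table(
        chrom = chrom, start = exi$start, end = exi$end, strand = strand,
        transcript_id = tid, gene_id = gene_id)
      labels[[length(labels) + 1L]] <- data.table::data.table(
        transcript_id = tid, gene_id = gene_id,
        label = if (coding && ii == 1L) "coding" else "noncoding")
    }

    ## plant the ORF + CDS on the base isoform of coding genes
    if (coding) {
      gpos <- .tx_gpos(base_ex, strand)
      L <- length(gpos)
      n_cod <- min(120L, (L - 30L - 130L - 3L) %/% 3L)
      if (n_cod >= 100L) {
        orf <- paste0("ATG", paste(sample(NON_STOP_CODONS, n_cod - 1L, replace = TRUE),
                                   collapse = ""), "TAA")
        gchar <- .plant_tx(gchar, chrom, gpos, strand, 30L, orf)
        segs <- .cds_segments(base_ex, strand, gpos, 30L, 30L + nchar(orf))
        cds_rows[[length(cds_rows) + 1L]] <- data.table::data.table(
          transcript_id = sprintf("%s.1", gene_id), chrom = chrom,
          start = segs$start, end = segs$end, strand = strand, phase = segs$phase)
      }
    }
  }

  ex_all <- data.table::rbindlist(exon_rows)
  cds_all <- if (length(cds_rows)) data.table::rbindlist(cds_rows) else NULL
  ann <- new_annotation(ex_all, cds = cds_all, source = "assembly", provenance = "truth")

  ## ---- plant splice dinucleotides (per unique donor site) ------------------
  intr <- unique(introns_of(ann)[, .(chrom, strand, start, end)])
  n_jn <- nrow(intr)
  n_gt <- 0L
  if (n_jn) {
    donors <- unique(intr[, .(chrom, strand,
                              dpos = ifelse(strand == "+", start, end))])
    donors[, djn := 0L]
    for (i in seq_len(nrow(donors))) {
      donors$djn[i] <- intr[chrom == donors$chrom[i] & strand == donors$strand[i] &
                              (ifelse(strand == "+", start, end)) == donors$dpos[i], .N]
    }
    target_gc <- n_jn - round(gtag_fraction * n_jn)
    ord <- sample(nrow(donors))
    gc_sites <- integer(); gc_total <- 0L
    for (i in ord) {
      if (gc_total + donors$djn[i] <= target_gc) {
        gc_sites <- c(gc_sites, i); gc_total <- gc_total + donors$djn[i]
        if (gc_total == target_gc) break
      }
    }
    donors[, donor_dinuc := "GT"]; donors$donor_dinuc[gc_sites] <- "GC"
    for (i in seq_len(nrow(donors))) {
      cn <- donors$chrom[i]; dd <- donors$donor_dinuc[i]
      if (donors$strand[i] == "+") {
        gchar[[cn]][(donors$dpos[i] + 1L):(donors$dpos[i] + 2L)] <- strsplit(dd, "")[[1L]]
      } else {
        rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(dd, "")[[1L]]), collapse = ""))
        gchar[[cn]][(donors$dpos[i] - 1L):donors$dpos[i]] <- strsplit(rc, "")[[1L]]
      }
    }
    for (i in seq_len(nrow(intr))) {   # acceptors always AG
      cn <- intr$chrom[i]
      if (intr$strand[i] == "+") {
        gchar[[cn]][(intr$end[i] - 1L):intr$end[i]] <- c("A", "G")
      } else {
        gchar[[cn]][(intr$start[i] + 1L):(intr$start[i] + 2L)] <- c("C", "T")
      }
    }
    ## realized GT-AG junction count
    dmap <- setNames(donors$donor_dinuc,
                     paste(donors$chrom, donors$strand, donors$dpos))
    jd <- dmap[paste(intr$chrom, intr$strand, ifelse(intr$strand == "+", intr$start, intr$end))]
    n_gt <- sum(jd == "GT")
  }

  ## ---- plant polyA hexamers per distinct TTS -------------------------------
  tts <- unique(.tts_table(ann)[, .(chrom, strand, pos)])
  for (i in seq_len(nrow(tts))) {
    if (runif(1) >= polya_prob) next
    off <- if (polya_offset_range[1L] == polya_offset_range[2L]) polya_offset_range[1L]
           else .rint(polya_offset_range[1L], polya_offset_range[2L])
    cn <- tts$chrom[i]; p <- tts$pos[i]
    if (tts$strand[i] == "+") {
      gchar[[cn]][(p + off + 1L):(p + off + 6L)] <- strsplit("AATAAA", "")[[1L]]
    } else {
      gchar[[cn]][(p - off - 5L + 1L):(p - off + 1L)] <- strsplit("TTTATT", "")[[1L]]
    }
    polya_rows[[length(polya_rows) + 1L]] <- data.table::data.table(
      chrom = cn, strand = tts$strand[i], tts = p, offset = off)
  }

  genome_out <- setNames(vapply(gchar, paste, character(1), collapse = ""), names(gchar))
  structure(list(genome = genome_out, annotation = ann,
                 labels = data.table::rbindlist(labels),
                 events = if (length(events)) data.table::rbindlist(events)
                          else data.table::data.table(gene_id = character(), transcript_id = character(),
                                                      type = character(), j = integer()),
                 signatures = list(n_gt = n_gt, n_junctions = n_jn,
                                   fraction = if (n_jn) n_gt / n_jn else NA_real_),
                 polya = if (length(polya_rows)) data.table::rbindlist(polya_rows)
                         else data.table::data.table(chrom = character(), strand = character(),
                                                     tts = integer(), offset = integer()),
                 free_from = cursor, seed = seed),
            class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d transcripts / %d genes, %d junctions (%.1f%% GT-AG), %d planted AS events\n",
              nrow(x$annotation$tx), data.table::uniqueN(x$annotation$tx$gene_id),
              x$signatures$n_junctions, 100 * (x$signatures$fraction %||% NA),
              nrow(x$events)))
  invisible(x)
}

#' Generate per-replicate assemblies from a truth annotation
#'
#' Each replicate contains the truth transcripts minus random dropouts,
#' with FPKM drawn from a log-normal law and transcript end coordinates
#' jittered (intron chains untouched).  Planted violations inject the
#' canonical consolidation edge cases in reserved genomic space:
#' a sub-threshold transcript (FPKM 0.8 in all replicates), a mono-exon
#' transcript present in only 3 of 4 replicates, a single-replicate orphan,
#' and a superchain pair (a 2-replicate supported transcript whose introns
#' are a proper subset of a 1-replicate transcript with more exons).
#'
#' @param truth a `SyntheticTruth`
#' @param seed RNG seed
#' @param n_reps number of biological replicates (default 4)
#' @param dropout per-transcript per-replicate dropout probability
#' @param fpkm_meanlog,fpkm_sdlog log-normal FPKM parameters
#' @param end_jitter maximum absolute jitter of transcript end coordinates
#' @param planted_violations inject the edge cases (default `FALSE`)
#' @param condition condition label
#' @return list with `rs` (a `ReplicateSet`) and `violations` (data.table
#'   `case`, `transcript_id`, `expected` verdict)
#' @export
make_replicate_assemblies <- function(truth, seed, n_reps = 4L, dropout = 0.1,
                                      fpkm_meanlog = 1, fpkm_sdlog = 0.8,
                                      end_jitter = 10L, planted_violations = FALSE,
                                      condition = "cond1") {
  set.seed(child_seed(seed, 2L))
  ann <- truth$annotation
  reps <- paste0("rep", seq_len(n_reps))
  viol <- list()

  ## reserved space for violation constructs
  vspace <- NULL
  if (isTRUE(planted_violations)) {
    cn <- names(truth$free_from)[1L]
    base <- truth$free_from[[cn]] + 200L
    if (base + 4000L > nchar(truth$genome[[cn]])) stop2("no reserved space for planted violations")
    mk_tx <- function(tid, starts, lens) data.table::data.table(
      chrom = cn, start = starts, end = starts + lens, strand = "+",
      transcript_id = tid, gene_id = paste0(tid, "g"))
    vspace <- list(
      sub = mk_tx("VIOL.sub", base + c(0L, 400L), c(250L, 250L)),
      mono3 = mk_tx("VIOL.mono3", base + 1000L, 300L),
      orphan = mk_tx("VIOL.orphan", base + 1500L, 260L) ,
      chainB = mk_tx("VIOL.chainB", base + 2000L + c(0L, 400L, 800L), c(250L, 250L, 250L)),
      chainA = mk_tx("VIOL.chainA", base + 2000L + c(-300L, 0L, 400L, 800L), c(220L, 250L, 250L, 250L)))
    ## orphan must be multi-exon with no superchain relation
    vspace$orphan <- mk_tx("VIOL.orphan", base + 1500L + c(0L, 300L), c(120L, 140L))
    viol <- list(
      data.table::data.table(case = "sub_threshold", transcript_id = "VIOL.sub", expected = "dropped"),
      data.table::data.table(case = "mono_3of4", transcript_id = "VIOL.mono3", expected = "dropped"),
      data.table::data.table(case = "orphan", transcript_id = "VIOL.orphan", expected = "dropped"),
      data.table::data.table(case = "superchain_sub", transcript_id = "VIOL.chainB", expected = "dropped_superseded"),
      data.table::data.table(case = "superchain_super", transcript_id = "VIOL.chainA", expected = "rescued"))
  }

  assemblies <- list()
  for (r in seq_len(n_reps)) {
    keep <- ann$tx$transcript_id[runif(nrow(ann$tx)) >= dropout]
    ex <- data.table::copy(ann$exons[transcript_id %in% keep])
    if (end_jitter > 0L && nrow(ex)) {
      ex[, first := seq_len(.N) == 1L, by = transcript_id]
      ex[, last := seq_len(.N) == .N, by = transcript_id]
      jit <- function(n) sample((-end_jitter):end_jitter, n, replace = TRUE)
      ex[first == TRUE, start := pmax(0L, pmin(start + jit(.N), end - 20L))]
      ex[last == TRUE, end := pmax(start + 20L, end + jit(.N))]
      ex[, c("first", "last") := NULL]
    }
    fpkm_v <- stats::rlnorm(length(keep), fpkm_meanlog, fpkm_sdlog)
    fp <- data.table::data.table(transcript_id = keep, sample = reps[r], fpkm = fpkm_v)
    if (!is.null(vspace)) {
      add <- list()
      addfp <- list()
      put <- function(tab, f) {
        add[[length(add) + 1L]] <<- tab
        addfp[[length(addfp) + 1L]] <<- data.table::data.table(
          transcript_id = tab$transcript_id[1L], sample = reps[r], fpkm = f)
      }
      put(vspace$sub, 0.8)                          # all reps, FPKM below threshold
      if (r <= 3L) put(vspace$mono3, 5)             # mono-exon, 3 of 4 reps
      if (r == 1L) put(vspace$orphan, 5)            # single-replicate orphan
      if (r <= 2L) put(vspace$chainB, 5)            # supported sub-chain
      if (r == 3L) put(vspace$chainA, 5)            # superchain in one replicate
      ex <- data.table::rbindlist(c(list(ex), add))
      fp <- data.table::rbindlist(c(list(fp), addfp))
    }
    assemblies[[reps[r]]] <- new_annotation(ex, fpkm = fp, provenance = reps[r])
  }
  list(rs = new_replicate_set(condition, assemblies),
       violations = if (length(viol)) data.table::rbindlist(viol)
                    else data.table::data.table(case = character(), transcript_id = character(),
                                                expected = character()))
}

#' Generate an expression matrix with planted patterns
#'
#' Housekeeping features are expressed (all samples well above threshold)
#' in every condition; tissue-specific features only in their tissue;
#' remaining features in a random subset of tissues (all stages).
#' Non-expressed cells stay strictly below the threshold in every sample.
#' Planted dominant-isoform switches make one isoform dominant in the first
#' half of the tissue panel and a sibling isoform dominant in the rest.
#'
#' @param a an `Annotation` supplying transcript/gene ids
#' @param seed RNG seed
#' @param tissues,stages,sexes,reps design (defaults: the 11-tissue rat
#'   panel, 4 stages, both sexes, 2 replicates)
#' @param hk_fraction fraction of genes made housekeeping
#' @param specific_fraction fraction of genes made single-tissue specific
#' @param switch_fraction fraction of eligible housekeeping multi-isoform
#'   genes given a dominant-isoform switch
#' @param fpkm_min expression threshold the plants are built around
#' @return list with `matrix` (transcript-level `ExpressionMatrix`),
#'   `planted_hk_tx`, `planted_hk_genes`, `planted_specific` (data.table
#'   `gene_id`, `tissue`), `planted_switches` (gene ids)
#' @export
make_expression_matrix <- function(a, seed,
                                   tissues = c("Ad", "Br", "He", "Ki", "Lu", "Li",
                                               "Mu", "Sp", "Th", "Te", "Ut"),
                                   stages = c("2w", "6w", "21w", "104w"),
                                   sexes = c("M", "F"), reps = 2L,
                                   hk_fraction = 0.3, specific_fraction = 0.2,
                                   switch_fraction = 0.5, fpkm_min = 0.5) {
  set.seed(child_seed(seed, 3L))
  meta <- data.table::CJ(tissue = tissues, stage = stages, sex = sexes,
                         replicate = seq_len(reps))
  meta[, sample := sprintf("%s_%s_%s_r%d", tissue, stage, sex, replicate)]
  gids <- unique(a$tx$gene_id)
  t2g <- setNames(a$tx$gene_id, a$tx$transcript_id)
  n_g <- length(gids)
  cls <- sample(c("hk", "specific", "mixed"), n_g, replace = TRUE,
                prob = c(hk_fraction, specific_fraction, 1 - hk_fraction - specific_fraction))
  names(cls) <- gids
  spec_tissue <- setNames(sample(tissues, n_g, replace = TRUE), gids)
  mixed_sets <- lapply(gids, function(g) sort(sample(tissues, sample(2:(length(tissues) - 1L), 1L))))
  names(mixed_sets) <- gids

  hk_genes <- gids[cls == "hk"]
  multi <- names(which(table(t2g) >= 2L))
  eligible <- intersect(hk_genes, multi)
  switches <- sort(sample(eligible, round(switch_fraction * length(eligible))))
  half1 <- tissues[seq_len(ceiling(length(tissues) / 2))]

  feats <- sort(names(t2g))
  vals <- matrix(0, length(feats), nrow(meta), dimnames = list(feats, meta$sample))
  lo <- function(n) runif(n, 0, 0.45)                       # never expressed
  hi <- function(n) pmax(0.8, stats::rlnorm(n, 1, 0.5))     # always expressed
  for (f in feats) {
    g <- t2g[[f]]
    tset <- switch(cls[[g]], hk = tissues, specific = spec_tissue[[g]], mixed = mixed_sets[[g]])
    on <- meta$tissue %in% tset
    v <- numeric(nrow(meta)); v[!on] <- lo(sum(!on)); v[on] <- hi(sum(on))
    if (g %in% switches) {
      sibs <- sort(names(t2g)[t2g == g])
      rank <- match(f, sibs)
      boost <- if (rank == 1L) meta$tissue %in% half1 else if (rank == 2L) !(meta$tissue %in% half1)
               else rep(FALSE, nrow(meta))
      v[on & boost] <- v[on & boost] + 10
    } else if (g %in% multi) {
      sibs <- sort(names(t2g)[t2g == g])
      if (match(f, sibs) == 1L) v[on] <- v[on] + 10        # stable dominant isoform
    }
    vals[f, ] <- v
  }
  m <- new_expression_matrix(vals, meta, level = "transcript")
  hk_tx <- feats[t2g[feats] %in% hk_genes]
  list(matrix = m, planted_hk_tx = hk_tx, planted_hk_genes = sort(hk_genes),
       planted_specific = data.table::data.table(gene_id = gids[cls == "specific"],
                                                 tissue = spec_tissue[cls == "specific"]),
       planted_switches = switches)
}

#' Generate homolog junction contexts with a planted conservation rate
#'
#' Conserved junctions get an identical homolog fragment; non-conserved
#' junctions get a fragment with `n_mut` point mutations (pushing identity
#' far below the rejection threshold).  Contexts are nucleotide-mode
#' (`in_cds = FALSE`).
#'
#' @param truth a `SyntheticTruth`
#' @param seed RNG seed
#' @param conserve_rate probability that a junction is conserved
#' @param n_mut mutations applied to non-conserved fragments (default 5)
#' @param k exonic bases per side of the junction window
#' @return list with `map` (named list gene_id -> data.table of homolog
#'   contexts) and `labels` (data.table `junction`, `gene_id`, `conserved`)
#' @export
make_homolog_contexts <- function(truth, seed, conserve_rate = 0.7, n_mut = 5L, k = 6L) {
  set.seed(child_seed(seed, 4L))
  ctx <- extract_junction_contexts(truth$annotation, truth$genome, k = k)
  uq <- ctx[, .SD[1L], by = junction]
  labels <- list(); map <- list()
  mutate <- function(s, n) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    pos <- sample(length(v), min(n, length(v)))
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    paste(v, collapse = "")
  }
  for (i in seq_len(nrow(uq))) {
    cons <- runif(1) < conserve_rate
    frag <- if (cons) uq$nt_fragment[i] else mutate(uq$nt_fragment[i], n_mut)
    g <- uq$gene_id[i]
    row <- data.table::data.table(nt_fragment = frag, peptide = NA_character_, in_cds = FALSE)
    map[[g]] <- if (is.null(map[[g]])) row else data.table::rbindlist(list(map[[g]], row))
    labels[[length(labels) + 1L]] <- data.table::data.table(
      junction = uq$junction[i], gene_id = g, conserved = cons)
  }
  list(map = map, labels = data.table::rbindlist(labels))
}

#' Generate ChIP-style peak intervals centred on anchors
#'
#' @param anchors data.frame with `chrom`, `pos` (e.g. expressed TSS table)
#' @param halfwidth peak half-width in bases
#' @return data.table of BED-style peak intervals
#' @export
make_peaks <- function(anchors, halfwidth = 500L) {
  anchors <- data.table::as.data.table(anchors)
  unique(anchors[, .(chrom, start = pmax(0L, pos - halfwidth), end = pos + halfwidth)])
}

#' Generate RepeatMasker-style repeat intervals
#'
#' @param truth a `SyntheticTruth` (supplies chromosome lengths)
#' @param seed RNG seed
#' @param n_te,n_non_te number of TE and non-TE records
#' @param len_range repeat length range
#' @return data.table `chrom`, `start`, `end`, `name` (class/family)
#' @export
make_repeats <- function(truth, seed, n_te = 30L, n_non_te = 10L, len_range = c(100L, 400L)) {
  set.seed(child_seed(seed, 5L))
  lens <- nchar(truth$genome)
  n <- n_te + n_non_te
  cn <- sample(names(lens), n, replace = TRUE)
  w <- .rint(len_range[1L], len_range[2L], n)
  s <- vapply(seq_len(n), function(i) sample.int(lens[[cn[i]]] - w[i], 1L) - 1L, integer(1))
  fam <- c(sample(TE_FAMILIES, n_te, replace = TRUE),
           sample(NON_TE_CLASSES, n_non_te, replace = TRUE))
  data.table::data.table(chrom = cn, start = s, end = s + w, name = fam)
}

#' Generate coding-evidence tables consistent with planted labels
#'
#' With `noise = 0`, coding transcripts pass all three tests and noncoding
#' transcripts fail all three, so the consensus classifier reproduces the
#' planted labels exactly.  `noise` flips each channel independently with
#' the given probability.
#'
#' @param truth a `SyntheticTruth` (uses `truth$labels`)
#' @param seed RNG seed
#' @param cpat_cutoff score cutoff the generated scores straddle
#' @param noise per-channel flip probability
#' @param dir optional directory: when given, writes `cpat.tsv`,
#'   `domains.tsv`, `hits.tsv` and returns their paths as attributes
#' @return list with `cpat`, `domains`, `hits` data.tables
#' @export
make_evidence_tables <- function(truth, seed, cpat_cutoff = 0.364, noise = 0, dir = NULL) {
  set.seed(child_seed(seed, 6L))
  lb <- truth$labels
  n <- nrow(lb)
  coding <- lb$label == "coding"
  flip <- function() runif(n) < noise
  pass1 <- xor(coding, flip()); pass2 <- xor(coding, flip()); pass3 <- xor(coding, flip())
  cpat <- data.table::data.table(transcript_id = lb$transcript_id,
                                 coding_score = ifelse(pass1, runif(n, cpat_cutoff + 0.05, 0.99),
                                                       runif(n, 0.01, cpat_cutoff - 0.05)))
  domains <- data.table::data.table(transcript_id = lb$transcript_id[pass2],
                                    domain = sprintf("PF%05d", sample.int(99999, sum(pass2), replace = TRUE)))
  ht_ids <- lb$transcript_id[pass3]
  species <- sample(c("MOUSE", "HUMAN", "RAT", "BOVIN"), length(ht_ids),
                    replace = TRUE, prob = c(0.35, 0.3, 0.25, 0.1))
  hits <- data.table::data.table(
    qseqid = ht_ids,
    sseqid = sprintf("Q%05d_%s", sample.int(99999, length(ht_ids), replace = TRUE), species),
    pident = round(runif(length(ht_ids), 70, 100), 1), length = 100L, mismatch = 5L,
    gapopen = 0L, qstart = 1L, qend = 300L, sstart = 1L, send = 100L,
    evalue = 10^-runif(length(ht_ids), 6, 50), bitscore = 200)
  out <- list(cpat = cpat, domains = domains, hits = hits)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(cpat, file.path(dir, "cpat.tsv"), sep = "\t")
    data.table::fwrite(domains, file.path(dir, "domains.tsv"), sep = "\t")
    data.table::fwrite(hits, file.path(dir, "hits.tsv"), sep = "\t", col.names = FALSE)
    attr(out, "paths") <- file.path(dir, c("cpat.tsv", "domains.tsv", "hits.tsv"))
  }
  out
}
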