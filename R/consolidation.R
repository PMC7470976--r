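## Post-assembly consolidation: replicate-support filtering of multi-exon
## transcripts, the superchain rescue rule, all-replicate mono-exon
## consolidation, intron-chain merging, and combination with reference
## annotations.
##
## Transcript identity across replicates is the exact intron chain
## (chromosome + strand + ordered intron intervals); mono-exon transcripts,
## whose reported ends vary between assemblies, are matched by
## single-linkage genomic overlap on the same strand instead.

.empty_decisions <- function() {
  data.table::setnames(
    data.table::data.table(k = character(), support = integer(),
                           fpkms = character(), verdict = character()), "k", "key")
}

#' Bundle per-replicate assemblies of one biological condition
#'
#' @param condition condition label (e.g. `"liver_6w_M"`)
#' @param assemblies named list of `Annotation` values, one per biological
#'   replicate (names are the replicate ids); at least 2
#' @return an object of class `ReplicateSet`
#' @export
new_replicate_set <- function(condition, assemblies) {
  if (length(assemblies) < 2L) stop2("a ReplicateSet needs at least 2 replicates")
  if (is.null(names(assemblies)) || any(!nzchar(names(assemblies))))
    names(assemblies) <- paste0("rep", seq_along(assemblies))
  stopifnot(all(vapply(assemblies, inherits, logical(1), "Annotation")))
  structure(list(condition = condition, assemblies = assemblies), class = "ReplicateSet")
}

#' @export
print.ReplicateSet <- function(x, ...) {
  cat(sprintf("ReplicateSet '%s' with %d replicates (%s)\n", x$condition,
              length(x$assemblies), paste(names(x$assemblies), collapse = ", ")))
  invisible(x)
}

## one FPKM value per transcript of a replicate assembly (NA = unknown)
.rep_fpkm <- function(a, rep_id) {
  if (!nrow(a$fpkm)) return(setNames(rep(NA_real_, nrow(a$tx)), a$tx$transcript_id))
  f <- if (rep_id %in% a$fpkm$sample) a$fpkm[sample == rep_id] else a$fpkm
  v <- setNames(rep(NA_real_, nrow(a$tx)), a$tx$transcript_id)
  ff <- f[, .(fpkm = fpkm[1L]), by = transcript_id]
  v[ff$transcript_id] <- ff$fpkm
  v
}

## long table of all multi-exon transcripts across replicates with chain keys
.multiexon_table <- function(rs) {
  out <- lapply(names(rs$assemblies), function(r) {
    a <- rs$assemblies[[r]]
    keys <- chain_keys(a)
    fp <- .rep_fpkm(a, r)
    tx <- a$tx[!is.na(keys[transcript_id])]
    if (!nrow(tx)) return(NULL)
    dt <- data.table::data.table(rep = r, transcript_id = tx$transcript_id,
                                 gene_id = tx$gene_id, chrom = tx$chrom, strand = tx$strand,
                                 start = tx$start, end = tx$end,
                                 fpkm = fp[tx$transcript_id])
    dt[, key := unname(keys[tx$transcript_id])]
    dt
  })
  data.table::rbindlist(out)
}

## rebuild exon rows for a chain key with given span boundaries
.chain_exons <- function(key, span_start, span_end, transcript_id, gene_id) {
  p <- strsplit(key, ":", fixed = TRUE)[[1L]]
  chrom <- p[1L]; strand <- p[2L]
  iv <- do.call(rbind, lapply(strsplit(p[3L], ",", fixed = TRUE)[[1L]],
                              function(s) as.integer(strsplit(s, "-", fixed = TRUE)[[1L]])))
  data.table::data.table(chrom = chrom,
                         start = c(span_start, iv[, 2L]),
                         end = c(iv[, 1L], span_end),
                         strand = strand, transcript_id = transcript_id, gene_id = gene_id)
}

## assemble an Annotation from a per-group table with columns
## key, start, end, transcript_id, gene_id (+ optional fpkm rows)
.annotation_from_groups <- function(groups, fpkm = NULL, provenance = "consolidated",
                                    source = "assembly") {
  if (!nrow(groups)) {
    return(new_annotation(data.frame(chrom = character(), start = integer(), end = integer(),
                                     strand = character(), transcript_id = character(),
                                     gene_id = character()),
                          provenance = provenance))
  }
  ex <- data.table::rbindlist(lapply(seq_len(nrow(groups)), function(i)
    .chain_exons(groups$key[i], groups$start[i], groups$end[i],
                 groups$transcript_id[i], groups$gene_id[i])))
  new_annotation(ex, fpkm = fpkm, source = source, provenance = provenance)
}

#' Replicate-support filter for multi-exon transcripts
#'
#' Multi-exon transcripts are grouped by identical intron chain across the
#' replicates of one condition.  A chain is retained iff at least
#' `min_reps` distinct replicates contain a copy with FPKM strictly greater
#' than `fpkm_min`.  The retained representative keeps the shared chain and
#' takes the leftmost start / rightmost end observed over all copies.
#' Transcripts without an FPKM value count as non-passing (with a warning).
#'
#' @param rs a `ReplicateSet`
#' @param fpkm_min FPKM threshold (strict `>`), default 1
#' @param min_reps minimum number of supporting replicates, default 2
#' @return list with `retained` (Annotation), `singletons` (Annotation of
#'   chains seen in exactly one replicate, candidates for
#'   [rescue_superchain()]) and `decisions` (one row per chain:
#'   `key`, `support`, `fpkms`, `verdict`)
#' @export
filter_multiexon_support <- function(rs, fpkm_min = 1, min_reps = 2) {
  me <- .multiexon_table(rs)
  if (!nrow(me)) {
    empty <- .annotation_from_groups(data.table::data.table())
    return(list(retained = empty, singletons = empty,
                decisions = .empty_decisions()))
  }
  if (anyNA(me$fpkm)) warn2("%d transcript copies lack FPKM; counted as non-passing", sum(is.na(me$fpkm)))
  grp <- me[, {
    pass <- !is.na(fpkm) & fpkm > fpkm_min
    .(support = data.table::uniqueN(rep[pass]),
      n_reps_seen = data.table::uniqueN(rep),
      fpkms = paste(format(fpkm[pass], trim = TRUE), collapse = ","),
      start = min(start), end = max(end),
      transcript_id = min(transcript_id), gene_id = gene_id[order(transcript_id)[1L]])
  }, by = key]
  grp[, verdict := ifelse(support >= min_reps, "retained", "dropped")]

  members <- me[, .(rep, transcript_id, key)]
  fpkm_rows <- merge(me[, .(key, rep, fpkm)], grp[, .(key, rid = transcript_id)], by = "key")
  fpkm_rows <- fpkm_rows[!is.na(fpkm), .(fpkm = max(fpkm)), by = .(transcript_id = rid, sample = rep)]

  retained <- .annotation_from_groups(grp[verdict == "retained"],
                                      fpkm = fpkm_rows[transcript_id %in% grp[verdict == "retained"]$transcript_id],
                                      provenance = paste0(rs$condition, ":multiexon"))
  singles <- .annotation_from_groups(grp[n_reps_seen == 1L],
                                     fpkm = fpkm_rows[transcript_id %in% grp[n_reps_seen == 1L]$transcript_id],
                                     provenance = paste0(rs$condition, ":singletons"))
  list(retained = retained, singletons = singles,
       decisions = grp[, .(key, support, fpkms, verdict)])
}

## per-transcript intron sets: list of "start-end" strings keyed by tid
.intron_sets <- function(a) {
  intr <- introns_of(a)
  keys <- chain_keys(a)
  ids <- names(keys)[!is.na(keys)]
  sets <- if (nrow(intr)) split(paste0(intr$start, "-", intr$end), intr$transcript_id) else list()
  meta <- a$tx[transcript_id %in% ids, .(transcript_id, chrom, strand)]
  list(sets = sets, meta = meta)
}

#' Rescue single-replicate superchain transcripts
#'
#' A multi-exon transcript found in only one replicate whose intron set is a
#' proper superset of the intron set of a supported novel transcript (same
#' chromosome and strand, strictly more exons) replaces that supported
#' transcript: the longer transcript is rescued, the shorter one abandoned.
#' Applied in a single pass (rescued transcripts do not seed further
#' rescues).
#'
#' @param singletons `Annotation` of chains seen in exactly one replicate
#' @param supported_novel `Annotation` of retained transcripts flagged novel
#' @return list with `rescued` (Annotation subset of `singletons`),
#'   `superseded_ids` (character ids removed from `supported_novel`) and
#'   `decisions`
#' @export
rescue_superchain <- function(singletons, supported_novel) {
  A <- .intron_sets(singletons); B <- .intron_sets(supported_novel)
  rescued_ids <- character(); superseded <- character()
  dec <- list()
  if (nrow(A$meta) && nrow(B$meta)) {
    for (i in seq_len(nrow(A$meta))) {
      aid <- A$meta$transcript_id[i]
      aset <- A$sets[[aid]]
      cand <- B$meta[chrom == A$meta$chrom[i] & strand == A$meta$strand[i]]
      for (bid in cand$transcript_id) {
        bset <- B$sets[[bid]]
        if (length(bset) < length(aset) && all(bset %in% aset)) {
          rescued_ids <- c(rescued_ids, aid)
          superseded <- c(superseded, bid)
          dec[[length(dec) + 1L]] <- data.table::setnames(data.table::data.table(
            k = aid, support = 1L, fpkms = "", verdict = "rescued"), "k", "key")
          dec[[length(dec) + 1L]] <- data.table::setnames(data.table::data.table(
            k = bid, support = NA_integer_, fpkms = "", verdict = "dropped_superseded"), "k", "key")
        }
      }
    }
  }
  list(rescued = subset_annotation(singletons, unique(rescued_ids)),
       superseded_ids = unique(superseded),
       decisions = data.table::rbindlist(dec))
}

## single-linkage overlap clustering of intervals; returns cluster id per row.
## rows must belong to one chrom+strand; overlap means sharing >= 1 base.
.overlap_clusters <- function(start, end) {
  o <- order(start, end)
  cl <- integer(length(start))
  cur <- 0L; maxend <- -Inf
  for (i in o) {
    if (start[i] >= maxend) { cur <- cur + 1L; maxend <- end[i] }
    else maxend <- max(maxend, end[i])
    cl[i] <- cur
  }
  cl
}

#' Consolidate mono-exon transcripts across replicates
#'
#' Mono-exon copies are clustered by single-linkage genomic overlap on the
#' same chromosome and strand.  A cluster is retained iff *every* replicate
#' of the condition contributes at least one copy with FPKM strictly greater
#' than `fpkm_min`; the retained transcript takes the leftmost 5' and
#' rightmost 3' end over all copies in the cluster.
#'
#' @param rs a `ReplicateSet`
#' @param fpkm_min FPKM threshold (strict `>`), default 1
#' @return list with `retained` (Annotation) and `decisions`
#' @export
consolidate_monoexon <- function(rs, fpkm_min = 1) {
  reps <- names(rs$assemblies)
  mono <- data.table::rbindlist(lapply(reps, function(r) {
    a <- rs$assemblies[[r]]
    keys <- chain_keys(a)
    tx <- a$tx[is.na(keys[transcript_id])]
    if (!nrow(tx)) return(NULL)
    fp <- .rep_fpkm(a, r)
    data.table::data.table(rep = r, transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                           chrom = tx$chrom, strand = tx$strand,
                           start = tx$start, end = tx$end, fpkm = fp[tx$transcript_id])
  }))
  empty_dec <- .empty_decisions()
  if (is.null(mono) || !nrow(mono)) {
    return(list(retained = .annotation_from_groups(data.table::data.table()), decisions = empty_dec))
  }
  mono[, cluster := paste(chrom, strand, .overlap_clusters(start, end), sep = "|"), by = .(chrom, strand)]
  grp <- mono[, {
    pass <- !is.na(fpkm) & fpkm > fpkm_min
    .(support = data.table::uniqueN(rep[pass]),
      all_reps = all(reps %in% rep[pass]),
      fpkms = paste(format(fpkm[pass], trim = TRUE), collapse = ","),
      chrom = chrom[1L], strand = strand[1L], start = min(start), end = max(end),
      transcript_id = min(transcript_id), gene_id = gene_id[order(transcript_id)[1L]])
  }, by = cluster]
  grp[, verdict := ifelse(all_reps, "retained", "dropped")]
  keep <- grp[verdict == "retained"]
  ex <- if (nrow(keep)) keep[, .(chrom, start, end, strand, transcript_id, gene_id)] else NULL
  fpkm_rows <- merge(mono[, .(cluster, rep, fpkm)], grp[, .(cluster, rid = transcript_id)], by = "cluster")
  fpkm_rows <- fpkm_rows[!is.na(fpkm), .(fpkm = max(fpkm)), by = .(transcript_id = rid, sample = rep)]
  ann <- if (is.null(ex)) .annotation_from_groups(data.table::data.table()) else
    new_annotation(ex, fpkm = fpkm_rows[transcript_id %in% keep$transcript_id],
                   provenance = paste0(rs$condition, ":monoexon"))
  list(retained = ann, decisions = grp[, .(key = cluster, support, fpkms, verdict)])
}

#' Merge transcript sets by intron chain and overlap
#'
#' Multi-exon transcripts with identical intron chains collapse to a single
#' transcript with the extreme observed boundaries; mono-exon transcripts
#' overlapping on the same strand collapse to their union interval.  Gene
#' ids are (re)assigned by single-linkage exonic-overlap clustering on the
#' same strand.  FPKM values are carried through as the per-sample maximum
#' over merged copies ("carried, not re-estimated").  The operation is
#' associative and idempotent.
#'
#' @param sets list of `Annotation` values (length >= 1)
#' @param provenance provenance label of the result
#' @return merged `Annotation`
#' @export
merge_transcript_sets <- function(sets, provenance = "merged") {
  stopifnot(length(sets) >= 1L)
  tx_all <- data.table::rbindlist(lapply(seq_along(sets), function(i) {
    a <- sets[[i]]
    if (!nrow(a$tx)) return(NULL)
    k <- chain_keys(a)
    dt <- data.table::data.table(set = i, transcript_id = a$tx$transcript_id,
                                 gene_id = a$tx$gene_id, chrom = a$tx$chrom, strand = a$tx$strand,
                                 start = a$tx$start, end = a$tx$end)
    dt[, key := unname(k[a$tx$transcript_id])]
    dt
  }))
  if (is.null(tx_all) || !nrow(tx_all))
    return(.annotation_from_groups(data.table::data.table(), provenance = provenance))

  fpkm_all <- data.table::rbindlist(lapply(seq_along(sets), function(i) {
    f <- sets[[i]]$fpkm
    if (!nrow(f)) NULL else data.table::data.table(set = i, f)
  }))

  ## multi-exon: group by chain key
  me <- tx_all[!is.na(key)]
  me_grp <- if (nrow(me)) me[, .(start = min(start), end = max(end),
                                 transcript_id = min(transcript_id)), by = key] else NULL
  ## mono-exon: overlap clustering per chrom+strand
  mo <- tx_all[is.na(key)]
  mo_grp <- NULL
  if (nrow(mo)) {
    mo[, cluster := paste(chrom, strand, .overlap_clusters(start, end), sep = "|"), by = .(chrom, strand)]
    mo_grp <- mo[, .(chrom = chrom[1L], strand = strand[1L], start = min(start), end = max(end),
                     transcript_id = min(transcript_id)), by = cluster]
  }

  ## exon rows of merged transcripts
  ex <- data.table::rbindlist(c(
    if (!is.null(me_grp) && nrow(me_grp))
      lapply(seq_len(nrow(me_grp)), function(i)
        .chain_exons(me_grp$key[i], me_grp$start[i], me_grp$end[i], me_grp$transcript_id[i], "G0")),
    if (!is.null(mo_grp) && nrow(mo_grp))
      list(mo_grp[, .(chrom, start, end, strand, transcript_id, gene_id = "G0")])))

  ## id mapping old -> merged, for FPKM carry-over
  map <- data.table::rbindlist(list(
    if (nrow(me)) merge(me[, .(set, transcript_id, key)], me_grp[, .(key, new_id = transcript_id)],
                        by = "key")[, .(set, transcript_id, new_id)],
    if (nrow(mo)) merge(mo[, .(set, transcript_id, cluster)], mo_grp[, .(cluster, new_id = transcript_id)],
                        by = "cluster")[, .(set, transcript_id, new_id)]))
  fp <- NULL
  if (!is.null(fpkm_all) && nrow(fpkm_all)) {
    fp <- merge(fpkm_all, map, by = c("set", "transcript_id"))[
      , .(fpkm = max(fpkm)), by = .(transcript_id = new_id, sample)]
  }

  ## gene assignment by exonic-overlap clustering
  gene_map <- .gene_clusters(ex)
  ex[, gene_id := gene_map[transcript_id]]
  new_annotation(ex, fpkm = fp, provenance = provenance)
}

## single-linkage exonic-overlap clustering of transcripts on one strand;
## returns named vector tid -> gene id ("G<n>", numbered by chrom+position)
.gene_clusters <- function(ex, prefix = "G") {
  ex2 <- data.table::copy(ex)
  ex2[, ecl := paste(chrom, strand, .overlap_clusters(start, end), sep = "|"), by = .(chrom, strand)]
  ## transcripts sharing an exon cluster belong to one gene (union-find)
  tids <- unique(ex2$transcript_id)
  parent <- seq_along(tids); names(parent) <- tids
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  byc <- split(match(ex2$transcript_id, tids), ex2$ecl)
  for (v in byc) {
    v <- unique(v)
    for (j in v[-1L]) { ri <- find(v[1L]); rj <- find(j); if (ri != rj) parent[rj] <- ri }
  }
  root <- vapply(seq_along(tids), find, integer(1))
  ## deterministic numbering by genomic position of the cluster
  pos <- ex2[, .(chrom = chrom[1L], start = min(start)), by = transcript_id]
  pos[, root := root[match(transcript_id, tids)]]
  ord <- pos[, .(chrom = min(chrom), start = min(start)), by = root]
  data.table::setorder(ord, chrom, start, root)
  ord[, gid := paste0(prefix, .I)]
  setNames(ord$gid[match(root[match(pos$transcript_id, tids)], ord$root)], pos$transcript_id)
}

#' Build the consolidated transcriptome of one condition
#'
#' Applies, in order: the multi-exon replicate-support filter, the
#' superchain rescue rule, mono-exon consolidation, intron-chain merging,
#' and the final length filter (transcripts longer than `min_len` bases of
#' summed exon length are retained; strict `>`).
#'
#' @param rs a `ReplicateSet`
#' @param fpkm_min FPKM threshold for the support rules (strict `>`)
#' @param min_reps replicate support for multi-exon chains
#' @param min_len minimum transcript length in exonic bases (strict `>`)
#' @param references optional list of reference `Annotation`s; when given,
#'   the rescue rule only considers supported transcripts that are novel
#'   (chain absent from every reference).  When `NULL`, all supported
#'   transcripts are treated as novel.
#' @return consolidated `Annotation` with a `decisions` attribute (the
#'   combined audit table of all support decisions)
#' @export
build_condition_transcriptome <- function(rs, fpkm_min = 1, min_reps = 2,
                                          min_len = 200, references = NULL) {
  f <- filter_multiexon_support(rs, fpkm_min = fpkm_min, min_reps = min_reps)
  novel_target <- f$retained
  if (!is.null(references)) {
    ref_keys <- unlist(lapply(references, function(r) chain_keys(r)), use.names = FALSE)
    keys <- chain_keys(f$retained)
    novel_ids <- names(keys)[is.na(match(keys, ref_keys))]
    novel_target <- subset_annotation(f$retained, novel_ids)
  }
  resc <- rescue_superchain(f$singletons, novel_target)
  keep_ids <- setdiff(f$retained$tx$transcript_id, resc$superseded_ids)
  multi <- subset_annotation(f$retained, keep_ids)
  mono <- consolidate_monoexon(rs, fpkm_min = fpkm_min)
  merged <- merge_transcript_sets(list(multi, resc$rescued, mono$retained),
                                  provenance = rs$condition)
  long_ids <- merged$tx[length > min_len]$transcript_id
  if (!length(long_ids)) warn2("condition '%s': no transcript survived consolidation", rs$condition)
  out <- subset_annotation(merged, long_ids)
  out$provenance <- rs$condition
  data.table::setattr(out, "decisions",
                      data.table::rbindlist(list(f$decisions, resc$decisions, mono$decisions)))
  out
}

#' Combine assembled transcripts with reference annotations
#'
#' Reference transcripts are always retained under their original ids.  An
#' assembled transcript whose structure exactly matches a reference
#' transcript (identical intron chain; for mono-exon queries, containment
#' within an exon-overlapping reference transcript on the same strand) is
#' represented by the reference entry.  Remaining assembled transcripts are
#' added as novel with generated ids `<prefix><gene#>.<k>`.  Genes are
#' rebuilt by exonic-overlap clustering; a cluster containing at least one
#' reference transcript keeps the (lexicographically first) reference gene
#' id.
#'
#' @param novel assembled `Annotation`
#' @param references list of reference `Annotation`s (e.g. Ensembl, RefSeq)
#' @param prefix id prefix for newly annotated genes/transcripts
#' @return combined `Annotation`; novel transcripts carry source `"novel"`
#' @export
combine_with_reference <- function(novel, references, prefix = "RTRG.") {
  if (inherits(references, "Annotation")) references <- list(references)
  ## concatenate references; on duplicate ids the first reference wins
  ref_ex <- data.table::rbindlist(lapply(seq_along(references), function(i)
    data.table::data.table(refidx = i, references[[i]]$exons)))
  ref_tx <- data.table::rbindlist(lapply(seq_along(references), function(i)
    data.table::data.table(refidx = i, references[[i]]$tx)))
  ref_cds <- data.table::rbindlist(lapply(references, function(r) r$cds))
  if (anyDuplicated(ref_tx$transcript_id)) {
    warn2("duplicate reference transcript ids; first occurrence wins")
    winner <- ref_tx[, .(refidx = min(refidx)), by = transcript_id]
    ref_tx <- merge(ref_tx, winner, by = c("transcript_id", "refidx"))
    ref_ex <- merge(ref_ex, winner, by = c("transcript_id", "refidx"))
  }
  tid_order <- sort(unique(ref_ex$transcript_id))
  ref_ann <- new_annotation(ref_ex[, .(chrom, start, end, strand, transcript_id, gene_id)],
                            cds = if (nrow(ref_cds)) ref_cds[transcript_id %in% tid_order] else NULL,
                            source = ref_tx$source[match(tid_order, ref_tx$transcript_id)],
                            provenance = "reference", validate = FALSE)
  cls <- classify_transcripts(novel, ref_ann)
  novel_ids <- names(cls)[cls != "exact"]
  nov <- subset_annotation(novel, novel_ids)

  ## cluster all transcripts into genes
  all_ex <- data.table::rbindlist(list(ref_ann$exons, nov$exons))
  gcl <- .gene_clusters(all_ex, prefix = prefix)
  ## map cluster -> reference gene id when available
  ref_gid <- setNames(ref_ann$tx$gene_id, ref_ann$tx$transcript_id)
  cl_tab <- data.table::data.table(transcript_id = names(gcl), cluster = gcl)
  cl_tab[, ref_gene := ref_gid[transcript_id]]
  gene_of_cluster <- cl_tab[, .(gid = if (any(!is.na(ref_gene))) min(ref_gene, na.rm = TRUE)
                                else cluster[1L]), by = cluster]
  gmap <- setNames(gene_of_cluster$gid, gene_of_cluster$cluster)

  ## generated ids for novel transcripts: <cluster>.<k> in positional order
  nov_tx <- nov$tx[, .(transcript_id, chrom, start)]
  nov_tx[, cluster := gcl[transcript_id]]
  data.table::setorder(nov_tx, cluster, chrom, start, transcript_id)
  nov_tx[, new_id := paste0(cluster, ".", seq_len(.N)), by = cluster]
  idmap <- setNames(nov_tx$new_id, nov_tx$transcript_id)

  out_ex <- data.table::rbindlist(list(
    data.table::copy(ref_ann$exons)[, gene_id := gmap[gcl[transcript_id]]],
    data.table::copy(nov$exons)[, `:=`(gene_id = gmap[gcl[transcript_id]],
                                       transcript_id = idmap[transcript_id])]))
  fp <- data.table::copy(nov$fpkm)
  if (nrow(fp)) fp[, transcript_id := idmap[transcript_id]]
  src <- c(setNames(ref_ann$tx$source, ref_ann$tx$transcript_id),
           setNames(rep("novel", nrow(nov$tx)), idmap[nov$tx$transcript_id]))
  tid_sorted <- sort(unique(out_ex$transcript_id))
  new_annotation(out_ex, fpkm = if (nrow(fp)) fp else NULL,
                 cds = if (nrow(ref_ann$cds)) ref_ann$cds else NULL,
                 source = unname(src[tid_sorted]), provenance = "combined")
}
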