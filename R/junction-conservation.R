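## Cross-species splice-junction conservation: extraction of spliced -6..+6
## contexts around junctions, a built-in Needleman-Wunsch global aligner
## with affine gaps (EMBOSS-needle conventions), and the three rejection
## rules (gap count, nucleotide identity, protein identity/similarity).

## Physico-chemical residue groups used for protein similarity.  Residues
## not listed are similar only to themselves; H belongs to both the
## aromatic and the positive group.
RESIDUE_GROUPS <- list(
  aliphatic = c("I", "L", "V"),
  aromatic  = c("F", "Y", "W", "H"),
  positive  = c("H", "K", "R"),
  negative  = c("D", "E"),
  tiny      = c("A", "C", "T", "S", "G"))

.residues_similar <- function(x, y) {
  x == y | vapply(seq_along(x), function(i)
    any(vapply(RESIDUE_GROUPS, function(g) x[i] %in% g && y[i] %in% g, logical(1))),
    logical(1))
}

## BLOSUM62 (standard 20 residues + X)
.blosum62 <- local({
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V","X")
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-1,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,-1,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,-1,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,-1,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,-1,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,-1,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-1,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,-1,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-1,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,-1,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-1,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-1,
    -1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1)
  m <- matrix(v, 21, 21, byrow = TRUE, dimnames = list(aa, aa))
  m
})

.nt_score <- function(x, y, match = 5, mismatch = -4, nscore = -2) {
  ifelse(x == "N" | y == "N", nscore, ifelse(x == y, match, mismatch))
}

#' Global alignment with affine gap penalties
#'
#' A Needleman-Wunsch / Gotoh implementation following EMBOSS-needle
#' conventions: DNA scoring match +5 / mismatch -4 (N scores -2 against
#' anything), protein scoring BLOSUM62; a gap of length L costs
#' `gap_open + L * gap_extend`.  Traceback tie-breaking is deterministic:
#' diagonal is preferred over a gap in the second sequence, which is
#' preferred over a gap in the first.
#'
#' Identity is the percentage of alignment columns with identical residues;
#' similarity (protein mode only) additionally accepts columns whose
#' residues share a physico-chemical group (aliphatic I/L/V, aromatic
#' F/Y/W/H, positive H/K/R, negative D/E, tiny A/C/T/S/G); `gap_columns`
#' counts columns containing a gap character.
#'
#' @param a,b non-empty sequences over the mode's alphabet
#' @param mode `"nucleotide"` or `"protein"`
#' @param gap_open gap opening penalty (default 10)
#' @param gap_extend gap extension penalty per gapped position (default 0.5)
#' @return list of class `AlignmentResult` with `a_aln`, `b_aln`, `score`,
#'   `identity`, `similarity` (`NA` in nucleotide mode), `gap_columns`,
#'   `columns`, `mode`
#' @export
global_align <- function(a, b, mode = c("nucleotide", "protein"),
                         gap_open = 10, gap_extend = 0.5) {
  mode <- match.arg(mode)
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (!length(A) || !length(B)) stop2("global_align requires non-empty sequences")
  alphabet <- if (mode == "nucleotide") c("A", "C", "G", "T", "N") else rownames(.blosum62)
  chk <- function(x, nm) {
    bad <- which(!x %in% alphabet)
    if (length(bad)) stop2("invalid %s character '%s' at position %d", mode, x[bad[1L]], bad[1L])
  }
  chk(A, "a"); chk(B, "b")
  sc <- function(x, y) if (mode == "nucleotide") .nt_score(x, y) else .blosum62[x, y]

  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)   # Ix: gap in b (consume a); Iy: gap in a
  pM <- pIx <- pIy <- matrix(0L, n + 1L, m + 1L) # predecessor state 1=M 2=Ix 3=Iy
  M[1L, 1L] <- 0
  for (i in seq_len(n)) { Ix[i + 1L, 1L] <- -(gap_open + i * gap_extend); pIx[i + 1L, 1L] <- 2L }
  if (n >= 2L) pIx[2L, 1L] <- 1L
  for (j in seq_len(m)) { Iy[1L, j + 1L] <- -(gap_open + j * gap_extend); pIy[1L, j + 1L] <- 3L }
  pIy[1L, 2L] <- 1L
  if (n >= 1L) pIx[2L, 1L] <- 1L
  for (i in seq_len(n)) {
    srow <- vapply(B, function(bb) sc(A[i], bb), numeric(1))
    for (j in seq_len(m)) {
      ## M state: prefer M > Ix > Iy on ties
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      k <- which.max(cand)                       # which.max returns first max: M>Ix>Iy
      M[i + 1L, j + 1L] <- cand[k] + srow[j]
      pM[i + 1L, j + 1L] <- k
      ## Ix: gap in b, consume A[i]
      cand <- c(M[i, j + 1L] - gap_open - gap_extend,
                Ix[i, j + 1L] - gap_extend,
                Iy[i, j + 1L] - gap_open - gap_extend)
      k <- which.max(cand)
      Ix[i + 1L, j + 1L] <- cand[k]; pIx[i + 1L, j + 1L] <- k
      ## Iy: gap in a, consume B[j]
      cand <- c(M[i + 1L, j] - gap_open - gap_extend,
                Ix[i + 1L, j] - gap_open - gap_extend,
                Iy[i + 1L, j] - gap_extend)
      k <- which.max(cand)
      Iy[i + 1L, j + 1L] <- cand[k]; pIy[i + 1L, j + 1L] <- k
    }
  }
  fin <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
  state <- which.max(fin)
  score <- fin[state]
  ## traceback
  i <- n; j <- m; av <- character(); bv <- character()
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      av <- c(A[i], av); bv <- c(B[j], bv)
      state <- pM[i + 1L, j + 1L]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      av <- c(A[i], av); bv <- c("-", bv)
      state <- pIx[i + 1L, j + 1L]; i <- i - 1L
    } else {
      av <- c("-", av); bv <- c(B[j], bv)
      state <- pIy[i + 1L, j + 1L]; j <- j - 1L
    }
  }
  cols <- length(av)
  gap <- av == "-" | bv == "-"
  ident <- !gap & av == bv
  sim <- if (mode == "protein") {
    ok <- !gap
    s <- logical(cols); s[ok] <- .residues_similar(av[ok], bv[ok]); s
  } else NULL
  structure(list(a_aln = paste(av, collapse = ""), b_aln = paste(bv, collapse = ""),
                 score = score,
                 identity = 100 * sum(ident) / cols,
                 similarity = if (mode == "protein") 100 * sum(sim) / cols else NA_real_,
                 gap_columns = sum(gap), columns = cols, mode = mode),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("%s alignment, score %.1f, identity %.1f%%%s, %d gap column(s)\n%s\n%s\n",
              x$mode, x$score, x$identity,
              if (!is.na(x$similarity)) sprintf(", similarity %.1f%%", x$similarity) else "",
              x$gap_columns, x$a_aln, x$b_aln))
  invisible(x)
}

#' Extract spliced junction contexts of a transcript set
#'
#' For every junction of every multi-exon transcript the spliced fragment of
#' the `k` exonic bases on each side is extracted (strand-corrected to
#' transcript orientation).  When the junction lies inside an annotated CDS
#' and is at least 3 nt from its edges, the -k..+k window is extended
#' outward to whole codons and translated into the in-frame peptide;
#' otherwise the peptide is absent and nucleotide mode is forced downstream.
#'
#' @param a an `Annotation` (CDS records supply the reading frame)
#' @param genome named character vector of chromosome sequences
#' @param k exonic bases per side (default 6)
#' @param transcript_ids optional subset of transcripts
#' @return data.table with one row per junction occurrence: `transcript_id`,
#'   `gene_id`, `junction` (key `chrom:strand:start-end` of the intron),
#'   `chrom`, `strand`, `intron_start`, `intron_end`, `nt_fragment`,
#'   `truncated`, `in_cds`, `peptide`
#' @export
extract_junction_contexts <- function(a, genome, k = 6L, transcript_ids = NULL) {
  intr <- introns_of(a)
  if (!is.null(transcript_ids)) intr <- intr[transcript_id %in% transcript_ids]
  if (!nrow(intr)) {
    return(data.table::data.table(transcript_id = character(), gene_id = character(),
                                  junction = character(), chrom = character(), strand = character(),
                                  intron_start = integer(), intron_end = integer(),
                                  nt_fragment = character(), truncated = logical(),
                                  in_cds = logical(), peptide = character()))
  }
  gid <- setNames(a$tx$gene_id, a$tx$transcript_id)
  ex_by_tx <- split(a$exons, by = "transcript_id")
  cds_by_tx <- if (nrow(a$cds)) split(a$cds, by = "transcript_id") else list()

  rows <- lapply(seq_len(nrow(intr)), function(r) {
    tid <- intr$transcript_id[r]
    ex <- ex_by_tx[[tid]]
    chrom <- intr$chrom[r]; strand <- intr$strand[r]
    s <- intr$start[r]; e <- intr$end[r]
    up <- ex[end == s]; down <- ex[start == e]
    ku <- min(k, up$end - up$start); kd <- min(k, down$end - down$start)
    frag <- paste0(seq_fetch(genome, chrom, s - ku, s), seq_fetch(genome, chrom, e, e + kd))
    if (strand == "-") frag <- revcomp(frag)
    trunc <- (ku < k) || (kd < k)

    in_cds <- FALSE; pep <- NA_character_
    cd <- cds_by_tx[[tid]]
    if (!is.null(cd) && nrow(cd) >= 2L && any(cd$end == s) && any(cd$start == e)) {
      in_cds <- TRUE
      seg <- cd[order(start)]
      cds_seq <- paste0(vapply(seq_len(nrow(seg)), function(i)
        seq_fetch(genome, chrom, seg$start[i], seg$end[i]), character(1)), collapse = "")
      cdslen <- nchar(cds_seq)
      ## junction position in CDS coordinates, transcript orientation
      pos_genomic <- sum(seg[end <= s]$end - seg[end <= s]$start)
      p <- if (strand == "+") pos_genomic else cdslen - pos_genomic
      if (strand == "-") cds_seq <- revcomp(cds_seq)
      if (p >= 3L && cdslen - p >= 3L) {
        lo <- max(0L, (as.integer(floor((p - k) / 3)) * 3L))
        ## never include the stop codon: peptides feed the protein aligner
        hi <- min(cdslen - 3L, (as.integer(ceiling((p + k) / 3)) * 3L))
        win <- substr(cds_seq, lo + 1L, hi)
        win <- substr(win, 1L, (nchar(win) %/% 3L) * 3L)
        pep <- tryCatch(as.character(Biostrings::translate(Biostrings::DNAString(win))),
                        error = function(e) NA_character_)
      } else {
        in_cds <- FALSE    # within 2 nt of a CDS edge: nucleotide mode
      }
    }
    data.table::data.table(transcript_id = tid, gene_id = unname(gid[tid]),
                           junction = sprintf("%s:%s:%d-%d", chrom, strand, s, e),
                           chrom = chrom, strand = strand,
                           intron_start = s, intron_end = e,
                           nt_fragment = frag, truncated = trunc,
                           in_cds = in_cds, peptide = pep)
  })
  data.table::rbindlist(rows)
}

#' Test one junction context for cross-species conservation
#'
#' The query context is aligned against every homolog context; an alignment
#' survives iff it has at most one gap column and meets the mode's
#' thresholds: nucleotide identity >= 80%, or protein identity >= 80% and
#' protein similarity >= 90%.  The mode per homolog follows whether the
#' homolog junction lies in a coding region (protein mode additionally
#' requires peptides on both sides).  The junction is conserved iff at
#' least one alignment survives.
#'
#' @param nt_fragment query spliced nucleotide fragment
#' @param peptide query in-frame peptide or `NA`
#' @param homologs data.table with columns `nt_fragment`, `peptide`,
#'   `in_cds` (one row per homolog junction context)
#' @param mode `"auto"` (default; per-homolog), `"nucleotide"` or `"protein"`
#' @param min_nt_identity,min_aa_identity,min_aa_similarity,max_gap_columns
#'   rejection thresholds
#' @param ... passed to [global_align()]
#' @return list with `conserved` (logical), `best` (best surviving
#'   `AlignmentResult`, or best rejected when none survives, or `NULL`),
#'   `reason` (`NA` when conserved; otherwise `"no homolog junctions"`,
#'   `"gaps"`, `"identity"` or `"similarity"`)
#' @export
test_junction_conservation <- function(nt_fragment, peptide = NA_character_, homologs,
                                       mode = c("auto", "nucleotide", "protein"),
                                       min_nt_identity = 80, min_aa_identity = 80,
                                       min_aa_similarity = 90, max_gap_columns = 1L, ...) {
  mode <- match.arg(mode)
  homologs <- data.table::as.data.table(homologs)
  if (!nrow(homologs))
    return(list(conserved = FALSE, best = NULL, reason = "no homolog junctions"))
  best_ok <- NULL; best_bad <- NULL; bad_reason <- NA_character_
  for (i in seq_len(nrow(homologs))) {
    h_in_cds <- isTRUE(homologs$in_cds[i])
    h_pep <- homologs$peptide[i]
    use_protein <- switch(mode,
                          protein = TRUE,
                          nucleotide = FALSE,
                          auto = h_in_cds && !is.na(h_pep) && !is.na(peptide))
    al <- if (use_protein) global_align(peptide, h_pep, mode = "protein", ...)
          else global_align(nt_fragment, homologs$nt_fragment[i], mode = "nucleotide", ...)
    reason <- NA_character_
    if (al$gap_columns > max_gap_columns) reason <- "gaps"
    else if (use_protein && al$identity < min_aa_identity) reason <- "identity"
    else if (use_protein && al$similarity < min_aa_similarity) reason <- "similarity"
    else if (!use_protein && al$identity < min_nt_identity) reason <- "identity"
    if (is.na(reason)) {
      if (is.null(best_ok) || al$score > best_ok$score) best_ok <- al
    } else if (is.null(best_bad) || al$score > best_bad$score) {
      best_bad <- al; bad_reason <- reason
    }
  }
  if (!is.null(best_ok)) list(conserved = TRUE, best = best_ok, reason = NA_character_)
  else list(conserved = FALSE, best = best_bad, reason = bad_reason)
}

#' Junction conservation report for an annotation
#'
#' Extracts the junction contexts of the given transcripts, tests each
#' *unique* junction against the homolog contexts mapped to its gene and
#' reports the per-junction verdicts plus the conserved fraction.
#'
#' @param a an `Annotation`
#' @param genome named character vector of chromosome sequences
#' @param homolog_map named list: `gene_id` -> data.table of homolog
#'   contexts (`nt_fragment`, `peptide`, `in_cds`)
#' @param k exonic bases per side of the junction window
#' @param mode alignment mode passed to [test_junction_conservation()]
#' @param transcript_ids optional transcript subset (e.g. novel coding only)
#' @return list with `table` (one row per unique junction: `junction`,
#'   `gene_id`, `mode`, `identity`, `similarity`, `conserved`, `reason`) and
#'   `fraction` (conserved fraction over unique junctions; 0 when the map
#'   is empty)
#' @export
conservation_report <- function(a, genome, homolog_map, k = 6L,
                                mode = "auto", transcript_ids = NULL) {
  ctx <- extract_junction_contexts(a, genome, k = k, transcript_ids = transcript_ids)
  if (!nrow(ctx)) return(list(table = ctx, fraction = NA_real_))
  uq <- ctx[, .SD[1L], by = junction]
  rows <- lapply(seq_len(nrow(uq)), function(i) {
    hom <- homolog_map[[uq$gene_id[i]]]
    res <- if (is.null(hom) || !nrow(hom))
      list(conserved = FALSE, best = NULL, reason = "no homolog junctions")
    else test_junction_conservation(uq$nt_fragment[i], uq$peptide[i], hom, mode = mode)
    data.table::data.table(junction = uq$junction[i], gene_id = uq$gene_id[i],
                           mode = if (is.null(res$best)) NA_character_ else res$best$mode,
                           identity = if (is.null(res$best)) NA_real_ else res$best$identity,
                           similarity = if (is.null(res$best)) NA_real_ else res$best$similarity,
                           conserved = res$conserved, reason = res$reason)
  })
  tab <- data.table::rbindlist(rows)
  list(table = tab, fraction = mean(tab$conserved))
}
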