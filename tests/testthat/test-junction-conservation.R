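test_that("global_align handles identity, the printed residue-group example, and errors", {
  al <- global_align("GTAAGT", "GTAAGT")
  expect_equal(al$identity, 100)
  expect_equal(al$gap_columns, 0L)
  ## I~L (aliphatic), K~R (positive): identity 50, similarity 100
  al2 <- global_align("ILVK", "LLVR", mode = "protein")
  expect_equal(al2$identity, 50)
  expect_equal(al2$similarity, 100)
  expect_error(global_align("ACGT", "AZGT"), "invalid")
  expect_error(global_align("", "A"), "non-empty")
  ## residues outside the five groups are similar only to themselves
  al3 <- global_align("MM", "MN", mode = "protein")
  expect_equal(al3$similarity, 50)
})

test_that("alignment scores equal an independent recursive DP oracle", {
  ## exhaustive: all pairs over a 2-letter alphabet up to length 5
  seqs <- unlist(lapply(1:5, function(L)
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")))
  for (a in seqs) for (b in seqs) {
    got <- global_align(a, b)$score
    expect_equal(got, o_align_score(a, b), info = paste(a, b))
  }
})

test_that("alignment scores match the oracle on random longer pairs in both modes", {
  set.seed(7)
  aa <- rownames(retra:::.blosum62)[1:20]
  for (r in 1:150) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, o_align_score(a, b), info = paste(a, b))
  }
  for (r in 1:150) {
    a <- paste(sample(aa, sample(3:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:8, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b, mode = "protein")$score,
                 o_align_score(a, b, mode = "protein"), info = paste(a, b))
  }
})

test_that("alignment invariants hold: similarity >= identity, reversal symmetry", {
  set.seed(8)
  aa <- rownames(retra:::.blosum62)[1:20]
  for (r in 1:50) {
    a <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 8, replace = TRUE), collapse = "")
    al <- global_align(a, b, mode = "protein")
    expect_gte(al$similarity, al$identity)
    rev_s <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(global_align(rev_s(a), rev_s(b), mode = "protein")$score, al$score)
  }
})

test_that("junction contexts are extracted strand-correctly with CDS peptides", {
  ## hand-built genome: exon1 = positions 0..8, intron 8..12, exon2 = 12..20
  genome <- c(chr1 = "AAGGTTCCGGGGTTCCAAGG")
  a <- mk_ann(mk_exons("t1", c(0, 12), c(8, 20)))
  ctx <- extract_junction_contexts(a, genome, k = 6)
  expect_equal(ctx$nt_fragment, paste0("GGTTCC", "TTCCAA"))
  expect_false(ctx$truncated)
  ## minus strand: reverse complement, sides swapped
  am <- mk_ann(mk_exons("t1m", c(0, 12), c(8, 20), strand = "-"))
  ctxm <- extract_junction_contexts(am, genome, k = 6)
  expect_equal(ctxm$nt_fragment, retra::revcomp(paste0("GGTTCC", "TTCCAA")))
  ## short exons truncate the window and flag it
  as <- mk_ann(mk_exons("ts", c(4, 12), c(8, 20)))
  ctxs <- extract_junction_contexts(as, genome, k = 6)
  expect_true(ctxs$truncated)
  expect_equal(nchar(ctxs$nt_fragment), 4 + 6)
  ## junction outside any CDS: peptide absent
  expect_true(is.na(ctx$peptide))

  ## synthetic coding transcripts yield in-frame peptides at in-CDS junctions
  g <- make_genome(55, 1, 120000)
  tr <- make_annotation(g, 55, n_genes = 20, coding_fraction = 1, mono_fraction = 0)
  ctx2 <- extract_junction_contexts(tr$annotation, tr$genome)
  with_pep <- ctx2[in_cds == TRUE]
  expect_gt(nrow(with_pep), 0)
  expect_false(any(grepl("\\*", with_pep$peptide)))   # planted ORFs have no internal stops
  ## peptide matches a direct translation of the spliced CDS window
  cds <- tr$annotation$cds
  for (i in seq_len(min(5, nrow(with_pep)))) {
    expect_gte(nchar(with_pep$peptide[i]), 4)          # -6..+6 padded to codons
    expect_lte(nchar(with_pep$peptide[i]), 5)
  }
})

test_that("conservation rejection rules fire with the stated thresholds and reasons", {
  frag <- "GGTTCCTTCCAA"
  hom1 <- data.table::data.table(nt_fragment = frag, peptide = NA_character_, in_cds = FALSE)
  r <- test_junction_conservation(frag, NA, hom1)
  expect_true(r$conserved)
  expect_equal(r$best$identity, 100)
  ## 2 gap columns -> rejected with reason "gaps"
  hom2 <- data.table::data.table(nt_fragment = "GGTTCCTTCCAAGG", peptide = NA_character_,
                                 in_cds = FALSE)
  r2 <- test_junction_conservation(frag, NA, hom2)
  expect_false(r2$conserved)
  expect_equal(r2$reason, "gaps")
  ## 9/12 matching columns = 75% identity, no gaps -> rejected (< 80%)
  frag2 <- "GGTTCCTTCCAA"; mut <- "GGTACCTACCTA"     # 3 mismatches
  al <- global_align(frag2, mut)
  expect_equal(al$identity, 75); expect_equal(al$gap_columns, 0L)
  r3 <- test_junction_conservation(frag2, NA,
                                   data.table::data.table(nt_fragment = mut,
                                                          peptide = NA_character_, in_cds = FALSE))
  expect_false(r3$conserved)
  expect_equal(r3$reason, "identity")
  ## protein mode: identity >= 80 but similarity < 90 -> reason "similarity"
  pep <- "AAAAAAAAKK"; hpep <- "AAAAAAAAWW"          # 80% identity, W not similar to K
  hp <- data.table::data.table(nt_fragment = frag, peptide = hpep, in_cds = TRUE)
  rp <- test_junction_conservation(frag, pep, hp, mode = "auto")
  expect_false(rp$conserved)
  expect_equal(rp$best$mode, "protein")
  expect_equal(rp$best$identity, 80)
  expect_equal(rp$reason, "similarity")
  ## empty homolog list
  r0 <- test_junction_conservation(frag, NA, data.table::data.table(
    nt_fragment = character(), peptide = character(), in_cds = logical()))
  expect_false(r0$conserved)
  expect_equal(r0$reason, "no homolog junctions")
})

test_that("adding homolog contexts never flips conserved to not conserved", {
  set.seed(9)
  frag <- "GGTTCCTTCCAA"
  for (r in 1:20) {
    n <- sample(1:4, 1)
    homs <- data.table::data.table(
      nt_fragment = vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = ""), character(1)),
      peptide = NA_character_, in_cds = FALSE)
    base <- test_junction_conservation(frag, NA, homs)
    more <- test_junction_conservation(frag, NA, rbind(homs, data.table::data.table(
      nt_fragment = frag, peptide = NA_character_, in_cds = FALSE)))
    if (base$conserved) expect_true(more$conserved)
    expect_true(more$conserved)   # the identical context always survives
  }
})

test_that("conservation_report recovers planted conservation rates", {
  g <- make_genome(66, 2, 100000)
  tr <- make_annotation(g, 66, n_genes = 25, mono_fraction = 0)
  for (rate in c(0.3, 1.0)) {
    hom <- make_homolog_contexts(tr, 66, conserve_rate = rate)
    rep <- conservation_report(tr$annotation, tr$genome, hom$map)
    planted <- mean(hom$labels$conserved)
    n <- nrow(hom$labels)
    ## recovery is binomial, not exact: homolog contexts are pooled per gene,
    ## so a junction can occasionally match a sibling junction's context
    expect_lte(abs(rep$fraction - planted), 3 * sqrt(rate * (1 - rate) / n) + 2 / n)
    expect_lte(abs(planted - rate), 3 * sqrt(rate * (1 - rate) / n) + 1e-9)
    if (rate == 1.0) expect_equal(rep$fraction, 1.0)
  }
  ## empty homolog map -> fraction 0
  rep0 <- conservation_report(tr$annotation, tr$genome, list())
  expect_equal(rep0$fraction, 0)
})
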