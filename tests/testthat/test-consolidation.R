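test_that("multi-exon support filter applies the strict FPKM/replicate rule", {
  rs <- mk_rs(list(
    rep1 = list(list(tid = "a1", starts = c(0, 300), ends = c(100, 400), fpkm = 2.0),
                list(tid = "b1", starts = c(1000, 1300), ends = c(1100, 1400), fpkm = 1.0)),
    rep2 = list(list(tid = "a2", starts = c(0, 300), ends = c(100, 420), fpkm = 3.0),
                list(tid = "b2", starts = c(1000, 1300), ends = c(1100, 1400), fpkm = 0.9)),
    rep3 = list(), rep4 = list()))
  f <- filter_multiexon_support(rs)
  shapes <- ann_shape(f$retained)
  expect_length(shapes, 1L)                      # chain a retained, chain b dropped (strict >)
  expect_match(shapes, "0:100")
  expect_match(shapes, "300:420")                # rightmost end over copies
  dec <- f$decisions
  expect_setequal(dec$verdict, c("retained", "dropped"))
})

test_that("superchain rescue retains the longer singleton and abandons the sub-chain", {
  singles <- mk_ann(mk_exons("A", c(0, 200, 400, 600), c(100, 300, 500, 700)))
  supported <- mk_ann(mk_exons("B", c(0, 200, 400), c(100, 300, 500)))
  r <- rescue_superchain(singles, supported)
  expect_equal(r$rescued$tx$transcript_id, "A")
  expect_equal(r$superseded_ids, "B")
  ## not a superset: no action
  singles2 <- mk_ann(mk_exons("A", c(0, 200, 600), c(100, 300, 700)))  # introns i1, i3
  supported2 <- mk_ann(mk_exons("B", c(0, 200, 400), c(100, 300, 500)))  # introns i1, i2
  r2 <- rescue_superchain(singles2, supported2)
  expect_equal(nrow(r2$rescued$tx), 0L)
  ## equal chains: not a PROPER superset
  r3 <- rescue_superchain(supported, supported)
  expect_equal(nrow(r3$rescued$tx), 0L)
  ## different strand: no action
  singles4 <- mk_ann(mk_exons("A", c(0, 200, 400, 600), c(100, 300, 500, 700), strand = "-"))
  r4 <- rescue_superchain(singles4, supported)
  expect_equal(nrow(r4$rescued$tx), 0L)
})

test_that("mono-exon consolidation requires all replicates and takes extreme ends", {
  rs <- mk_rs(list(
    rep1 = list(list(tid = "m1", starts = 100, ends = 300, fpkm = 2)),
    rep2 = list(list(tid = "m2", starts = 120, ends = 310, fpkm = 2)),
    rep3 = list(list(tid = "m3", starts = 110, ends = 305, fpkm = 2)),
    rep4 = list(list(tid = "m4", starts = 100, ends = 320, fpkm = 2))))
  m <- consolidate_monoexon(rs)
  expect_equal(m$retained$tx$start, 100L)
  expect_equal(m$retained$tx$end, 320L)
  ## 3 of 4 replicates: dropped
  rs3 <- mk_rs(list(
    rep1 = list(list(tid = "m1", starts = 100, ends = 300, fpkm = 2)),
    rep2 = list(list(tid = "m2", starts = 120, ends = 310, fpkm = 2)),
    rep3 = list(list(tid = "m3", starts = 110, ends = 305, fpkm = 2)),
    rep4 = list()))
  expect_equal(nrow(consolidate_monoexon(rs3)$retained$tx), 0L)
  ## present in all four but one replicate only at FPKM <= 1: dropped
  rs4 <- mk_rs(list(
    rep1 = list(list(tid = "m1", starts = 100, ends = 300, fpkm = 2)),
    rep2 = list(list(tid = "m2", starts = 120, ends = 310, fpkm = 2)),
    rep3 = list(list(tid = "m3", starts = 110, ends = 305, fpkm = 1.0)),
    rep4 = list(list(tid = "m4", starts = 100, ends = 320, fpkm = 2))))
  expect_equal(nrow(consolidate_monoexon(rs4)$retained$tx), 0L)
})

test_that("exhaustive per-chain support enumeration matches the direct rule", {
  ## all 4^4 combinations of {absent, 0.9, 1.0, 2.0} across 4 replicates
  lv <- c(NA, 0.9, 1.0, 2.0)
  combos <- expand.grid(r1 = lv, r2 = lv, r3 = lv, r4 = lv)
  for (i in seq_len(nrow(combos))) {
    fp <- unlist(combos[i, ])
    present <- !is.na(fp)
    if (!any(present)) next
    spec <- lapply(seq_len(4L), function(r) {
      if (!present[r]) list()
      else list(list(tid = paste0("t.r", r), starts = c(0, 300), ends = c(100, 400),
                     fpkm = fp[r]))
    })
    names(spec) <- paste0("rep", 1:4)
    rs <- mk_rs(spec)
    f <- filter_multiexon_support(rs)
    expected <- sum(fp > 1, na.rm = TRUE) >= 2L
    expect_equal(nrow(f$retained$tx) == 1L, expected,
                 info = paste(fp, collapse = ","))
  }
})

test_that("randomized ReplicateSets match the brute-force rule evaluator", {
  for (seed in 1:60) {
    rs <- random_rs(seed)
    f <- filter_multiexon_support(rs)
    ora <- o_multiexon(rs)
    got <- f$retained$tx[order(start), .(start, end)]
    exp <- data.table::as.data.table(ora)[order(lo), .(start = lo, end = hi)]
    expect_equal(as.data.frame(got), as.data.frame(exp), info = paste("seed", seed))

    m <- consolidate_monoexon(rs)
    orm <- o_monoexon(rs)
    gotm <- m$retained$tx[order(chrom, strand, start), .(chrom, strand, start, end)]
    expm <- data.table::as.data.table(orm)[order(chrom, strand, lo),
                                           .(chrom, strand, start = lo, end = hi)]
    expect_equal(as.data.frame(gotm), as.data.frame(expm), info = paste("seed", seed))

    r <- rescue_superchain(f$singletons, f$retained)
    orr <- o_rescue(f$singletons, f$retained)
    expect_setequal(r$rescued$tx$transcript_id, orr$rescued)
    expect_setequal(r$superseded_ids, orr$superseded)
  }
})

test_that("merge collapses identical chains and overlapping mono-exons", {
  a <- mk_ann(mk_exons("t1", c(90, 300), c(200, 410)))
  b <- mk_ann(mk_exons("t2", c(100, 300), c(200, 400)))
  m <- merge_transcript_sets(list(a, b))
  expect_equal(nrow(m$tx), 1L)
  expect_equal(m$tx$start, 90L); expect_equal(m$tx$end, 410L)
  ## mono-exon union
  c1 <- mk_ann(mk_exons("u1", 0, 150))
  c2 <- mk_ann(mk_exons("u2", 100, 250))
  mm <- merge_transcript_sets(list(c1, c2))
  expect_equal(c(mm$tx$start, mm$tx$end), c(0L, 250L))
  ## opposite strands do not merge
  c3 <- mk_ann(mk_exons("u3", 100, 250, strand = "-"))
  expect_equal(nrow(merge_transcript_sets(list(c1, c3))$tx), 2L)
})

test_that("merge is associative and idempotent on random sets", {
  for (seed in 1:25) {
    rs <- random_rs(seed, n_chains = 5L)
    sets <- unname(rs$assemblies)
    m_all <- merge_transcript_sets(sets)
    m_nested <- merge_transcript_sets(list(merge_transcript_sets(sets[1:2]),
                                           merge_transcript_sets(sets[3:4])))
    expect_identical(ann_shape(m_all), ann_shape(m_nested), info = paste("seed", seed))
    ## idempotence
    expect_identical(ann_shape(merge_transcript_sets(list(m_all))), ann_shape(m_all))
  }
})

test_that("monotonicity: raising fpkm_min never grows the retained set", {
  for (seed in 1:15) {
    rs <- random_rs(seed)
    lo <- filter_multiexon_support(rs, fpkm_min = 0.5)
    hi <- filter_multiexon_support(rs, fpkm_min = 2)
    expect_true(all(ann_shape(hi$retained) %in% ann_shape(lo$retained)))
    mlo <- consolidate_monoexon(rs, fpkm_min = 0.5)
    mhi <- consolidate_monoexon(rs, fpkm_min = 2)
    expect_true(all(ann_shape(mhi$retained) %in% ann_shape(mlo$retained)))
  }
})

test_that("the condition transcriptome applies the strict length filter", {
  mk <- function(len) mk_rs(setNames(lapply(1:4, function(r)
    list(list(tid = paste0("t.r", r), starts = 0, ends = len, fpkm = 5))), paste0("rep", 1:4)))
  expect_equal(nrow(build_condition_transcriptome(mk(201))$tx), 1L)
  expect_equal(nrow(suppressWarnings(build_condition_transcriptome(mk(200)))$tx), 0L)
})

test_that("combine_with_reference keeps reference ids and generates novel ids", {
  ref <- mk_ann(mk_exons("ENST1", c(0, 300), c(100, 400), gid = "ENSG1"))
  ## novel transcript with an identical chain -> represented by the reference
  nov <- mk_ann(mk_exons("n1", c(10, 300), c(100, 410)),
                mk_exons("n2", c(5000, 5300), c(5100, 5400)))
  comb <- combine_with_reference(nov, list(ref))
  expect_true("ENST1" %in% comb$tx$transcript_id)
  expect_false(any(c("n1", "n2") %in% comb$tx$transcript_id))
  novel_row <- comb$tx[startsWith(transcript_id, "RTRG.")]
  expect_equal(nrow(novel_row), 1L)
  expect_equal(novel_row$source, "novel")
  expect_true(startsWith(novel_row$gene_id, "RTRG."))
  ## counting: |output| = |reference| + |novel non-matching|
  for (seed in 1:10) {
    rs <- random_rs(seed, n_chains = 5L)
    pred <- merge_transcript_sets(unname(rs$assemblies))
    cls <- classify_transcripts(pred, ref)
    comb2 <- combine_with_reference(pred, list(ref))
    expect_equal(nrow(comb2$tx), nrow(ref$tx) + sum(cls != "exact"))
  }
})

test_that("duplicate reference transcript ids resolve to the first reference", {
  r1 <- mk_ann(mk_exons("T1", c(0, 300), c(100, 400), gid = "G1"))
  r2 <- mk_ann(mk_exons("T1", c(1000, 1300), c(1100, 1400), gid = "G2"))
  nov <- mk_ann(mk_exons("n1", c(7000, 7300), c(7100, 7400)))
  expect_warning(comb <- combine_with_reference(nov, list(r1, r2)), "first occurrence wins")
  expect_equal(sum(comb$tx$transcript_id == "T1"), 1L)
  expect_equal(comb$tx[transcript_id == "T1"]$start, 0L)
})
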