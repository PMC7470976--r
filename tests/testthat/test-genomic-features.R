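test_that("tss_profile matches plateau examples and the bitmap oracle", {
  a <- mk_ann(mk_exons("t1", 50000, 50900))
  peaks <- data.frame(chrom = "chr1", start = 49500, end = 50500)
  pr <- tss_profile(a, c(t1 = 2), peaks, flank = 1000)
  v <- setNames(pr$values, pr$offsets)
  expect_equal(unname(v[c("-500", "0", "499", "500", "-501")]), c(1, 1, 1, 0, 0))
  expect_equal(pr$n_anchors, 1L)
  ## two TSSs, peak covering only the first -> plateau 0.5
  a2 <- mk_ann(mk_exons("t1", 50000, 50900), mk_exons("t2", 70000, 70900))
  pr2 <- tss_profile(a2, c(t1 = 2, t2 = 2), peaks, flank = 1000)
  expect_equal(pr2$values[pr2$offsets == 0], 0.5)
  ## expression filter: keep >= 0.5
  pr3 <- tss_profile(a2, c(t1 = 0.5, t2 = 0.4), peaks, flank = 100)
  expect_equal(pr3$n_anchors, 1L)
  expect_error(tss_profile(a2, c(t1 = 0.1, t2 = 0), peaks), "no expressed TSS")
  ## duplicate TSS positions are deduplicated
  a3 <- mk_ann(mk_exons("x1", 50000, 50900, gid = "g"), mk_exons("x2", 50000, 50500, gid = "g"))
  expect_equal(tss_profile(a3, c(x1 = 2, x2 = 2), peaks, flank = 10)$n_anchors, 1L)

  ## random TSS/peak layouts vs per-base bitmap oracle (incl. minus strand)
  set.seed(5)
  for (r in 1:10) {
    n_t <- sample(2:5, 1)
    tssdf <- data.frame(chrom = "chr1", strand = sample(c("+", "-"), n_t, replace = TRUE),
                        pos = sample(2000:8000, n_t))
    ex <- do.call(rbind, lapply(seq_len(n_t), function(i) {
      if (tssdf$strand[i] == "+") mk_exons(paste0("t", i), tssdf$pos[i], tssdf$pos[i] + 500,
                                           strand = "+")
      else mk_exons(paste0("t", i), tssdf$pos[i] - 500, tssdf$pos[i] + 1, strand = "-")
    }))
    ann <- new_annotation(ex)
    pk <- data.frame(chrom = "chr1",
                     start = sort(sample(1000:9000, 3)))
    pk$end <- pk$start + sample(100:800, 3)
    expr <- setNames(rep(2, n_t), paste0("t", seq_len(n_t)))
    got <- tss_profile(ann, expr, pk, flank = 300)
    dedup <- unique(tssdf)
    expect_equal(got$values, o_tss_profile(dedup, pk, 300), info = paste("seed rep", r))
  }
})

test_that("shuffle_anchors is seed-reproducible and stays on chromosome", {
  anchors <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                        pos = 1:10 * 100, strand = rep(c("+", "-"), 5))
  gl <- c(chr1 = 5000L, chr2 = 8000L)
  s1 <- shuffle_anchors(anchors, gl, seed = 3)
  s2 <- shuffle_anchors(anchors, gl, seed = 3)
  expect_identical(s1, s2)
  expect_identical(s1$chrom, anchors$chrom)
  expect_identical(s1$strand, anchors$strand)
  expect_true(all(s1$pos >= 0 & s1$pos < gl[s1$chrom]))
  expect_false(identical(shuffle_anchors(anchors, gl, seed = 4)$pos, s1$pos))
})

test_that("tts_polya_scan finds planted hexamers at exact offsets", {
  ## plant AATAAA at offset -25 for a plus- and a minus-strand transcript
  g <- strsplit(paste(rep("C", 400), collapse = ""), "")[[1]]
  tts_plus <- 300L                                      # exon [100,301), TTS base 300
  g[(tts_plus - 25 + 1):(tts_plus - 25 + 6)] <- strsplit("AATAAA", "")[[1]]
  tts_minus <- 50L                                      # exon [50,200) on -, TTS base 50
  g[(tts_minus + 25 - 5 + 1):(tts_minus + 25 + 1)] <- strsplit("TTTATT", "")[[1]]
  genome <- c(chr1 = paste(g, collapse = ""))
  a <- mk_ann(mk_exons("p", 100, 301), mk_exons("m", 50, 200, strand = "-"))
  res <- tts_polya_scan(a, genome, window = 100)
  expect_equal(res$profile$values[res$profile$offsets == -25], 1.0)
  expect_equal(sum(res$profile$values), 1.0)            # single spike
  expect_setequal(res$hits$transcript_id, c("p", "m"))
  expect_equal(res$hits$offset, c(-25L, -25L))
  ## no hexamer anywhere -> all-zero profile
  res0 <- tts_polya_scan(a, c(chr1 = paste(rep("G", 400), collapse = "")))
  expect_true(all(res0$profile$values == 0))
  ## regex-position oracle on random genomes
  set.seed(11)
  for (r in 1:10) {
    gen <- c(chr1 = paste(sample(c("A", "T"), 3000, replace = TRUE), collapse = ""))
    ann <- mk_ann(mk_exons("t1", 500, 2500))
    res <- tts_polya_scan(ann, gen, window = 100)
    win <- substr(gen, 2400, 2499)                      # TTS base 2499; window [2399,2499)
    hits <- sort(unique(unlist(lapply(c("AATAAA", "ATTAAA"), function(h) {
      m <- gregexpr(h, win, fixed = TRUE)[[1]]
      if (m[1] == -1) integer() else as.integer(m)
    }))))
    expect_setequal(res$hits$offset, -100 + hits - 1)
  }
})

test_that("splice signatures are read strand-correctly and planted fractions recovered", {
  ## intron [8,20) with GT..AG on plus; the same genomic intron on minus reads CT..AC
  genome <- c(chr1 = "AAAAAAAAGTCCCCCCCCAGTTTTTTTT")
  ap <- mk_ann(mk_exons("p", c(0, 20), c(8, 28)))
  s <- splice_signature_stats(ap, genome)
  expect_equal(unname(s$fractions["GT-AG"]), 1)
  am <- mk_ann(mk_exons("m", c(0, 20), c(8, 28), strand = "-"))
  sm <- splice_signature_stats(am, genome)
  expect_equal(unname(sm$counts["GT-AG"]), 0)
  expect_equal(unname(sm$counts["other"]), 1)           # CT-AC read on minus
  genome2 <- c(chr1 = "AAAAAAAACTCCCCCCCCACTTTTTTTT")   # CT..AC genomic = GT-AG on minus
  expect_equal(unname(splice_signature_stats(am, genome2)$fractions["GT-AG"]), 1)
  expect_equal(sum(splice_signature_stats(ap, genome)$fractions), 1)
  ## planted fraction is recovered exactly on a synthetic genome
  g <- make_genome(21, 2, 100000)
  tr <- make_annotation(g, 21, n_genes = 25, gtag_fraction = 0.9)
  st <- splice_signature_stats(tr$annotation, tr$genome)
  expect_equal(unname(st$fractions["GT-AG"]), tr$signatures$fraction)
  expect_equal(unname(st$counts["GT-AG"] + st$counts["GC-AG"]), st$counts[["GT-AG"]] + st$counts[["GC-AG"]])
  expect_equal(sum(st$fractions), 1)
})

test_that("te_overlap removes non-TE repeats and matches the bitmap oracle", {
  a <- mk_ann(mk_exons("t1", 0, 100))
  te <- data.frame(chrom = "chr1", start = 0, end = 50, name = "LINE/L1")
  expect_equal(te_overlap(a, te)[family == "all_TE"]$fraction, 0.5)
  ## overlap only with a simple repeat -> 0
  sr <- data.frame(chrom = "chr1", start = 0, end = 50, name = "Simple_repeat")
  expect_equal(te_overlap(a, sr)[family == "all_TE"]$fraction, 0)
  expect_equal(is_te(c("LINE/L1", "Low_complexity", "Satellite", "Simple_repeat", "LTR/ERVL-MaLR")),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  ## splitting a TE interval into abutting pieces changes nothing
  te2 <- data.frame(chrom = "chr1", start = c(0, 20), end = c(20, 50),
                    name = c("LINE/L1", "LINE/L1"))
  expect_equal(te_overlap(a, te2)[family == "all_TE"]$fraction, 0.5)
  ## random layouts vs per-base oracle
  set.seed(13)
  for (r in 1:10) {
    g <- make_genome(400 + r, 1, 50000)
    tr <- make_annotation(g, 400 + r, n_genes = 8, mono_fraction = 0.3)
    reps <- make_repeats(tr, 400 + r, n_te = 15, n_non_te = 5)
    got <- te_overlap(tr$annotation, reps)[family == "all_TE"]$fraction
    expect_equal(got, o_te_fraction(tr$annotation, as.data.frame(reps[is_te(name)])),
                 info = paste("rep", r))
  }
})
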