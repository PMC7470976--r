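## canonical two-isoform gene builder on one chromosome/strand
pair_ann <- function(ex1_starts, ex1_ends, ex2_starts, ex2_ends, strand = "+") {
  mk_ann(mk_exons("t1", ex1_starts, ex1_ends, strand = strand, gid = "g"),
         mk_exons("t2", ex2_starts, ex2_ends, strand = strand, gid = "g"))
}

test_that("each canonical AS pattern receives its label", {
  ## SE
  a <- pair_ann(c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500))
  ev <- classify_pair(a, "t1", "t2")
  expect_equal(ev$type, "SE")
  expect_equal(c(ev$lo, ev$hi), c(200L, 300L))          # skipped exon coordinates
  ## IR
  b <- pair_ann(c(0, 200), c(100, 300), 0, 300)
  expect_equal(classify_pair(b, "t1", "t2")$type, "IR")
  ## A5SS on + (donor side differs, acceptor shared)
  c1 <- pair_ann(c(0, 200), c(100, 300), c(0, 200), c(80, 300))
  expect_equal(classify_pair(c1, "t1", "t2")$type, "A5SS")
  ## A3SS on + (acceptor side differs, donor shared)
  c2 <- pair_ann(c(0, 200), c(100, 300), c(0, 230), c(100, 300))
  expect_equal(classify_pair(c2, "t1", "t2")$type, "A3SS")
  ## MXE (spec pattern)
  d <- pair_ann(c(0, 200, 500), c(100, 300, 600), c(0, 350, 500), c(100, 450, 600))
  expect_equal(classify_pair(d, "t1", "t2")$type, "MXE")
  ## AFE on +: disjoint first exons sharing the downstream acceptor
  e <- pair_ann(c(0, 200), c(50, 300), c(100, 200), c(160, 300))
  expect_equal(classify_pair(e, "t1", "t2")$type, "AFE")
  ## ALE on +: disjoint last exons sharing the upstream donor
  f <- pair_ann(c(0, 200), c(100, 260), c(0, 300), c(100, 380))
  expect_equal(classify_pair(f, "t1", "t2")$type, "ALE")
})

test_that("strand awareness mirrors donor/acceptor and first/last-exon labels", {
  ## the A5SS(+) pattern is A3SS on the minus strand
  m1 <- pair_ann(c(0, 200), c(100, 300), c(0, 200), c(80, 300), strand = "-")
  expect_equal(classify_pair(m1, "t1", "t2")$type, "A3SS")
  m2 <- pair_ann(c(0, 200), c(100, 300), c(0, 230), c(100, 300), strand = "-")
  expect_equal(classify_pair(m2, "t1", "t2")$type, "A5SS")
  ## SE is strand-invariant
  m3 <- pair_ann(c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500), strand = "-")
  expect_equal(classify_pair(m3, "t1", "t2")$type, "SE")
  ## AFE(+) pattern becomes ALE on minus
  m4 <- pair_ann(c(0, 200), c(50, 300), c(100, 200), c(160, 300), strand = "-")
  expect_equal(classify_pair(m4, "t1", "t2")$type, "ALE")
})

test_that("non-events and degenerate cases yield no events", {
  ## identical chains with different terminal ends
  a <- pair_ann(c(0, 200), c(100, 300), c(20, 200), c(100, 350))
  expect_equal(nrow(classify_pair(a, "t1", "t2")), 0L)
  ## mono-exon vs mono-exon length difference
  b <- pair_ann(0, 300, 50, 400)
  expect_equal(nrow(classify_pair(b, "t1", "t2")), 0L)
  ## extra upstream exon without exonic coverage of the intron: end difference
  c1 <- pair_ann(c(0, 200), c(100, 300), 200, 300)
  expect_equal(nrow(classify_pair(c1, "t1", "t2")), 0L)
  ## different strands error
  d <- mk_ann(mk_exons("t1", 0, 100, strand = "+", gid = "g"),
              mk_exons("t2", 0, 100, strand = "-", gid = "g"))
  expect_error(classify_pair(d, "t1", "t2"), "strand")
  ## symmetry: classify_pair(t1,t2) == classify_pair(t2,t1)
  a2 <- pair_ann(c(0, 200, 400), c(100, 300, 500), c(0, 400), c(100, 500))
  e12 <- classify_pair(a2, "t1", "t2"); e21 <- classify_pair(a2, "t2", "t1")
  expect_identical(e12$key, e21$key)
})

test_that("gene_events deduplicates identical bubbles across isoform pairs", {
  a <- mk_ann(mk_exons("t1", c(0, 200, 400), c(100, 300, 500), gid = "g"),
              mk_exons("t2", c(0, 400), c(100, 500), gid = "g"),
              mk_exons("t3", c(10, 400), c(100, 520), gid = "g"))   # same chain as t2
  ev <- gene_events(a, "g")
  expect_equal(nrow(ev), 1L)                 # the SE bubble appears once
  expect_equal(ev$type, "SE")
  ## SE and IR in one gene at separated slots
  b <- mk_ann(mk_exons("t1", c(0, 200, 400, 600, 800), c(100, 300, 500, 700, 900), gid = "g"),
              mk_exons("t2", c(0, 400, 600, 800), c(100, 500, 700, 900), gid = "g"),
              mk_exons("t3", c(0, 200, 400, 600), c(100, 300, 500, 900), gid = "g"))
  evb <- gene_events(b, "g")
  expect_setequal(evb$type, c("SE", "IR"))
  ## single isoform -> empty
  s <- mk_ann(mk_exons("t1", 0, 300, gid = "g"))
  expect_equal(nrow(gene_events(s, "g")), 0L)
})

test_that("emitted labels always satisfy their structural predicates (grid enumeration)", {
  ## a coarser grid than the acceptance run (which enumerates 12 sites)
  sites <- seq(0L, 80L, by = 10L)
  one_intron <- utils::combn(sites, 2L)
  chains <- lapply(seq_len(ncol(one_intron)), function(i) one_intron[, i, drop = FALSE])
  ## all 1-intron vs 1-intron pairs over the 12-point grid, both strands
  mkpair <- function(c1, c2, strand) {
    tx <- function(tid, ch) {
      bounds <- c(-20L, as.vector(ch), 130L)
      starts <- bounds[seq(1L, length(bounds), 2L)]
      ends <- bounds[seq(2L, length(bounds), 2L)]
      mk_exons(tid, starts + 20L, ends + 20L, strand = strand, gid = "g")
    }
    new_annotation(rbind(tx("t1", c1), tx("t2", c2)))
  }
  n_checked <- 0L
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (i == j) next
    a <- mkpair(matrix(chains[[i]], ncol = 1), matrix(chains[[j]], ncol = 1), "+")
    ev <- classify_pair(a, "t1", "t2")
    for (r in seq_len(nrow(ev))) {
      expect_true(as_event_ok(ev[r]), info = paste(i, j, ev$type[r]))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 1000L)
  ## random 2-3 intron chains, both strands
  set.seed(17)
  for (r in 1:120) {
    strand <- sample(c("+", "-"), 1)
    pick <- function() {
      k <- sample(2:3, 1)
      matrix(sort(sample(sites, 2L * k)), nrow = 2L)
    }
    c1 <- pick(); c2 <- pick()
    a <- mkpair(c1, c2, strand)
    ev <- classify_pair(a, "t1", "t2")
    for (rr in seq_len(nrow(ev)))
      expect_true(as_event_ok(ev[rr]), info = paste(r, ev$type[rr]))
    ## event coordinates lie within the union of spans
    if (nrow(ev)) {
      expect_true(all(ev$lo >= min(a$tx$start) & ev$hi <= max(a$tx$end)))
    }
  }
})

test_that("event_distribution recovers planted event counts exactly", {
  for (seed in c(31, 32, 33)) {
    g <- make_genome(seed, 2, 150000)
    tr <- make_annotation(g, seed, n_genes = 30, isoform_dist = c(0.3, 0.4, 0.3))
    d <- event_distribution(tr$annotation)
    planted <- table(factor(tr$events$type, levels = retra:::AS_TYPES))
    expect_equal(as.integer(d$counts), as.integer(planted), info = paste("seed", seed))
    expect_equal(d$n_complex, 0L)
  }
  ## all-single-isoform annotation -> empty distribution
  g <- make_genome(34, 1, 60000)
  tr1 <- make_annotation(g, 34, n_genes = 8, isoform_dist = 1)
  expect_true(all(event_distribution(tr1$annotation)$counts == 0L))
  ## 1 SE + 1 IR -> 50/50 percentages
  b <- mk_ann(mk_exons("t1", c(0, 200, 400), c(100, 300, 500), gid = "g1"),
              mk_exons("t2", c(0, 400), c(100, 500), gid = "g1"),
              mk_exons("u1", c(5000, 5200), c(5100, 5300), gid = "g2"),
              mk_exons("u2", 5000, 5300, gid = "g2"))
  db <- event_distribution(b)
  expect_equal(unname(db$percentages[c("SE", "IR")]), c(50, 50))
})
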