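---
title: "Methods: consolidation rules, conservation testing and the synthetic world"
author: "retra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consolidation rules, conservation testing and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`retra` re-implements, as a reusable toolkit, the computational stages that
turn per-replicate genome-guided transcript assemblies into a re-annotated
transcriptome, and the downstream analyses used to validate one: coding
potential, splice-junction conservation, TSS/TTS signals, repeat content,
alternative-splicing events and expression-presence patterns.  Upstream
read alignment and assembly are out of scope: the input unit is an
assembled transcript model (a GTF with per-transcript FPKM), not reads.

All internal coordinates are 0-based half-open.  GTF (1-based inclusive)
converts at the I/O boundary; BED passes through unchanged.  A single
arithmetic convention in every module is the cheapest defence against
off-by-one drift between interval operations.

# Consolidation rules

Transcript identity across replicates is the *exact intron chain*
(chromosome + strand + ordered intron intervals).  Terminal exon ends vary
between assemblies of the same transcript, so they are excluded from the
identity and instead resolved to the extreme observed boundaries.
Mono-exon transcripts have no chain; they are matched by single-linkage
genomic overlap on the same strand, because assemblies report "copies"
with jittered ends.

The rules, with their thresholds read as strict inequalities exactly as
printed in the field's protocols:

* multi-exon: keep a chain iff ≥ `min_reps` (2) distinct replicates carry
  a copy with FPKM > `fpkm_min` (1).  A missing FPKM is *unknown*, not
  zero: the copy counts as non-passing and a warning is logged.
* rescue: a chain seen in exactly one replicate whose intron set is a
  **proper** superset of a supported novel chain's intron set (same
  chromosome and strand, strictly more exons) replaces that chain.
  Intron-set inclusion is exact interval identity — the only reproducible
  reading.  One pass only; rescued transcripts do not seed further rescues
  (chaining is undefined in the source protocol, so the simplest behavior
  is chosen and documented here).
* mono-exon: keep a cluster iff **every** replicate contributes a copy
  with FPKM > 1; boundaries are the leftmost/rightmost observed ends.
* merge: identical chains collapse (extreme boundaries); overlapping
  same-strand mono-exons collapse to their union.  The operation is
  associative and idempotent, so "merge per condition, then across
  conditions, then across assemblers" is just repeated application.
* length: keep transcripts with summed exon length > 200.

Gene construction is never specified by merge tools' documentation in a
reproducible way, so `retra` defines it: single-linkage clustering of
transcripts sharing ≥ 1 bp of exonic overlap on the same strand.  FPKM is
carried through merges as the per-sample maximum and labelled carried, not
re-estimated.

When assembled transcripts are combined with reference annotations,
reference entries always win: an assembled transcript whose chain matches
a reference transcript exactly is represented by the reference id; the
rest become novel entries with generated ids (`RTRG.<gene>.<k>`), and
gene ids are preserved from the references wherever a rebuilt cluster
contains a reference transcript.

# Comparison and summary statistics

Match classes are ordered exact > contained (contiguous sub-chain) >
novel isoform (shares ≥ 1 junction) > other; precision defaults to
exact-chain matching for multi-exon queries and containment-within-an-
exon-overlapping-transcript for mono-exon queries, and is configurable
because "matched" is underspecified in common usage.  "Transcribed
region" is the union of full transcript spans (introns included) and
"exon region" the union of exons, both strand-blind; this reproduces the
characteristic exon-ratio ≪ transcribed-ratio pattern of annotation
summary tables.  Exon number counts distinct (chrom, start, end, strand)
coordinates, not exon records, so shared exons across isoforms count
once; the record-count alternative is a flag.

# Coding-potential consensus

Three independent evidence channels: a coding score (CPAT-style), domain
hits (Pfam-style) and protein-database hits (BLASTx-style 12-column
tabular).  A transcript is coding with high confidence iff
score > cutoff **and** ≥ 1 domain **and** best hit e-value < 1e-5; noncoding
with high confidence iff all three fail; ambiguous otherwise (6 of the 8
combinations).  Unknown evidence fails closed.  The score cutoff has no
universal value — the default 0.364 is a published convention for a
related rodent model — so it is a visible parameter echoed into every
report, never a silent default.  "High similarity" is operationalized
purely as the e-value threshold; identity is recorded but not
thresholded, because no identity cutoff is printed anywhere in the
protocol being reproduced.

# Junction conservation

For each junction of a multi-exon transcript the spliced context is the
last k = 6 exonic bases of the upstream exon plus the first 6 of the
downstream exon, strand-corrected to transcript orientation.  When the
junction lies inside an annotated CDS and ≥ 3 nt from its edges, the
window is extended outward to whole codons and translated; the window
never includes the stop codon (peptides feed a protein aligner whose
alphabet has no stop).  Junctions closer than 3 nt to a CDS edge fall
back to nucleotide mode.

The aligner is a built-in Needleman–Wunsch/Gotoh implementation under
EMBOSS-needle conventions: DNA +5/−4 (N scores −2), protein BLOSUM62, a
gap of length L costing `gap_open + L·gap_extend` (10 and 0.5 by
default), end gaps penalized, and deterministic traceback (diagonal over
gap-in-second over gap-in-first).  The tool being emulated names no
parameters, so these defaults are stated rather than assumed, and all are
arguments.

An alignment is rejected when it has more than one gap **column** in the
12-nt window (the window *is* "close" to the junction; counting gap
openings instead is not implemented because the column reading is
stricter and unambiguous), when nucleotide identity < 80%, or in protein
mode when identity < 80% or similarity < 90%.  Similarity uses exactly
five residue groups — aliphatic I/L/V, aromatic F/Y/W/H, positive H/K/R,
negative D/E, tiny A/C/T/S/G; H is in two groups; unlisted residues
(M, N, Q, P) are similar only to themselves.  A junction is conserved iff
at least one homolog context survives.  Homology mapping itself is an
input, not computed.

# Feature analyses

* TSS metaprofile: unique (chrom, position, strand) TSSs of transcripts
  with FPKM ≥ 0.5 (the two printed forms of this filter disagree at
  exactly 0.5; keeping ≥ is the documented choice), windows of ± 10 kb
  flipped to transcript orientation on the minus strand, binary per-base
  in-peak coverage, normalized by the number of anchors.  A shuffled
  control re-draws each anchor uniformly on its own chromosome under an
  explicit seed.
* TTS polyA scan: the 100 genomic bases upstream of each TTS in
  transcript orientation are scanned for AATAAA/ATTAAA; the profile is
  the fraction of transcripts with a hexamer *starting* at each offset
  (so hits live in −100..−6).
* Splice signatures: donor = first two intronic bases, acceptor = last
  two, strand-corrected; tallied over unique junctions into GT-AG, GC-AG,
  AT-AC, other.
* TE overlap: repeat records whose class matches low-complexity,
  satellite or simple repeats are removed first.  The fraction is the
  per-transcript exon/TE base overlap summed over transcripts, divided by
  the summed transcript length.  (A union numerator over a summed
  denominator would be inconsistent when isoforms share exons; the
  summed/summed definition matches the "divide overlap by total length of
  transcripts" phrasing.)

# Alternative-splicing events

Isoform pairs are compared by bubble decomposition: the genome axis is cut
at splice sites present in both transcripts, and each segment where the
intron chains disagree is a variation bubble.  Bubbles are matched against
structural patterns — SE (two introns vs one sharing outer boundaries,
with the skipped exon in between), IR (one intron vs exonic coverage),
A5SS/A3SS (single introns sharing one boundary; the donor side is
strand-aware), MXE (2 vs 2 introns sharing outer boundaries with disjoint
internal exons), and AFE/ALE (terminal bubbles sharing one internal splice
site with disjoint terminal exons).  Anything else is "complex" and is
reported separately but excluded from the seven-way tally: forcing a
nested or multi-way bubble into one category would misclassify it, and the
full event grammar of dedicated AS tools is out of scope.  Pure 5′/3′-end
length differences are not events.  The event unit is the unique bubble
per gene (pairwise events deduplicated by type + variant coordinates);
whether published event tallies deduplicate per gene is typically
unstated, so the choice is explicit here.

# Expression rules

A feature is expressed in a biological condition — a (tissue, stage) pair,
sexes pooled by default because a 11 × 4 condition grid pools them; a flag
splits by sex — iff > 0.5 FPKM in ≥ 2 of its samples, strictly.  Tissue
expression is the OR over the tissue's stages.  Housekeeping features are
expressed in every tissue; tissue-unique features in exactly one.
"Expresses different isoforms among tissues" is operationalized as
dominant-isoform switching: the dominant isoform of a gene in a tissue is
the one with the highest mean FPKM over the tissue's samples (ties broken
by smallest transcript id and flagged), and a gene is reported iff its
dominant isoform differs between two tissues where it is expressed.  The
source material cites external work without a formula here, so the
definition is a package decision, printed in the report header.

# The synthetic world

The generators produce every input the toolkit consumes, with planted
ground truth, from one master seed (fanned into per-component child seeds
so one component's configuration does not perturb another's stream).
Defaults mirror the stated world of the emulated study: 4 biological
replicates per condition, an 11-tissue × 4-stage × 2-sex design, FPKM > 1
and > 0.5 thresholds, 97% GT-AG junctions, polyA hexamers 10–40 nt
upstream of TTSs, ORFs ≥ 100 codons on coding transcripts.  FPKM noise is
log-normal (meanlog 1, sdlog 0.8 by default — a right-skewed law with
most mass above the FPKM = 1 threshold); the rules under test depend only
on threshold crossings, so the law's exact shape is non-critical.
Replicate assemblies jitter terminal exon ends by up to ±10 bp (intron
chains untouched), emulating assembler end variability; dropout is
per-transcript per-replicate.

What a green test does and does not establish: the generator plants one
AS event per extra isoform at separated intron slots, writes splice
dinucleotides per unique donor site, and keeps expression plants strictly
on the passing/failing side of each threshold.  Real data violate all of
this — overlapping genes, shared junctions between genes, expression
hovering at thresholds, truncated assemblies — so recovery of planted
truth validates the *rules*, not performance on real libraries.  Two
deliberate consequences: the realized GT-AG fraction is `round(f·n)/n`
over the n unique junctions (the acceptance fixture uses 100 four-exon
single-isoform genes so that n = 300 and the fraction is exactly 0.97),
and homolog contexts are pooled per gene, so a non-conserved junction can
occasionally match a sibling junction's conserved context — planted
conservation rates are recovered within binomial error, exactly only at
rate 1.

# Numerical and testing choices

Degenerate inputs fail loudly: empty predicted sets make precision an
error, zero expressed TSSs make the metaprofile an error, single-isoform
genes yield empty event lists, all-single-isoform annotations report the
multi-isoform mean as NA.  Strand "." is accepted on input but excluded
from strand-dependent operations with a warning.

The test suite checks every operation against independent oracles that
share no code with the implementation: direct rule evaluators for the
consolidation filters (including the complete 4⁴ grid of per-replicate
presence/FPKM patterns around both strict-inequality boundaries), a
recursive memoized DP for the aligner, per-base bitmaps for unions,
coverage and TE overlap, and structural predicates for every emitted AS
label over a 12-point splice-site grid.  One stated enumeration is scaled
down for runtime: exhaustive alignment pairs run at length ≤ 5 over a
2-letter alphabet (3 844 pairs) rather than ≤ 8 (260 000), topped up with
300 random longer pairs in both scoring modes.

# Known limitations

No GFF3 or BAM input; FPKM is consumed, never computed; ortholog mapping
is an input; the AS grammar covers the seven canonical patterns plus an
explicit "complex" bucket; differential expression and differential
splicing are out of scope; mono-exon matching by overlap clustering can
chain distinct loci bridged by a long copy (inherent to single-linkage);
rescue is single-pass; FPKM after merging is carried, not re-estimated.
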