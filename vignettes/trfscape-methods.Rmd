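---
title: "Calling and profiling tRNA-derived fragments with trfscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and profiling tRNA-derived fragments with trfscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfscape)
```

## The model

A tRNA-derived fragment (tRF) is a contiguous piece of a *mature* tRNA:
the strand-resolved, intron-free gene body with the post-transcriptional
`CCA` tail. `trfscape` models fragment calling as exact substring matching
of 25–45 nt unique reads against mature tRNA sequences, with three
structural commitments:

* **Exactness.** A read is a fragment of a tRNA only if it matches a
  mature sequence with no mismatches and no gaps. Exact matching is
  deterministic, parameter-free, and checkable against a brute-force
  enumeration oracle (the test suite does exactly that); a hook for an
  external mismatch-tolerant aligner exists but is off by default.
* **CCA awareness.** Eukaryotic genomes do not encode the tail, so a read
  carrying `CCA` can be genomic nowhere yet still be a genuine 3'-anchored
  fragment. A hit is accepted either entirely within the genomic part of
  the mature sequence or flush against its 3' end (tail "masked");
  fragments ending *inside* the tail (a dangling `C`/`CC`) are rejected by
  default (`cca_partial = FALSE`) because a partial tail cannot be
  distinguished from a truncated read.
* **Compartment precedence.** Reads are confronted with the mitochondrial
  compartment first; *any* mitochondrial occurrence — tRNA or not —
  consumes the read, and only unclaimed reads proceed to the nuclear
  contigs. This mirrors the serial mapping design of the reference
  analysis and makes the assignment unambiguous when compartments share
  subsequences.

Nuclear candidates then pass three removal rules: (a) reads that also
occur at any non-tRNA genomic locus (either strand; a read antisense to a
tRNA gene counts as non-tRNA, since fragments derive from the sense mature
molecule); (b) reads mappable to a tRNA gene with polymorphic sites;
(c) reads mappable to genes of two or more distinct anticodons. Rule (a)
and (c) are nuclear-side rules by default (`footnote_a_mito`,
`footnote_c_mito`): the mitochondrial genome is small and single-copy, so
cross-locus ambiguity is a nuclear phenomenon, but within-mitochondrial
multi-anticodon hits are still dropped. For rule (b) the default
(`poly_mode = "any"`) removes a read as soon as any parent is polymorphic;
`"only"` instead discards the polymorphic parents and keeps the read if a
clean parent remains. Reads matching several same-anticodon subtypes
(isodecoders) are kept, attributed to every parent, and counted once in
their anticodon's total.

## Region classification

The mature tRNA is anchored at the anticodon: the anticodon loop is the
7-nt window `anticodon ± 2`, and the anticodon stem-loop extends it by the
stem width `S` (default 5 bp) on each side. A fragment span is classified
in a fixed decision order — 5' half, 3' half, 5' end, 3' end, AC
stem-loop, other — with three tolerances:

* `t5`, `t3` (default 2 nt): how far inside a terminus a fragment may
  start/end and still count as anchored. Published fragment alignments
  show variants starting a few nucleotides inside the terminus grouped
  with the terminal classes, so 0 would be too strict; the value is
  configurable.
* `w` (default 5 nt): slack around the stem-loop window for the unanchored
  class. This default is a deliberate geometric choice: with the loop at
  31–37 and `S = 5` the strict window is 26–42 (17 nt), and a slack of 3
  admits spans of at most 23 nt — shorter than any read in the 25–45 nt
  calling range, which would make the class structurally empty. `w = 5`
  is the smallest slack that admits the shortest legal reads (25–27 nt)
  while still requiring them to be centered on the anticodon.

Spans that fit no rule (e.g. 5'-anchored but overrunning the loop) are
reported as "other", never silently dropped. Per anticodon, the "main
region" label reports every category holding at least `f = 25%` of the
pooled reads, most abundant first, joined by `" and "`; 25% reproduces the
one- and two-label style of published summaries on plausible mixtures and
is configurable. Ties are broken by the fixed category order.

## Normalization, coverage and trends

Per-stage scaling uses the two spike-in RNAs: `factor_s = K / spikesum_s`
with `K` the geometric mean of the six per-stage spike sums. The
geometric-mean anchor makes factors scale-free (they multiply to 1), and
within-stage ratios between any two fragments are untouched by
construction; fixed-constant and first-stage anchors are available where
absolute units matter. A zero spike sum in any stage is an error — there
is nothing to scale by.

Positional coverage of a parent at position *p* sums the normalized counts
of fragments covering *p*, CCA positions included; the column sums
therefore equal normalized count × span length summed over fragments, a
conservation law the tests assert. Heatmap rows are the top-3 variants per
anticodon (ties broken lexicographically by sequence, so output is stable)
divided by the row maximum; all-zero rows stay zero and are flagged. Rows
are clustered with average linkage on 1 − uncentered correlation — the
defaults of the Cluster 3.0 program that stage-resolved fragment studies
conventionally use — with centered Pearson available as an option.

Developmental trends operationalize three qualitative classes over the six
ordered stages. Increasing/decreasing are Spearman rank correlation with
stage index beyond ±0.8. Egg enrichment (egg > 50% of the variant's
total) is evaluated first, with one carve-out: any clean stage-halving
series concentrates over half its mass in the egg, so a majority-egg
series is still called *decreasing* when it declines smoothly — rank
correlation ≤ −0.8 *and* some later stage retains at least 25% of the egg
signal. A sharp post-egg collapse (later stages all below a quarter of
the egg) stays egg-enriched however well-ordered its tail noise happens
to be. These thresholds are this package's operationalization of
qualitative published classes, not measured constants; all three are
arguments of `expression_trend()`.

## Catalog curation choices

* Records with begin > end are minus-strand genes with normalized
  intervals. Coordinates are 1-based inclusive everywhere.
* "Polymorphic" genes are those the annotation marks as such, plus pairs
  of genes at overlapping same-strand loci (two unresolved alleles); both
  copies are flagged.
* Genes within `E = 5` nt of a contig boundary are removed as likely
  truncated models; no published value exists for this margin, so it is a
  configurable package choice.
* Nuclear loci reported only by the eukaryotic covariance-model search are
  retained: the eukaryotic-vs-bacterial score rule is a comparison and is
  only defined where both searches report the locus. Mitochondrial genes
  come from the organellar search and bypass the comparison.
* The anticodon's mature position is not part of tRNAscan-SE tabular
  output; it is located as the occurrence of the anticodon triplet whose
  center is closest to cloverleaf position 34 (leftmost on ties), scanning
  overlapping occurrences so homopolymeric anticodons (e.g. CCC) cannot be
  skipped.

## Read filtering choices

The quality rule "Phred < 20" is applied to the read's *mean* base quality
by default (`quality_mode = "mean"`), the common small RNA convention when
a single per-read threshold is reported; a min-base mode is provided. The
"fewer than five times" abundance rule is applied to the count pooled
across all six libraries (`per_stage = FALSE`), matching the reporting of
a single unique-read total across stages; a per-stage mode is provided.
The abundance and length filters are pure per-read predicates and commute;
the filter report accounts for every rejected read by reason, at both the
unique-sequence and read level. Adapter trimming is assumed done upstream.

## What the synthetic generator emulates — and what it does not

`generate_genome()`/`simulate_reads()` emulate the *structure* of the
study design: six stage libraries; a small mitochondrial genome and
several nuclear contigs hosting 70–76 nt tRNA genes with the anticodon at
mature 33–35 (so the region map is unambiguous and the classifier
exhaustively testable); isodecoder subtypes differing by one substitution
outside the anticodon; a decoy (an unannotated exact copy of a gene body
in non-tRNA context, exercising removal rule a); a polymorphic-flagged
gene (rule b); a pseudogene and a contig-boundary gene (curation); a
locus scoring higher under the bacterial model (score comparison); two
spike-ins planted at different per-stage counts so normalization factors
are nontrivial; and per-anticodon fragmentation profiles — a dominant
region holding 70% of reads, cycled through the five categories, plus a
developmental trend (doubling, halving, egg-concentrated, flat) shaping
stage budgets. Defaults are the package's study conditions: 20
fragment-bearing anticodons, 10,000 fragment reads, 5% noise, and small
planted doses of N-containing, low-quality, too-short/too-long and
below-abundance reads.

The truth table records an intended fate per read and is exact by
construction: fragment sequences whose sampled pooled count falls under
the abundance threshold are recorded as `below_threshold` (the filter
runs before mapping, so that fate takes precedence over what the read's
parents would imply), and decoy ambiguity is determined by an actual
substring check against the planted copy — a 3'-anchored read ending in
`CCA` is *not* absorbed by a decoy, because the copy, like the genome,
lacks the tail. Intergenic filler never begins with `C` or ends with `G`,
so a genomic gene body can never be accidentally extended into a flush
`CCA` (or antisense `TGG`) context that would create spurious non-tRNA
occurrences of 3'-anchored reads.

Deliberately *not* modeled: sequencing substitution errors (calling is
exact, so an error model would only shrink recoverable counts),
modification-induced misincorporation at modified tRNA positions (a real
phenomenon that depresses 3'-fragment recovery in real libraries), miRNA /
piRNA background beyond unmappable noise, and realistic tRNA secondary
structure beyond the anticodon-anchored region map. Passing the planted
recovery tests therefore demonstrates the pipeline's bookkeeping and
filtering logic, not robustness to the error structure of real reads.

## Numerical and degenerate-input behavior

Everything is deterministic: generation is a pure function of the config
seed; calling output is invariant to read and catalog order (tests
permute both); reruns of a pipeline config reproduce every output table
byte for byte, and the manifest records seed and config hash. Degenerate
inputs fail loudly: an anticodon too close to a terminus for the loop to
fit, a gene interval out of contig bounds, a stage with zero spike reads,
a span outside the mature sequence, malformed annotation rows (with line
number). Empty inputs flow through: empty catalogs yield zero calls with
every read unassigned; an empty fragment table yields an empty two-section
report with zero headers; clustering fewer than two rows returns the
identity ordering.

## Problem sizes used by the test suite

The suite verifies oracle equivalence of the calling path on 220 random
instances (small bundles of 2 mitochondrial + 4 nuclear anticodons and
40 adversarial reads each — mature spans, CCA and partial-tail suffixes,
contig windows, decoy windows, antisense and random reads), classifies
all ~860 legal spans of a 75-nt tRNA against an independent predicate
table, and runs the full pipeline at the default scale (10,000 fragment
reads) comparing against the truth table exactly. These sizes were chosen
so the entire suite exercises every rule densely while remaining quick to
run during development.

## Known limitations

* Exact matching cannot call fragments from tRNAs with post-transcriptional
  edits or sequencing errors inside the fragment; counts are conservative.
* Region calls use the first (lexicographically smallest) parent of a
  multi-subtype read; subtypes at different lengths could in principle
  disagree on the category, though same-anticodon subtypes rarely do.
* The eukaryotic-vs-bacterial score rule keeps euk-only loci; if a
  bacterial-only contaminant tRNA were real, it would be invisible here.
* The trend classifier sees exactly six points; it is a labeling rule,
  not a test with error control.
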