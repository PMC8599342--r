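---
title: "Screening candidate reprogramming factors from chromatin accessibility and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate reprogramming factors from chromatin accessibility and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacscreen)
```

## The screen

`atacscreen` implements a two-axis screen for transcription factors that
plausibly drive a cell state. Given ATAC-seq tag alignments from two cell
states (for example a pluripotent line and a somatic cell type) and an
RNA-seq count matrix over the same states, the screen asks, for each TF in
a motif library:

1. **Chromatin axis** — is the TF's DNA-binding motif over-represented in
   the open-chromatin peaks *specific* to the target state, relative to
   the peaks specific to the other state?
2. **Expression axis** — is the TF gene itself highly expressed in the
   target state relative to the other state?

A TF passing both filters is a `candidate`. A TF whose motif is enriched
but whose expression is flat is kept as `motif_only` — the pattern typical
of TF families that share a binding motif, where accessibility alone
cannot distinguish the expressed family members from the silent ones; the
expression axis does that separation. The remaining verdicts are
`expression_only` and `rejected`.

## Stage by stage

### Tag filtering and coverage

Tags are filtered per replicate before any merging:

* **Mapping quality**: tags with MAPQ < 35 are removed; the boundary
  value 35 is kept, matching the semantics of `samtools view -q 35`.
* **Mitochondrial removal**: name-based (`chrM` by default) — ATAC
  libraries carry heavy mitochondrial contamination and the
  mitochondrial genome has no regulatory chromatin of interest here.
* **Deduplication**: one tag per `(chromosome, start, end, strand)` key,
  first occurrence kept. Tags at the same position on opposite strands
  are distinct. Deduplication is per replicate; replicates are then
  concatenated and coordinate-sorted *without* re-deduplication, because
  identical positions in different biological replicates are
  reproducible signal, not PCR artifacts.

Coverage tracks are scaled to reads per ten million:
`scale = 10^7 / total_unique_reads`, so the genome-wide track integral
equals `scale × Σ tag lengths` exactly — a conservation property the test
suite checks to 10^-6 relative error. Signal-level replicate averaging
(`mean_coverage()`) is provided as an alternative to read-level merging
and is flagged in the track metadata; the pipeline default is read-level
merging, and peak statistics are calibrated for it.

### Peak calling

The caller is deliberately simple and fully specified, because the
screen's logic needs *a* consistent caller rather than any particular
sophisticated one: coverage is binned (100 bp), bin mass is converted to
an estimated tag count (bin mass / mean tag length, so the statistic is
approximately Poisson), smoothed with a centred 3-bin moving average, and
thresholded at the `1 - 10^-6` Poisson quantile of the genome-wide mean
bin count. Super-threshold runs closer than 200 bp are merged; runs
shorter than 200 bp are dropped; each peak is scored by its maximum
smoothed bin count. All five settings are exposed in `screen_config()`
and logged in the run report. With roughly 10^3–10^4 bins per genome and
a 10^-6 tail, the expected number of false bins per run is of order
10^-2–10^-3, which the suite verifies as "at most 1 false peak per Mb"
under a planted-null simulation.

Smoothing width is a free parameter: 3 bins gives one bin of bleed on
each side of a signal block, which the minimum-width filter absorbs.

### Peak classification and gene linkage

"Open in A but closed in B" is operationalized as *peak-set membership*:
a peak of A is A-specific iff no peak of B overlaps it by at least
`min_overlap` bases (default 1; a reciprocal-fraction mode is available
via `min_frac`). This is a deliberate design choice: the comparison is
between peak sets, not a quantitative count-based differential test,
which is out of scope. Intervals are half-open at the BED level, so
peaks that merely touch do not overlap.

Genes are linked to peaks when the TSS lies within 10 kb of the peak
(inclusive bound, distance 0 inside the peak, otherwise base distance to
the nearest peak edge).

### Motif model and enrichment statistic

Motifs are position weight matrices scored as summed log2 odds against a
uniform background; both strands are scanned, the reverse strand on the
reverse complement. The match threshold defaults to 60% of each motif's
maximum achievable score — a conventional operating point that admits
most instances sampled from the matrix while keeping the random-sequence
match probability per 200 bp peak in the few-percent range for the
shipped matrices. Thresholds are per-motif and configurable. Windows
containing non-ACGT bases score −∞.

Enrichment is tested on per-peak presence/absence (not match counts, to
avoid length bias), with each peak trimmed to a fixed 200 bp around its
summit before scanning. With `k` of `n` target peaks and `K` of `N`
background peaks motif-positive, the p-value is the upper-tail
cumulative hypergeometric — the probability of drawing at least `k`
positive peaks in `n` draws from the pooled `n + N` peaks — and fold
enrichment is `(k/n)/(K/N)`. The background is the *opposite* state's
specific peak group, so the two groups serve as each other's contrast;
GC-matched background subsampling is available as an optional mode
(`gc_match_background()`). P-values across the library are
Benjamini–Hochberg adjusted.

Because the hypergeometric test is exact and discrete, its attained
type-I error at nominal α = 0.05 sits slightly below nominal (about
0.03–0.05 for 50-peak groups, depending on the margin); the calibration
test uses 500 bp random peaks, whose per-peak match probability (~0.3
for the OCT4-like matrix) puts the attained level near its maximum.

### The shipped motif library

`motif_library()` loads ten matrices named for the factors a
pluripotency screen cares about: OCT4, SOX2, the OCT4-SOX2 composite,
TEAD1–TEAD4, ZIC3, a KLF4-like GC-box and a CTCF-like matrix. **These
are synthetic stand-ins**, constructed from the canonical consensus of
each family (sharp core columns at 94/100, flanks at 82/100), not
measured genomic frequencies — which is sufficient for the screen's
statistics and for known-truth simulation, but they should be replaced
with measured matrices (e.g. a JASPAR download via `read_jaspar()`) for
any analysis of real data. The TEAD1–4 matrices share the canonical
`CATTCC` core but differ in their flanks by enough that sampled
instances of one member do not cross-match another at the default
threshold; family cross-talk in real data would be stronger, which is
precisely why the expression axis, not the chromatin axis, separates
family members.

### Expression normalization and classification

Counts are GC-normalized per sample by quantile-binning genes on GC
fraction (10 bins) and rescaling each gene by
`median(bin medians) / its bin's median`, followed by an optional
between-sample upper-quartile rescaling. This median-of-GC-bins scheme
is a simple, idempotent, zero-preserving normalizer that removes
monotone GC bias to |Spearman ρ| < 0.1 on 2,000 genes in the suite's
checks; it deliberately replaces heavier within-lane loess/full-quantile
machinery, trading flexibility for testability, and the substitution is
recorded in the run metadata.

"Highly expressed in A" is a fold-and-floor rule: replicate-mean
abundance ≥ `min_expr` (default 30 normalized counts) and
`meanA / (meanB + ε) ≥ min_fc` (default 2, ε = 1). The thresholds are
declared defaults, not estimates of any particular study's unstated
cutoffs; both are exposed and logged. With two replicates per state —
the two-donor design the simulator reproduces — a pooled-variance
two-tailed t test is available per gene (`tf_expression_test()`) but is
flagged `low_power`; classification therefore runs on fold change by
default and the t test is reported alongside, not used as a gate.

### Nomination

The verdict is a pure function of the motif's adjusted p (gate at
α = 0.05) and the gene's expression class. The rank score
`-log10(p_adj) × max(log2FC, 0)` is an artifact of this implementation —
some total order is needed and this one is monotone in both evidence
axes; `pvalue_only` is available as an alternative. Several TFs may map
to one motif; each is evaluated independently on its own expression.

## The synthetic landscape

`simulate_landscape()` generates the known-truth inputs every stage is
tested against:

* **Genome**: i.i.d. bases at GC 0.41 (human-like); two 150 kb nuclear
  chromosomes plus a 16 kb `chrM`. Region placement uses one slot per
  kilobase, guaranteeing disjoint regions.
* **Regulatory truth**: 50 regions each of A-specific, B-specific and
  shared classes, 500 bp wide. Target and decoy motifs are planted in
  A-specific regions with probability 0.8 per region; every other
  motif-region pair gets the 0.05 background probability. Instances are
  *sampled column-wise from the PWM*, not consensus-written, so scanner
  thresholds are genuinely exercised; they are placed near region
  centres (motifs concentrate at accessibility summits) and written
  into the genome, with every edit recorded in the truth table.
* **ATAC tags**: 20,000 per replicate, 50 bp, two replicates per state.
  Within the nuclear genome, per-base tag density is 10× higher in the
  regions open in that state than in background. Contamination follows
  the processing chain being tested: 30% mitochondrial tags, 15% tags
  with MAPQ below 35, 20% exact duplicates. Base tags are unique by
  construction, so the duplicate fraction is exactly the planted one.
* **Counts**: 2,000 genes plus one gene per library motif; 200 planted
  A-high and 150 B-high genes at |log2FC| = 3; negative-binomial noise
  (size 20) around lognormal baseline means (median 100); a
  multiplicative GC bias of 2^(3·(GC − 0.5)) per sample. The three
  target-TF genes (TEAD2, TEAD4, ZIC3 in the default truth) carry
  log2FC = 3; the decoy TF (TEAD1) has an enriched motif but null
  expression.

Sequencing depth per library is a free parameter of the simulation, not
an estimate of any real study; 20,000 tags on a 300 kb genome gives
per-bin counts comparable to a deeply sequenced ATAC library on a
mammalian genome.

What the simulator does **not** model: read-level sequences and aligner
error (inputs are alignments, not FASTQ), fragment-length periodicity
and nucleosome positioning, transposase sequence bias, overdispersion of
tag placement beyond region/background densities, and correlated
GC effects between ATAC and RNA. Passing tests therefore demonstrate
that the *pipeline logic* is correct and calibrated under its stated
model, not that the screen's power on real libraries matches the
simulated power.

## Numerical and design choices

* Coordinates are 1-based closed inside R (`GRanges` convention) and
  0-based half-open in every file format (BED convention); conversion
  happens only at I/O boundaries.
* All randomness flows from one config seed through fixed derived
  streams, so `run_screen()` is byte-reproducible; the suite asserts
  identical `candidates.tsv` and `report.json` across runs.
* Degenerate inputs are defined, not accidental: zero tags give a
  flagged empty track and no peaks; all-zero GC bins are skipped with a
  warning; zero variance in both t-test groups gives p = 1 (equal
  means) or a flagged p → 0 (unequal); an empty peak group is a usage
  error for the enrichment contrast.
* Enrichment ties in the ranking are broken by fold, then motif id, so
  output order is independent of input order.
* `fold = (k/n)/(K/N)` is ∞ when the background count is zero; reports
  serialize that as `null` rather than a number.

## Problem sizes in the test suite

The suite's simulations use the default conditions above; the
end-to-end recovery property runs the full screen over 50 seeds
(about three seconds per seed), the calibration property 500 null
enrichment tests, and the oracle-equivalence properties exhaustively
cover all contingency tables with `n + N ≤ 25`, 500×500 random-peak
classification, and 10 kb scanner comparisons. These sizes make every
property decidable in minutes on one CPU while leaving the statistical
assertions well-powered.

## Worked example

```{r example, eval = FALSE}
cfg <- screen_config(sim = sim_config(seed = 42))
res <- run_screen(cfg, outdir = "screen_out")
res$candidates
```

On the default landscape this nominates TEAD2, TEAD4 and ZIC3 (the
planted trio) with the TEAD1 decoy retained as `motif_only`; the
`screen_out/` directory holds every stage's files, `candidates.tsv`,
and a `report.json` recording all thresholds, seeds and per-stage
counts.

## Known limitations

* The peak caller is a calibrated stand-in, not a reimplementation of
  any published kernel-based caller; absolute peak boundaries on real
  data will differ from specialised tools.
* Peak-set membership classification ignores quantitative
  accessibility differences below the peak-calling threshold.
* The hypergeometric contrast treats peaks as exchangeable; GC matching
  is optional rather than default.
* With n = 2 replicates the per-gene t test is nearly powerless; the
  fold-change rule does the classification and the t test is
  descriptive.
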