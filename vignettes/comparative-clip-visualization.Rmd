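---
title: "Comparative visualization of CLIP crosslink signal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative visualization of CLIP crosslink signal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

CLIP assays identify, per experiment, the set of nucleotides at which an
RNA-binding protein (RBP) was crosslinked to RNA, with a count of crosslink
events at each position. Two obstacles stand between those files and a
valid visual comparison. First, libraries differ in depth, so raw counts
from different experiments are not on a common scale. Second, the signal is
a sparse train of single-nucleotide spikes; over a gene-sized window the
spikes from adjacent sites must be aggregated before binding *regions*, and
quantitative differences between them, become visible. `xlinkplot`
addresses exactly this visualization step. Upstream read processing and
peak calling, and downstream differential-binding statistics, are out of
scope by design: the package consumes already-processed crosslink tracks
and produces a figure.

# Signal model and processing pipeline

Each crosslink track is densified over the queried region into one value
per nucleotide (zero where nothing was observed), keeping only sites on the
region's strand. The pipeline order is fixed: **densify → normalize →
smooth**. Normalizing before smoothing matters for the nonlinear maxpeak
mode; for the linear CPM map the two commute, but the implementation still
normalizes first so that one documented order holds for every mode.

## Normalization modes

* `libsize` (default): $c_i = x_i / N \times 10^6$, crosslinks per
  million, where $N$ is the crosslink total of the *whole file* — all
  chromosomes, both strands. A region-restricted total would make the
  scale depend on the viewing window, so it is deliberately not used.
* `maxpeak`: division by the maximum per-position value observed within
  the region across all tracks of a display group. The group's values then
  lie in $[0,1]$ with maximum exactly 1. Pooling the maximum across
  grouped replicates (rather than scaling each track on its own) preserves
  relative replicate sizes; it is also why an apparent replicate imbalance
  under `maxpeak` can simply reflect library-depth differences — the
  combined mode below is the safer way to read relative differences.
* `libsize_maxpeak`: CPM first, maxpeak second. The profile shapes equal
  those of per-group free y-scaling, but the axis is an interpretable
  fraction of the group maximum.
* `custom`: division by user-supplied per-experiment size factors
  (one per track, strictly positive).
* `none`: raw counts, useful for inspecting a single experiment.

Degenerate inputs are handled explicitly: a zero-signal group under
`maxpeak` is left unchanged with a warning (no division by zero); CPM with
a zero library size is a fatal error; coverage bigWigs are never normalized
or smoothed at all.

## Smoothing

Both smoothers use a window of $w$ nt, default $w = 100$ — a deliberate
compromise for gene-scale windows; focused analyses of small elements
benefit from something like 50 nt, dispersed binders from wider windows.
The default *method* is the rolling mean; both defaults are overridable
per run.

* **Rolling mean**: each position becomes the mean of the values in a
  window centered on it (delegated to `zoo::rollapply`). Edge positions
  use the truncated window (partial mean), so output length always equals
  region length and the plot has a value everywhere; the alternative —
  dropping or NA-filling $\lfloor w/2\rfloor$ positions per edge — would
  leave visible gaps.
* **Gaussian**: Nadaraya–Watson kernel regression on the regular
  per-nucleotide grid with a Gaussian kernel, $\sigma = w/4$, truncated at
  $\pm w/2$, with weights renormalized over the positions that exist near
  the edges (the kernel analogue of the truncated-window rule). The
  bandwidth rule is this package's own documented choice: $\pm 2\sigma$
  covering the window makes the Gaussian window visually comparable to the
  rolling mean at equal $w$. It is configurable through $w$; exact
  numerical agreement with other tools' Gaussian smoothers is not a goal.

Even windows are widened by one nucleotide (with a notice) so "centered" is
well defined; windows exceeding the region are clamped with a warning;
$w = 1$ is the identity. Both smoothers preserve constants and commute
with scalar multiplication, and the rolling mean preserves the profile
mean exactly on circularly padded input — these invariants are enforced by
the test suite against independent brute-force implementations.

# Coordinates, formats and conventions

Interval arithmetic uses the 1-based, closed convention of
GenomicRanges/IRanges throughout, with `rtracklayer` performing the
half-open/0-based conversions for BED, BedGraph and bigWig at the I/O
boundary; tests pin the absence of off-by-one drift (a BED record covering
$k$ bases yields exactly $k$ single-nucleotide sites). User coordinate
queries follow the genome-browser convention (1-based inclusive). Signed
BedGraph scores encode strand in the sign (the common iCLIP dialect);
stranded BED uses column 6. Further conventions, chosen once and logged at
run time where they act:

* BedGraph records spanning several nucleotides are expanded to one site
  per covered base, each carrying the full score (BedGraph semantics: the
  value applies to every base).
* Crosslink BED/BedGraph records without strand are treated as plus strand
  with a warning; duplicate position/strand records are summed with a
  warning; zero-score records are kept (they change nothing, but dropping
  them silently would hide malformed inputs).
* Chromosome-name dialects (`chr1` vs `1`) are *not* aliased: a mismatch
  yields an empty profile plus a prominent warning naming the spellings on
  both sides. Silent aliasing guesses wrong exactly when it matters
  (scaffolds, patch contigs).
* For an unstranded coordinate region, both strands are processed and
  overlaid, minus-strand profiles with their own linetype — summing the
  strands would fabricate signal no strand actually shows.

The GTF is parsed once into a lightweight gene/transcript/exon index and
cached next to the GTF (`.xlinkplot-cache.rds`, keyed by file name and
modification time; a cache older than its GTF is rebuilt with a notice).
Gene-level annotation collapses each gene to a meta-transcript — the
interval union of all isoform exons (`GenomicRanges::reduce`), which is
idempotent and order-independent. Transcript stacking uses deterministic
greedy first-fit by start coordinate with a fixed padding gap (1% of the
widest span, minimum 1 nt), which never places overlapping models on one
row.

# Figure composition

Panels (crosslink; auxiliary intervals; coverage; annotation) are ggplot2
objects assembled with patchwork on a shared x-range; the figure object is
available programmatically (`buildFigure()`) so its geometry can be
inspected without rendering. Height ratios default to 40:10:25:25 with the
annotation share growing by 3 units per additional transcript row; user
ratios override them verbatim; absent panels get ratio 0. Colors come from
a fixed ordered palette (Okabe–Ito first) assigned in order of group
appearance, and gene colors in the annotation panel by sorted gene id —
both so reruns are byte-identical. Unsmoothed profiles are drawn as
per-nucleotide bars, smoothed ones as lines. The optional highlight box is
drawn beneath the data in every signal panel. Output format follows the
file extension (`.pdf`, `.png` at 300 dpi; anything else is fatal), and
the file is written atomically so failed runs leave nothing behind.
Per-group y-scaling (`--scale_y`) uses free-y facets, one per group.

# The synthetic data generator

`makeFixture()` emits a complete toy study on one 6 kb chromosome,
emulating the structure of a two-RBP competition experiment: two replicate
BedGraphs of "RBP-A" sharing a Gaussian-shaped binding peak (height 30
expected counts, σ = 40 nt, centered at position 3400), two replicates of
"RBP-B" with the peak shifted 240 nt downstream at 80% height, a BED9
repeat-like feature under the shared peak, six bigWig coverage tracks in
three condition groups where knockdown raises expression of a cassette
exon under that feature (CTRL ≈ 2 vs KD ≈ 34–40 signal units against ≈ 50
on constitutive exons), and a GTF with one multi-isoform gene (one isoform
carrying the cassette exon) plus a second, minus-strand gene. Counts are
per-position Poisson draws around the peak-shaped mean plus uniform
background (rate 0.03 plus-strand, 0.01 minus-strand); at these rates
CPM-normalized, 50-nt-smoothed replicates correlate above 0.9, which the
suite asserts. Output is byte-deterministic per seed.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: uridine-biased, non-Poisson crosslinking
noise; overlapping genes and many-isoform loci; multi-chromosome inputs at
scale; real library-size imbalances of an order of magnitude; bigWigs with
missing contigs or nonuniform bin sizes. The format handling is exercised
by construction, the biology is only sketched.

# Problem sizes and determinism

The test suite works at desk scale by choice: random profiles up to 500 nt
against brute-force smoother oracles (100 cases per smoother at tolerance
1e-9), 100 random maxpeak groups, 10-fold randomized round-trips and
layouts, and the full four-panel end-to-end run on the 6 kb fixture. All
randomized tests run under fixed seeds. Determinism is asserted at three
levels: fixture file checksums, figure object models (built layer data),
and PNG bytes across repeated identical runs.

# Known limitations

* BAM/CRAM, GFF3, remote URLs and tabix-indexed input are unsupported
  (BED/BedGraph/bigWig/GTF cover the processed-data formats the tool
  targets).
* No peak calling and no statistical comparison of conditions; the figure
  is evidence for the eye, not a test.
* Very isoform-dense regions draw every transcript; there is no cap, so
  the annotation panel can dominate the page (the dynamic ratio growth
  mitigates but does not bound this).
* `maxpeak` alone can misrepresent replicate balance when library sizes
  differ; prefer `libsize_maxpeak` when relative differences matter.
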