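---
title: "Chromatin accessibility dynamics from ATAC-seq peak supersets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin accessibility dynamics from ATAC-seq peak supersets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdyn)
library(dplyr)
```

## The problem

Peak callers applied to single ATAC-seq libraries are conservative: a
weak peak present in one library is often called in a deep library and
missed in a shallow one. Any downstream comparison of "peaks present in
A but not B" then confounds biology with caller sensitivity. The
approach implemented here sidesteps that by *re-calling*: take the
union of peak calls across all libraries (the peak **superset**), score
every superset locus in every library by its normalized sequence tag
density, and decide open/closed per locus per library with one fixed
threshold. A locus is then "closed" only because its signal is low,
never because a caller skipped it.

On top of the re-called matrix the package classifies each locus's
trajectory over a differentiation time course into temporal dynamics
classes, compares the classes between conditions (wild-type versus a
TF knockout), and relates transcription-factor co-binding to gene
expression change via TSS windows, signal pileups and a moving-average
co-binding density along expression-ranked genes.

## The procedure and its assumptions

**Normalization.** Each library's coverage is multiplied by
`1e7 / total_unique_reads` (tags per ten million), putting all
libraries on a common depth. The normalization assumes total unique
read count is an adequate size factor — no signal-proportion
(e.g. TMM-style) correction is applied, which is acceptable when the
global accessible fraction is broadly comparable across libraries.

**Tag density.** The density of a locus in a library is the *mean
per-base scaled coverage* over the locus: total scaled coverage mass
inside the locus divided by locus length. The definition is
length-independent, so one threshold applies to short and long loci
alike. The open/closed threshold is `theta = 0.2734` in these units;
density exactly at `theta` is called open (the threshold is read as the
minimum density of a genuine peak — a tie rule is required for
determinism, and this is the documented one). `theta` is a parameter
everywhere it is consumed, because its numeric value is only meaningful
relative to the density definition used when it was derived.

**Superset construction.** Overlapping *and book-ended* peaks merge
into one locus, so each superset locus is a maximal contiguous
candidate region. Merging book-ends keeps locus counts reproducible
under refinement of the input peaks.

**Replicate merging.** Biological replicates are merged *before*
density computation by averaging their depth-scaled tracks per base,
mirroring the common practice of merging replicates before peak
calling. `run_pipeline(merge_replicates = FALSE)` disables this.

**Dynamics classes.** With calls $(c_0, c_1, c_2)$ over an ordered
3-timepoint course (D0 < D1 < D3):

| pattern | label | reading |
|---|---|---|
| closed, open, open | CO1 | opens at the first transition |
| closed, closed, open | CO2 | opens only at the end |
| open, closed, closed | OC1 | closes at the first transition |
| open, open, closed | OC2 | closes only at the end |
| open, open, open | PO / PO_UP / PO_DOWN | persistently open |
| closed, closed, closed | PC | persistently closed |
| closed, open, closed / open, closed, open | COMPLEX | non-monotone |

The CO/OC subgroup index is the day of transition, formalized as the
number of leading timepoints before the state flips; this is the
minimal monotone reading of "subgroups based on the day of opening and
closing". Non-monotone trajectories get an explicit COMPLEX label
instead of being forced into CO/OC, keeping those classes semantically
clean; COMPLEX and PC counts are reported but excluded from CO/OC/PO
figures. Persistently open loci are subdivided by
$\Delta = \log_2\frac{d_\mathrm{last} + \varepsilon}{d_\mathrm{first} + \varepsilon}$
with pseudocount $\varepsilon = 0.01$ (in density units, guarding the
ratio against near-zero densities): $\Delta \ge$ `fc_threshold` is
PO_UP, $\Delta \le -$`fc_threshold` is PO_DOWN, otherwise PO. The
direction of the subdivision is given by the class definitions; the
magnitude is not, so the default `fc_threshold = 1` (2-fold) is a
package choice exposed as a parameter. $\Delta = 0$ is always plain PO,
so `fc_threshold = 0` splits every changed locus without swallowing
exactly unchanged ones.

**Condition comparison.** Classes are computed per condition on one
*shared* superset, which is what makes locus-identity Venn counts
(shared / unique-to-A / unique-to-B per class) well defined.

**Co-binding integration.** Two binding-site sets are each merged
internally, then overlap is counted A-centrically with a $\ge$ 1 bp
criterion (the simplest reproducible rule; a minimum-overlap parameter
is exposed). Loci are assigned to genes when the TSS lies within 10 kb
of the locus (distance 0 when the locus spans the TSS; strand is
ignored since the window is symmetric). Co-binding presence per gene
uses the same distance rule at 5 kb against the shared loci — the TSS
is used as the gene anchor, consistent with the 10 kb rule. The
moving-average profile ranks genes by log2 fold change (descending,
ties broken by gene id) and smooths the 0/1 presence indicator with a
centered window of 101 genes, truncated at the edges rather than
padded; window size is a display parameter and is exposed. Pileups are
centered on locus midpoints with $\pm$ 2000 bp flanks in 50 bp bins
(both exposed); windows clipped by contig edges contribute zeros, and a
clipped bin still divides by the full bin width.

## Coordinate and format conventions

All intervals are BED-standard 0-based half-open. bedGraph is the
required signal format: tracks must define at most one value per base
(overlaps are rejected, not resolved), unsorted input is sorted, and
uncovered bases have implicit value 0. Contig names match by exact
string equality — no "chr" aliasing — and a locus on a contig a track
never covers scores density 0 with a warning naming the contig.
Parsers reject malformed records (negative start, `end <= start`,
non-integer coordinates) with the offending line number; nothing is
silently repaired. One declared normalization (tags per ten million) is
applied to any track the pipeline scales, whether ATAC or CUT&RUN-like,
and the CLI records resolved parameters in a `#` metadata header of
every output.

## What the simulator emulates

`simulate_dataset()` generates the full study design: 3 timepoints
(D0/D1/D3) × 2 conditions (WT/KO) × 2 replicates, with
7 × `n_per_class` (default 500) non-overlapping 400 bp loci planted on
three 12 Mb contigs, each locus carrying one dynamics class per
condition. Key choices:

* **Noise model.** Per-locus, per-library densities are the planted
  class mean times $e^{N(0,\sigma)}$ with $\sigma =$ `noise_sd` = 0.2.
  Log-normal multiplicative noise has positive support and realistic
  coverage dispersion; no count-level (Poisson) layer is simulated.
* **Separation.** Open and closed means (1.0 and 0.05) straddle
  `theta = 0.2734` by construction; at the default noise an open locus
  falls below threshold only at $\approx 6.5\sigma$, so recovery is
  limited by the PO/PO_UP/PO_DOWN boundary, not by open/closed calls.
* **PO ramp.** PO_UP runs $2^{-1}, 2^{0}, 2^{+1}$ times the open mean
  (PO_DOWN mirrored), i.e. a symmetric planted $|\Delta| = 2$ that
  keeps both endpoints above `theta`.
* **Missed weak peaks are real in fixtures.** Per-library peak BEDs
  are thresholded on that library's *sampled* density, not on the
  truth, so individual libraries genuinely miss loci that are closed
  (or noisily weak) there, and the superset re-call is exercised, not
  simulated away.
* **Condition divergence.** KO labels are a partial permutation of the
  WT label multiset (`condition_shuffle = 0.5` of loci), preserving
  per-condition class counts exactly while making the per-class Venn
  non-trivial.
* **Read depths** vary uniformly within ±20% of `1e7`, so depth
  scaling matters; raw track values are sampled density divided by the
  library's scale factor.
* **Co-binding coupling.** Gene log2 fold changes are N(0, 1). Genes
  in the top expression tercile receive an overlapping A/B site pair
  within 5 kb of the TSS with probability `cobind_fraction_up` (0.6),
  the bottom tercile with `cobind_fraction_down` (0.1), and the middle
  tercile with their mean — a deliberately simple coupling sufficient
  to reproduce the qualitative "co-binding tracks upregulation" shape.
  Each factor also gets 500 gene-independent sites so the two sets
  overlap only partially.
* **Background** is a constant 0.01 density outside loci, keeping
  thresholding non-degenerate.

What the simulator does **not** emulate: read-level sampling
(fragment lengths, Tn5 insertion bias, duplicates), locus width
variation, correlated noise between neighboring loci or replicates,
mappability artifacts, and caller-specific peak-boundary jitter.
Passing tests therefore demonstrate that the pipeline's logic is
correct under the planted statistical structure — they do not certify
performance on real libraries, where the open/closed margin is far
less clean than 1.0 versus 0.05.

## Numerical and degenerate-input choices

* Density quantification and pileups use exact weighted interval
  overlaps (no per-base materialization), verified in tests against
  per-base brute-force arrays to 1e-9 or better.
* `scale = 1e7 / total` is exact floating-point arithmetic;
  mass-conservation tests require equality within 1 ulp-scale
  tolerance.
* Empty inputs: an empty BED parses to an empty interval table; an
  empty bedGraph is an all-zero track; an empty A set makes the
  overlap fraction undefined and is an error, as is an empty locus set
  for a pileup.
* Tie rules are fixed and documented: density `== theta` is open;
  `delta_log2 == 0` is PO; equal fold changes rank by gene id.
* Determinism: the simulator restores the caller's RNG state and the
  same config (including seed) yields byte-identical written bundles.

## Problem sizes used in the checks

The packaged tests run the full pipeline on the default design (3500
loci × 12 libraries) once per noise level, and use 10–200 randomized
small instances (≤ 50 intervals per library on 10 kb contigs, ≤ 1 Mb
gene-assignment contigs) for the oracle comparisons; the co-binding
coupling is checked across 10 seeds at two `cobind_fraction_up`
values. These sizes exercise every code path while keeping the whole
suite and the reproduction script to a few minutes on one CPU.

## Known limitations

* The dynamics classifier assigns named subgroups for any number of
  timepoints, but only monotone single-transition patterns; richer
  trajectories all map to COMPLEX.
* `theta` is taken as given. Its published value is tied to a
  particular density normalization that is not fully specified in
  public sources; this package defines density as mean per-base scaled
  coverage and exposes `theta` so users can recalibrate against their
  own normalization.
* Gene assignment uses TSS distance only; whole-gene-body anchors are
  not implemented.
* No statistical enrichment testing of overlaps (permutation nulls) —
  the overlap module reports counts and fractions, and exports BEDs as
  the hand-off point for enrichment tools.
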