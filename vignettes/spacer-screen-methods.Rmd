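---
title: "Methods: tiling spacer screens, acquisition maps, and the simulated experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling spacer screens, acquisition maps, and the simulated experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerscreen)
```

This vignette is the package's own account of the models and rules it
implements: what each stage assumes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where a design was
genuinely open and a choice had to be made.

## The screen and its observable

A genome-tiling spacer library turns type III-A CRISPR immunity into a
pooled fitness assay. Each cell carries one spacer; after phage infection,
cells whose crRNA gives effective (and survivable) defense outgrow the
rest. The observable is the per-spacer **enrichment ratio**

$$E(s) = \frac{f_{\text{post}}(s)}{f_{t_0}(s)}, \qquad
  f(s) = \frac{c(s)}{\sum_{s'} c(s')},$$

with frequencies taken over the spacers extracted in that sample (not over
the designed manifest — a spacer that never made it into the sequencing
library contributes nothing to the denominator). Type III-A biology enters
through one geometric rule: a crRNA can only engage a transcript it is
complementary to, so a spacer is **targeting** iff its midpoint lies in a
transcribed region and its strand is opposite to the mRNA strand. No
PAM/PFS rule is applied; type III-A interference does not require one.

Coordinates are 0-based half-open everywhere, and every emitted table says
so in its header. Region membership uses the spacer midpoint,
`floor((start + end) / 2)`; because intervals are half-open, a midpoint
landing exactly on a shared boundary belongs to the downstream region —
the deterministic tie-break needed for spacers straddling the early/late
junction.

## Library design

`design_tiling_library()` tiles spacers of length `k` (default 35 nt, the
canonical type III-A spacer size — configurable, since only the 90-nt
total oligo length is a hard synthesis constraint) every `step` nt
(default 2) along the replicon. Both strands share one coordinate grid
anchored at plus-strand position 0; the minus-strand spacer over
`[p, p + k)` is the reverse complement of the plus-strand window. Per
strand the count is `floor((L - k)/step) + 1`.

Each oligo is
`priming_left + bsai_left + repeat_left + spacer + repeat_right + bsai_right + priming_right`,
totalling 90 nt with the default 5 + 6 + 17 + 35 + 17 + 6 + 4 layout. The
BsaI recognition site (`GGTCTC`) appears once per flank, oriented inward
so Golden Gate digestion releases repeat-homology overhangs; plus- and
minus-strand schemes use distinct priming sequences so the two
half-libraries amplify independently. The repeat-homology arms are the
terminal 17-mers of the package's synthetic direct repeat — design
constants, not sequences of a natural locus. Spacers whose sequence occurs
more than once in the designed set are kept but flagged `duplicate`;
downstream mapping classifies them as ambiguous rather than guessing a
locus.

## Spacer extraction

`extract_spacers()` recovers spacers as maximal runs `DR·S·DR` in each
read, with every direct-repeat occurrence within `max_repeat_mismatches`
(default 1) Hamming distance on a full-length window. Substitutions
dominate on the MiSeq-class data this models, so no indel alignment is
attempted — the search stays exact and fast
(`Biostrings::vmatchPattern()` under the hood). Expanded arrays share the
middle repeat: `DR·S1·DR·S2·DR` yields both spacers.

Numerical/tie-break rules:

* Overlapping DR candidates are resolved greedily left-to-right: within
  each overlap cluster the lowest-mismatch (then leftmost) candidate wins,
  and everything overlapping it is discarded.
* Spacer length bounds default to [20, 50] nt; out-of-bounds gaps are
  skipped and tallied, as are reads shorter than the repeat.
* A read with any forward DR pair is treated as amplicon-oriented; only
  reads without one are rescanned as their reverse complement, so counts
  are reported in a single canonical orientation and
  reverse-complementing every read leaves the table unchanged.
* Spacers are counted as exact strings. At the default tiling step of 2,
  designed neighbours differ by at least two positions, so error
  clustering would mostly merge designed spacers with their own
  error-mutated singletons; those singletons are instead left as
  low-count noise and naturally drop out of ratio statistics.
* Base qualities are ignored: the repeat anchors already reject damaged
  copies, and a quality filter would discard whole reads for errors the
  anchor tolerates.

## Enrichment statistics

`compute_enrichment()` defaults to the `na` zero policy: a spacer absent
at t0 has no defined ratio and is excluded from group statistics. The
alternative pseudocount policy uses
$f = (c + \alpha)/(\text{total} + \alpha N)$ with `alpha = 0.5` and `N`
the library size; as `alpha -> 0` it converges to the `na`-policy values
for spacers detected at t0. Group summaries are on the natural enrichment
scale (a log option exists) because the group means this field reports
are natural-scale. Group comparisons use the package's own Welch t
(unequal variances, n−1 denominators, Welch–Satterthwaite df); the t tail
is evaluated by `stats::pt`, i.e. the regularized incomplete beta
function. `correlate_with_expression()` summarises each spacer's target
expression as the mean per-position normalized coverage over its
interval, strands summed, and reports the Pearson r and the n used.

Whether screen group means should be computed over all spacers or
detected-only, and at which timepoint, is genuinely open; the functions
take the annotated table as-is, so either choice is a one-line filter by
the caller. The defaults follow the `na` policy (detected-only) at the
first post-infection timepoint.

## Acquisition mapping

Acquired spacers are copied from their protospacers, so `map_spacers()`
defaults to exact matching (`max_mismatches = 0`), with a ≤2-mismatch
mode for sequencing errors. The mapper is a transparent seed-and-verify
rule rather than an external aligner with unstated parameters: a 12-mer
index of each replicon's plus strand, pigeonhole seeding (m + 1 seeds
guarantee one exact seed at ≤ m mismatches; queries too short for that
fall back to an exhaustive scan), full-length Hamming verification, both
strands of every replicon searched. Lowest mismatch wins; equal-best
placements at more than one locus mark the spacer ambiguous; ambiguous
spacers are excluded from coverage tracks (single-nucleotide maps must
not double-count) but tallied.

RPM tracks add each uniquely aligned spacer's count to every position of
its interval on its strand and scale by one million over the total
uniquely aligned reads pooled across replicons. This makes the
per-replicon identity
$\sum_p \text{RPM}(p) = 10^6 \,\bar{k}\, n_r / n_{\text{total}}$
(with $\bar{k}$ the count-weighted mean aligned length) an exact
invariant, which the tests verify to 1e-9.

## Early/late operon calling

The early/late promoter architecture was historically annotated by
inspecting coverage tracks; `call_operons()` formalises that as a
reproducible rule. Per strand and timepoint, per-million-normalized
coverage is smoothed with a centred running mean (window 501 nt, odd,
shrinking at the edges). A position is "on" at timepoint t if its
smoothed value exceeds `threshold_factor` (default 5) times a baseline.

The baseline needs care: by late infection most of a phage genome is
transcribed, so a per-timepoint median sits on the *active* level and a
median-based threshold calls nothing. The baseline is therefore the
minimum over timepoints of the per-timepoint lower quartile
(`baseline_quantile = 0.25`) of smoothed coverage — correct whenever at
least a quarter of the genome is still quiet at the first sampled
timepoint, which holds for the early-operon fractions seen here (~35% of
the genome) with margin. The caller's assumptions fail on a genome
transcribed almost wholly within the first sample; such data needs an
earlier timepoint, not a different threshold.

Each position's activation time is the earliest "on" timepoint; maximal
runs sharing one activation time and at least `min_region` (500 nt) long
become regions. Segmenting by activation time is what splits two
*adjacent* operons firing at different times — a plain on/off run rule
would fuse them. Smoothing displaces each true boundary by at most half a
window, which is why boundary-recovery checks use a ±(window/2 + 50) nt
tolerance and why TSS-level precision is an explicit non-goal. Lowering
the threshold can move the early/late change point but never shrinks the
transcribed territory (the union of called regions), which is the form of
monotonicity the tests assert.

## The simulated experiment

The generator produces every input the pipeline consumes, under one
master seed (each stage draws from a fixed offset, so stages are
independently reproducible and byte-identical across runs).

* **Genome**: uniform-random ACGT, default 40 kb, with a plus-strand
  early operon [1,000, 15,000) activating at 5 min and a late operon
  [15,000, 40,000) at 15 min. The exact early/late boundary of a real
  phage is not a universal constant, so region boundaries are inputs
  everywhere, never hard-coded.
* **Screen**: t0 counts are multinomial over Gamma-dispersed near-uniform
  proportions (shape 100; `Inf` gives exact uniformity). Selection is one
  effective multinomial reweighting per timepoint: expected post
  frequencies ∝ f_t0 · w^rounds (defaults: 1 round at 5 h, 2 at 24 h).
  For one round the expected enrichment is the closed form w / w̄, which
  is the oracle the tests check to 2%. Per-spacer lognormal fitness noise
  (sdlog 0.25) models cell-to-cell and position-to-position variability
  and sets realistic group SDs.
* **Fitness presets** are calibration constants, not measurements: WT
  selects all early-operon targeting spacers (w = 10 vs 1); dcsm6 keeps
  selection only upstream of the PE midpoint split (Csm6-independent
  defense); the Cas10 nuclease-dead preset is calibrated analytically so
  that, under the default geometry at one round, expected group means are
  0.78 (early targets) and 1.96 (late targets) — w_PE = 1.5926,
  w_PL = 4.0019 from solving w/w̄ for the two groups simultaneously. The
  dormancy biology behind those numbers (fast Csm6 activation by early
  targets ⇒ earlier growth arrest ⇒ fewer descendants) is deliberately
  collapsed into the weights; explicit population dynamics are a
  non-goal.
* **Acquisition**: each surviving colony contributes one spacer, phage
  with probability θ/(1+θ), else plasmid; positions are drawn from
  per-start weights that favour the early-operon minus strand ×10 under
  WT (upstream-PE only under dcsm6) and are uniform for the nuclease-dead
  presets. θ defaults: 48 for WT/dcsm6 (phage fraction 97.96%) and 0.0095
  for cas10HD (0.94%) — odds calibrated to the source fractions such
  screens report, flagged as calibration artifacts in the provenance
  JSON.
* **RNA-seq**: Poisson counts around baseline 2 + amplitude 100 on the
  mRNA strand of each operon active by the timepoint, with an optional
  exponential 3′ decay (default half-distance 20 kb) modelling lower read
  abundance far downstream of a promoter. Reads are not simulated for
  this stage; coverage is emitted directly.
* **Reads**: screen and acquisition amplicons are `DR·spacer·DR` with
  per-base substitution errors (default 0.001) and constant qualities.

What the simulation does *not* emulate — and hence what passing tests do
not show about real data: PCR amplification bias and chimeras, indel
errors and quality-correlated errors, paired-end structure, partial or
nested repeat matches from real CRISPR arrays, phage escape mutants, and
any explicit infection dynamics (MOI, lysis timing, dormancy and
regrowth). The pipeline's correctness on real data rests on the same
contracts (repeat-anchored extraction, ratio statistics, exact mapping),
not on these simulations.

## Problem sizes

The shipped checks run at deliberately chosen scales: screens of ~2,000
spacers (a 40 kb genome tiled every 40 nt) at 2×10^5 reads per sample for
the genotype presets; 10^5 error-free amplicons for extraction fidelity;
100 replicates at depth 10^6 for the selection law; 10^4 null
simulations for Welch calibration; 1,000 random spacers against a 10 kb
genome for mapper equivalence; and 50 randomized 20 kb architectures for
boundary recovery. Full-size libraries (~40,000 spacers at step 2) run
through the same code paths unchanged; the package's own full-size check
is the library-frequency identity 1/40,338 → 2.4×10⁻⁵.

## Known limitations

* The DR search tolerates substitutions only; an indel inside a repeat
  loses that read.
* The mapper is ungapped by design; acquired spacers with indels relative
  to the protospacer go unaligned rather than mis-placed.
* The operon caller assumes a mostly-quiet genome at the first timepoint
  and two discrete activation classes; graded activation times collapse
  onto the sampled grid.
* Enrichment ratios are not a dispersion-aware differential-abundance
  model; no per-spacer significance is attempted, only group-level tests,
  because per-spacer replication is not part of the assay design.
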