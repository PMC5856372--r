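---
title: "Diagnosing and correcting biases in whole-genome bisulfite sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing and correcting biases in whole-genome bisulfite sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgbsbias)
```

## The problem

Sodium-bisulfite treatment converts unmethylated cytosine to uracil (read
as thymine) while leaving 5-methylcytosine and 5-hydroxymethylcytosine
intact, which is what makes single-base methylation maps possible. The
same chemistry, however, distorts the library in three coupled ways:

1. **Degradation.** Bisulfite causes random base loss at *unmethylated*
   cytidines, and the abasic sites break the backbone under heat and
   alkali. A single-stranded molecule therefore dies with a probability
   that grows with its count of unmethylated cytosines. C-rich,
   unmethylated sequences are depleted from the pool; methylated molecules
   are protected and over-represented, so global methylation is
   *overestimated* and coverage becomes methylation- and GC-dependent.
2. **Incomplete conversion.** A fraction of unmethylated cytosines escape
   conversion and are read as methylated. Because non-CpG (CH = CHG + CHH)
   cytosines outnumber CpG ones more than twentyfold in CpG-depleted
   genomes and are mostly unmethylated, conversion failure manifests
   chiefly as spurious CH methylation. Failures are not independent
   across positions: whole molecules escape conversion, and some motifs
   (CC(A/T)GG-like) resist conversion in every sample.
3. **PCR amplification.** Polymerases favour GC-rich templates. After
   conversion a molecule's GC content depends on how many cytosines it
   *retained* — i.e. on its methylation and on conversion failure — so PCR
   preferentially amplifies methylated and poorly converted molecules,
   compounding the first two biases. Amplification-free protocols avoid
   this entirely.

The package provides the diagnostics that make these biases visible in
any aligned WGBS dataset, the corrections that remove the conversion
artefacts, quantification strategies that resist coverage bias, and a
generative simulator of the whole library-preparation process with full
ground truth, so that every diagnostic is validated by parameter
recovery rather than by fiat.

## Data model

Everything operates on four plain objects: a `ref_genome` (named
uppercase sequences; all coordinates 0-based, half-open), BED-style
interval tables, raw reads, and `bs_alignments` — ungapped read
footprints carrying a per-reference-position call string in the usual
aligner dialect (`z/Z` CpG, `x/X` CHG, `h/H` CHH, `u/U` unknown;
uppercase = unconverted; `.` = not a cytosine on the read's parent
strand) plus the bisulfite-strand provenance (OT/OB/CTOT/CTOB). SAM/BAM
with XM/XR/XG tags is read via Rsamtools; only ungapped alignments are
accepted — gapped or clipped records are counted and skipped rather than
silently reinterpreted, because reconciling an indel with a
reference-congruent call string is not well defined.

Duplicate handling follows the two analysis regimes: genome-wide
diagnostics skip duplicate-flagged reads by default, while repeat and
tandem analyses (strand counts, position profiles) include them, since
reads from high-copy repeats are not uniquely mappable and deduplication
there is meaningless. Every operation exposes the switch.

## The diagnostics

**Composition report.** `genome_composition()` and
`observed_composition()` tally mono- and overlapping dinucleotides of the
genomic sequence under read footprints (the read sequence itself is
useless here — converted cytosines appear as thymines);
`bias_report()` compares the two as log2(observed/expected) fractions.
A depleted C row indicates degradation; C enrichment indicates poor
conversion; G and A/T skews measure amplification and polymerase
preference. Ratios are only defined where both fractions are positive;
undefined entries are flagged, never fabricated.

One subtlety is strand orientation. In reference (top-strand) coordinates
the C-depletion of top-strand molecules and the G-depletion of
bottom-strand molecules partially cancel in mixed dinucleotides such as
TC. The causal variable is the cytosine content of the *molecule's own
strand*, so `observed_composition(orientation = "parent")`
reverse-complements bottom-strand footprints before tallying; under
degradation every C-containing dinucleotide is then depleted. The default
remains reference orientation for comparability with standard reports.

**Coverage diagnostics.** `strand_read_counts()` exposes the strand skew
of GC-asymmetric references (telomere, major satellite, mtDNA);
`tandem_unit_histogram()` counts non-overlapping repeat units per raw
read (with a reverse-complement option for post-bisulfite libraries, and
`filter_min_units()` to drop the low-copy bins where genomic TTTTAA runs
are indistinguishable from converted CCCTAA); `tile_gc_coverage()` bins
fixed-width tiles by genomic G or C percentage and reports mean
normalised read counts per bin with the tile-count background, assigning
reads by footprint midpoint so no read is counted in two tiles;
`feature_relative_coverage()` scales features to a fixed number of body
bins, adds fixed-width flanks, and normalises by mean genome-wide
per-base coverage so 1 means no bias. `high_coverage_mask()` excludes
1-kb windows with more than 1000 read starts — collapsed-repeat artefact
regions — from these analyses; the threshold is strict (exactly 1000
reads is kept).

**Conversion corrections.** Three strategies, in increasing order of
power on our simulations:

- `threshold_filter()` zeroes per-cytosine calls below a methylation
  cutoff (3–20% in common practice). It fails exactly where noise is
  concentrated: at modest coverage a single unconverted call already
  clears a 10% cutoff, and motif-resistant positions are far above it.
- `filter_nonconversion_reads()` — the 3xC filter — removes reads with
  ≥ 3 *consecutive* unconverted CH calls. Consecutive means successive CH
  cytosine positions along the read: non-cytosines and CpG positions do
  not break a run, a converted CH call does; unknown-context calls count
  as CH by default (conservative). A `total` mode covers the alternative
  reading of counting unconverted CH calls regardless of adjacency.
  Removing whole molecules is what makes this powerful: conversion
  failure is molecule-correlated, and a poorly converted molecule betrays
  itself within a few CH positions.
- `background_subtract()` normalises each cytosine against an
  unmethylated control library of the same genome. It is the only
  strategy that removes *sequence-specific* resistance, because the same
  motif fails in the control. Subtraction operates on percentages with
  optional zero-clipping; note that clipping makes per-position means
  biased upward under pure noise, so genome-wide residuals should be
  computed as the difference of the two global levels instead.

`spike_in_conversion()` estimates conversion efficiency from reads on an
unmethylated spike-in reference (lambda/M13-style), with a per-context
breakdown.

**Quantification.** `extract_per_cytosine()` turns call strings into
per-position, per-strand counts. `region_methylation()` implements the
two common region strategies: pooling all calls
(100·Σmeth/Σtotal) versus averaging per-cytosine percentages. They agree
exactly under equal coverage; under degradation, coverage correlates with
methylation, pooling weights highly methylated cytosines more, and the
per-cytosine mean is the less biased estimator. Requiring a minimum
per-cytosine coverage (the widespread ≥5 or ≥10 rule) *reinforces* the
coverage bias — the package exposes the knob and the acceptance suite
demonstrates the damage. Regions are included when they reach three total
observations by default, with no per-cytosine floor, matching the less
bias-prone convention. `cytosine_tiles()` builds fixed-cytosine-count
windows (50 or 150 cytosines are typical) so each probe rests on the same
number of measurable positions; `differential_regions()` selects tiles
differing by strictly more than 20 percentage points;
`overlap_count()` compares selections by tile identity, since both value
sets are computed on one probe frame.

## The simulator

`simulate_wgbs()` runs fragmentation → per-molecule methylation states →
bisulfite conversion with degradation → PCR → read emission, with one
root seed and named independent substreams per stage (changing PCR
settings does not perturb fragmentation draws; identical configuration
and seed give byte-identical output files).

- **Degradation** is whole-molecule: a single-strand molecule survives
  with probability $(1-\beta_u)^{k_u}(1-\beta_m)^{k_m}$ where $k_u, k_m$
  count its unmodified/modified cytosines and $\beta_m \le \beta_u$
  encodes the protective effect of 5mC/5hmC. Survive-or-die is a
  simplification of breakpoint resampling, but every diagnostic here
  observes only which molecules reach the sequencer, for which the
  survival law is sufficient and analytically convenient
  (`calibrate_breakage()` inverts it: a twofold recovery difference
  between 15% and 30% C fragments of length $L$ gives
  $\beta = 1 - 2^{-1/(0.15 L)}$).
- **Conversion failure** is a molecule-level mixture: a fraction
  `poor_fraction` of molecules fail at `poor_epsilon` per cytosine, the
  rest at the low base rate that preserves the configured `epsilon_CG` /
  `epsilon_CH` as marginal rates. The mixture is not an embellishment —
  with independent per-cytosine failure at 1%, runs of three consecutive
  unconverted CH calls are vanishingly rare and the 3xC filter could not
  work at all; molecule-correlated failure is also the stated mechanism
  behind preferential amplification of poorly converted reads. Motif
  multipliers (IUPAC W/S/R/Y/N supported) scale the base rate at
  cytosines inside matching occurrences, modelling conversion-resistant
  sites; that their signal passes the read filter but not background
  subtraction is exactly the behaviour the correction suite asserts. Over-conversion of modified cytosines happens with
  probability `gamma`.
- **PCR** copies each molecule per cycle with efficiency
  `clamp(e0 + slope·(gc_post − g_ref), 0, 1)` where `gc_post` is the
  molecule's post-conversion G+C fraction: genomic Gs plus *retained*
  cytosines. This single term couples amplification to methylation and
  conversion failure. `cycles = 0` reproduces amplification-free
  behaviour exactly. When a sequencing yield `n_reads` is set, reads are
  drawn from the copy pool with probability proportional to copy number —
  repeated draws of one molecule are precisely PCR duplicates.
- **Read emission** takes one read per molecule copy from the molecule's
  5' end, computes call strings from the recorded per-cytosine truth, and
  emits raw sequences in read orientation. Only OT/OB reads are emitted;
  complementary-strand PCR products are not modelled as separately
  sequenced molecules (the CTOT/CTOB tag mapping is still supported on
  input). Reads are emitted un-deduplicated.

The truth bundle records every fragment's fate and aggregates molecule
states *before* degradation — the target an unbiased measurement should
recover. Named presets (`null`, `heat_like`, `alkaline_like`,
`ambs_like`, `kapa_like`, `pbat_like`) encode the published *fold*
relationships rather than absolute rates, which are not published: heat
denaturation set to a twofold C-poor/C-rich recovery ratio, alkaline to
1.3-fold but with four times the conversion failure, modification
protection to a fourfold recovery gain for C-rich fragments, and the
amplification-free preset to zero cycles.

What the simulator does not emulate: sequencer base-calling errors and
quality scores, adapter chemistry, strand reannealing or template
switching, mappability (reads are emitted with their true coordinates, so
alignment error is out of frame), and explicit fragmentation-site
resampling. Passing the recovery suites therefore shows that the
*diagnostics measure what they claim to measure* under the modelled
chemistry — not that any particular real protocol has these exact rates.

## Numerical conventions and degenerate inputs

Percentages are undefined (NA, flagged) rather than zero wherever a
denominator is empty: zero-coverage positions, regions failing the
observation minimum, empty GC bins, zero-read strand counts. Log2 ratios
require both fractions positive. Ties in the majority-context vote at a
position are broken by first-sorted context and counted as conflicts.
Fixed-cytosine tiles discard the trailing remainder (< n positions) and
count it. A window request longer than the sequence degrades to a single
whole-sequence window; a genome shorter than the mean fragment length is
fragmented as whole molecules with a warning. The non-conversion filter
partition always satisfies seen = kept + removed.

## Problem sizes used in the validation suites

The test and acceptance suites run entirely on synthetic data sized for
desk-scale reproducibility: a 10-kb genome at 50× fragment depth for the
null (all-biases-off) suite, averaged over five replicate simulations for
the rank-correlation flatness check (a single 100-tile replicate's
Spearman rho has null spread comparable to the ±0.1 band being asserted);
10,000 molecules per fragment pool for the twofold-recovery calibration;
150–600-kb genomes at 10–41× for the conversion-correction and
quantification-strategy comparisons. The mammalian-like context ratio is
computed on a 200-kb synthetic genome with GC 0.42 and CpG
observed/expected 0.2 — a code-generated stand-in, since the claim is
about CpG depletion, which the generator reproduces, not about any
particular assembly.

## Known limitations

Gapped and soft-clipped alignments are rejected, not reconciled. The
relative-trend normalisation (mean genome-wide per-base coverage) is a
declared approximation of interactive genome-browser behaviour. The
threshold filter zeroes calls rather than dropping positions — the
alternative reading is documented and easy to emulate downstream. CH
context is the union of CHG and CHH throughout, and unknown-context calls
are treated as CH by the read filter unless switched off.
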