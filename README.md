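# wgbsbias

Bias diagnostics, artefact filtering and methylation quantification for
whole-genome bisulfite sequencing (WGBS).

Bisulfite conversion is what makes base-resolution DNA methylation maps
possible — and it is also the main source of their systematic errors.
The chemistry breaks DNA preferentially at *unmethylated* cytosines, so
C-rich unmethylated sequences are depleted from the library and global
5mC is overestimated; a fraction of unmethylated cytosines escape
conversion and are read as methylated, which in CpG-depleted genomes
surfaces mostly as spurious non-CpG (CH) methylation; and PCR
preferentially amplifies the molecules that retained more cytosines —
the methylated and the poorly converted ones — compounding both effects.

`wgbsbias` is for anyone who analyses or compares WGBS libraries and
wants to know how biased they are and what to do about it. It provides:

- **Composition diagnostics** — observed vs genomic-expected mono- and
  dinucleotide content of the mapped data with log2 ratios (a depleted C
  row means degradation, C enrichment means poor conversion, G/AT skews
  mean polymerase bias), plus strand-specific base-content wiggle tracks.
- **Coverage diagnostics** — strand-resolved read counts on GC-skewed
  references (telomere, satellite, mtDNA), tandem-repeat unit histograms
  on raw reads, read coverage as a function of tile G/C content with
  artefact-window masking, and relative coverage trends over feature sets
  such as CpG islands.
- **Conversion-artefact corrections** — the 3xC filter (remove reads with
  ≥ 3 consecutive unconverted CH calls), methylation-threshold filtering,
  background subtraction against an unmethylated control of the same
  genome, and spike-in conversion-efficiency estimation.
- **Quantification** — per-cytosine extraction from call strings, pooled
  vs per-cytosine-mean region methylation, fixed-cytosine-count tiles,
  differential-region selection and overlap counting.
- **A generative simulator** of bisulfite library preparation
  (per-unmethylated-cytosine breakage with modification protection,
  molecule-correlated and motif-specific conversion failure,
  GC-dependent PCR) that emits aligned reads in SAM with Bismark-style
  XM/XR/XG tags together with the full ground truth, so every diagnostic
  above is validated by parameter recovery.

## The model in brief

A single-strand molecule with $k_u$ unmodified and $k_m$ modified
cytosines survives bisulfite treatment with probability

$$P(\text{survive}) = (1-\beta_u)^{k_u}\,(1-\beta_m)^{k_m}, \qquad \beta_m \le \beta_u,$$

so a twofold recovery difference between fragments of 15% and 30%
cytosine content pins down $\beta_u = 1 - 2^{-1/(0.15L)}$
(`calibrate_breakage()`). Unmethylated cytosines on surviving molecules
escape conversion with a context-specific marginal rate realised as a
molecule-level mixture (most molecules fail rarely; a small fraction
fail almost everywhere — which is why *consecutive* unconverted CH calls
identify bad molecules). Each PCR cycle copies a molecule with
efficiency `clamp(e0 + slope · (GC_post − g_ref), 0, 1)` where `GC_post`
counts genomic Gs plus retained cytosines. Pooled region methylation
`100·Σmeth/Σtotal` inherits any coverage–methylation correlation these
mechanisms induce; averaging per-cytosine percentages does not.

## Worked example

Simulate a heat-denaturation-style library (strong degradation, good
conversion, GC-biasing PCR) on a 50-kb mammalian-like synthetic genome
with 70% CpG methylation, then run the diagnostics:

```r
library(wgbsbias)

genome <- synth_genome(50000, gc = 0.42, cpg_factor = 0.2, seed = 42)
pre <- sim_preset("heat_like")
sim <- simulate_wgbs(genome, methylome_model(p_mCG = 0.7),
                     pre$protocol, pre$pcr, depth = 20, seed = 42)

br <- bias_report(observed_composition(sim$alignments, genome,
                                       orientation = "parent"),
                  genome_composition(genome))
subset(br, k == 1)[, c("kmer", "genome_pct", "sample_pct", "log2_ratio")]
#>   kmer genome_pct sample_pct log2_ratio
#> 1    A       30.5       30.4   -0.00381
#> 2    C       22.4       18.4   -0.28228
#> 3    G       16.9       21.0    0.31370
#> 4    T       30.2       30.2   -0.00241

pc <- extract_per_cytosine(sim$alignments, contexts = "CG")
global_methylation(pc)                      # measured: 70.55
sim$truth$global$true_percent[
  sim$truth$global$context == "CG"]         # truth:    69.87

filter_nonconversion_reads(sim$alignments)
#> filter_outcome: 2874 seen, 2868 kept, 6 removed (0.21%)
```

The composition report shows the two signatures at once: cytosine is
depleted on the molecule strand (log2 −0.28, degradation of unmethylated
C-rich molecules) while G is enriched (+0.31, GC-preferring PCR), and the
measured global mCG overshoots the known truth — the bias the
quantification tools are designed to expose and resist.

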