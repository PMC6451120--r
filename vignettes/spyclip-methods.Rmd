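---
title: "Methods: crosslink-site cluster analysis for UMI-tagged CLIP libraries"
author: "spyclip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crosslink-site cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`spyclip` analyses CLIP libraries produced by a covalent-purification
protocol in which reverse transcription truncates at the crosslinked
nucleotide. The central modelling assumption follows from the chemistry:
**the crosslink site is the strand-aware 5' genomic start of the mapped
read** (the 3' end of the insert cDNA). Every downstream quantity — PCR
deduplication keys, cluster summits, motif windows, metagene positions — is
anchored at that single nucleotide.

The pipeline stages, in dependency order:

1. **Read processing.** A 10-nt UMI is sliced from the read 5' end and kept
   as the read's molecular identity. The 3' adapter is removed at the
   leftmost position where a prefix of the adapter matches the read suffix
   with at least 3 nt of overlap and at most a 10% mismatch rate. Inserts
   are kept iff their length is in [30, 65] nt.
2. **Deduplication.** Reads sharing (chromosome, strand, 5' start, UMI) are
   PCR copies; the first in coordinate-sorted order is kept. A saturation
   curve subsamples the raw library at increasing depths and reports the
   usable (post-collapse) fraction.
3. **Cluster calling.** Distinct 5' starts become sites with read counts.
   Sites are chained by single linkage with a maximum gap of 3 nt; the
   summit is the leftmost maximal-count site. Cluster abundance is RPM
   (reads x 10^6 / usable library size).
4. **Input deduction.** A cluster is RBP-specific iff its CLIP RPM is at
   least 15-fold its input RPM over the same span. A cluster with zero
   input reads receives a one-read pseudocount *in the input*, so loci
   absent from input remain callable without dividing by zero.
5. **Annotation.** Clusters are labelled 5'UTR / CDS / intron / 3'UTR by a
   configurable precedence order (one order appropriate for spliceosomal
   RBPs, one for AGO2-like RBPs); anything overlapping no region is
   intergenic. Distributions can be corrected by total region length.
6. **Motifs.** Pentamer occurrences in [-10, +10] windows around specific
   cluster summits are compared to 100 random draws in which each window is
   replaced by an equal-width window from the same annotation class; a
   z-score >= 200 calls a binding motif. The crosslink (CL) profile is the
   per-offset fraction of reads whose genomic tetramer is all-pyrimidine.
7. **miRNA analysis.** Mature miRNAs are counted allowing 3' truncation by
   up to 2 nt or genomic-templated extension by up to 2 nt, with fractional
   assignment of ambiguous reads. Cluster sequences are scanned for reverse
   complements of every successive miRNA 7-mer; seed (nt 2-8) complement
   density is profiled around summits. Harringtonine (HAR) enrichment
   combines cluster loci across conditions and flags loci with >= 2-fold
   RPM gain.
8. **Metagene.** Read 5' starts are projected through the exon chain of the
   longest transcript per gene into spliced coordinates and binned
   50+50+50 (5'UTR | CDS | 3'UTR) for coding genes or 150 bins for
   lncRNAs, normalising each transcript's counts to sum 1 before summation.

# The synthetic-data generator

Because the protocol's guarantees are positional and arithmetical, every
stage is tested against synthetic experiments with a complete ground-truth
ledger (`sim_config()` / `simulate_spyclip_experiment()`). The generator is a
first-class component, not a test shim.

**Defaults are the study conditions.** A default experiment has a 100 kb
genome on 2 chromosomes carrying 20 genes (3 histone-like single-exon genes,
3 lncRNAs, 14 coding genes of 150 nt 5'UTR, 3 x 250 nt CDS exons, 2 x 400 nt
introns, 400 nt 3'UTR), 200 planted crosslink sites with Poisson(30) reads
each, a planted TCTCT motif at each site, 20% background reads, 5%
contaminant (rRNA-like) reads at 2 loci present in both CLIP and input, PCR
duplication rate 1.0 (copies = 1 + Poisson(1)), 10-nt UMIs, truncated
geometric insert lengths over (20, 80), 20 miRNAs with reverse-complement
7-mers planted 6 nt 3'-ward of half the sites, and a 20,000-read input
library.

Design choices and their rationale:

* **Minimum site separation 30 nt** keeps each planted site in its own
  cluster (window 3) and prevents the planted motif (offsets 0-4) and
  miRNA target 7-mer (offsets 6-12) from overwriting each other, so truth
  tables map 1:1 onto expected clusters.
* **Input depth 20,000.** The input is a deep, universal control shared
  across experiments, so it is realistic for it to be deeper than one CLIP
  library. A shallow input also makes the pseudocount RPM so coarse that
  weak true sites fail the 15-fold test for purely arithmetic reasons,
  which would misrepresent the method.
* **Deterministic stage seeds.** Each stage draws from
  `child_seed(seed, k)`, so standalone calls (e.g. regenerating the miRNA
  set alone) reproduce exactly the same objects as the full experiment, and
  outputs are byte-identical across runs of the same seed.
* **Planting by genome mutation.** Motifs and target complements are
  written into the genome *before* reads are extracted, so reads, genome
  and truth always agree; there is no separate read-level signal model.

Limits: the generator has uniform background, no mapping error, no sequence
error, and block-structured genes; it validates positional arithmetic and
statistical calls, not aligner behaviour.

# Numerical and interpretive choices

Several protocol statements admit more than one reading; the implemented
choices are:

* **Single-linkage window.** "Sites within 3 nt are merged" is implemented
  as transitive chaining: a new cluster starts only when the gap to the
  previous site exceeds 3 nt. This is the standard CLIP practice and is
  what the oracle tests encode.
* **Pseudocount semantics.** The one-read pseudocount applies only when a
  cluster has *zero* input reads; clusters with input evidence use their
  actual counts. With this reading a 30-RPM cluster against a 2-RPM input
  is exactly 15-fold, matching the protocol's worked example.
* **Replicate reproducibility** is the Pearson correlation of log10 RPM
  over the union of cluster loci (merged at the cluster window), with the
  pseudocount filling loci missing from one replicate. At least 3 union
  loci are required.
* **Per-start 7-mer percentages are pooled over miRNAs**: the percentage at
  start *s* is the share of clusters hit at *s* by at least one of the
  scanned miRNAs (not a per-miRNA average).
* **Pentamer counts are total occurrences** (a pentamer occurring twice in
  one window counts twice), for both observed and background windows; a
  21-nt window contributes 17 pentamer starts.
* **Per-transcript metagene normalisation** rescales each transcript's bin
  counts to sum 1 before summation, so a single deep gene cannot dominate
  the profile; `normalize = FALSE` gives raw sums.
* **Coordinates.** All internal coordinates are 1-based inclusive
  (`GenomicRanges`); BED I/O converts to 0-based half-open at the boundary;
  miRNA sequences are RNA-alphabet at the interface and converted to DNA
  internally.

# Problem sizes

Test problem sizes (10,000-read dedup fixtures, 2,000-site clustering
fixtures, 200-site default experiments, 100 background draws) are the
package's own choices: large enough that empirical rates (recall, z-score
calibration, saturation) have tight sampling error, small enough that the
whole suite runs in minutes on one CPU.

# Reproduction

`scripts/acceptance.R` regenerates a default-condition experiment from a
single seed, runs the full analysis against the installed package, and
writes the headline quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
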