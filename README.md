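# spyclip

Crosslink-site cluster analysis for UMI-tagged CLIP sequencing libraries.

## The problem

Covalent-purification CLIP protocols (SpyTag/SpyCatcher-based) produce
libraries in which reverse transcription truncates at the protein-crosslinked
nucleotide, so the crosslink site is the **strand-aware 5' genomic start of
each mapped read**. Given such a library, a matched input control, an
annotation, and optionally a mature miRNA set, the analysis must:

- collapse PCR duplicates on (chromosome, strand, 5' start, UMI), where the
  UMI is a 10-nt tag that serves as the read's molecular identity;
- call **clusters**: distinct 5' starts (sites) chained by single linkage
  with gap ≤ 3 nt, each with a summit (leftmost maximal-count site) and an
  abundance in RPM (reads × 10⁶ / usable reads);
- call a cluster **RBP-specific** iff RPM_CLIP / RPM_input ≥ 15, with a
  one-read pseudocount in the input when a cluster has no input reads;
- annotate clusters into 5'UTR / CDS / intron / 3'UTR with an RBP-appropriate
  precedence order;
- test motif enrichment: pentamer z-scores in [−10, +10] summit windows
  against annotation-class-matched random backgrounds (motif iff z ≥ 200),
  and the per-offset fraction of reads with an all-pyrimidine tetramer
  (the crosslink motif profile);
- quantify miRNAs allowing −2..+2 nt 3' end variants (extensions must be
  genome-templated), scan clusters for reverse complements of successive
  miRNA 7-mers, and profile seed (nt 2–8) complement density;
- build length-normalised metagene profiles (50+50+50 bins over
  5'UTR | CDS | 3'UTR, or 150 bins for lncRNAs).

The package ships a synthetic-data generator with a complete ground-truth
ledger (planted sites, per-molecule PCR copies, planted motifs and miRNA
targets), so every stage is verifiable end-to-end without external data.

## Worked example

```r
library(spyclip)

# simulate a full experiment at the default study conditions
sim <- simulate_spyclip_experiment(sim_config(seed = 1))

# deduplicate, call clusters, quantify, deduct input
dd_clip  <- collapse_duplicates(sim$clip$aligned_bed)
dd_input <- collapse_duplicates(sim$input$aligned_bed)
clusters <- cluster_sites(call_crosslink_sites(dd_clip$usable))
clusters <- quantify_rpm(clusters, length(dd_clip$usable))
clusters <- deduct_input(clusters, dd_input$usable)

c(raw = length(sim$clip$aligned_bed), usable = length(dd_clip$usable),
  clusters = length(clusters), specific = sum(clusters$specific))
#>      raw   usable clusters specific
#>    16191     8063     1475      196

# annotate and summarise the specific clusters
specific <- clusters[clusters$specific]
specific$category <- assign_category(specific, sim$annotation,
                                     category_order_splicing)
round(category_distribution(specific, sim$annotation), 3)
#>          intron three_prime_utr             cds  five_prime_utr      intergenic
#>           0.296           0.168           0.434           0.102           0.000

# pentamer enrichment around summits (planted motif: TCTCT)
z <- pentamer_zscores(specific, sim$genome, sim$annotation,
                      categories = specific$category, seed = 1)
head(z, 3)
#>       pentamer observed bg_mean    bg_sd        z is_motif
#> TCTCT    TCTCT      218   27.98 5.304810 35.82032    FALSE
#> CTCTC    CTCTC      118   16.42 4.632298 21.92864    FALSE
#> CTCTA    CTCTA       69   11.01 3.046757 19.03335    FALSE
```

The planted pentamer tops the ranking; at this desk scale its z-score does
not reach the genome-scale motif-call threshold of 200, so `is_motif` stays
FALSE while the ranking itself is the planted signal.

196 of the 200 planted sites are recovered as specific clusters (recall
0.98) with no false positives (precision 1.0), and the two contaminant loci
— abundant in both CLIP and input — are excluded by input deduction.

The file-based pipeline (`run_config()` + `run_pipeline()`, or the
`inst/scripts/spyclip` command-line wrapper) runs all stages from
genome FASTA / GTF / BED / FASTQ inputs and writes every stage output plus a
checksum manifest; reruns with the same config and seed are byte-identical.

## Reproduction

`scripts/acceptance.R` regenerates a default-condition experiment from a
single seed, runs the full analysis against the installed package, and
writes the headline quantities (usable reads, duplicate fraction, cluster
and specific-cluster counts, site recall/precision, summit accuracy,
planted-pentamer z-score, crosslink-profile peak, miRNA target recovery,
metagene coverage) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

Methodological details, generator assumptions and interpretive choices are
documented in `vignettes/spyclip-methods.Rmd`.
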