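test_that("config validation rejects impossible settings", {
  expect_error(sim_config(background_read_fraction = 1.2), "fraction")
  expect_error(sim_config(insert_length_range = c(0, 50)))
  expect_error(sim_config(motif = "TCXCT"), "alphabet")
  expect_error(sim_config(mirna_length_range = c(10, 12)))
})

test_that("genome and annotation have the configured structure", {
  cfg <- small_config()
  ga <- generate_genome_and_annotation(cfg)
  expect_length(ga$genome, cfg$n_chroms)
  expect_true(all(width(ga$genome) == cfg$genome_length))
  expect_true(all(strsplit(as.character(ga$genome[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_equal(length(ga$annotation$genes), cfg$n_genes)
  expect_setequal(unique(ga$annotation$genes$gene_type),
                  c("protein_coding", "histone_like", "lncRNA"))
  # region blocks of one gene never overlap each other
  for (gid in ga$annotation$genes$gene_id) {
    r <- ga$annotation$regions[ga$annotation$regions$gene_id == gid]
    if (length(r) > 1)
      expect_true(all(countOverlaps(r, r) == 1))
  }
  # histone-like genes are single-exon
  hist_ids <- ga$annotation$genes$gene_id[
    ga$annotation$genes$gene_type == "histone_like"]
  for (gid in hist_ids)
    expect_equal(sum(ga$annotation$exons$gene_id == gid), 1L)
  # lncRNA genes have no CDS regions
  lnc_ids <- ga$annotation$genes$gene_id[
    ga$annotation$genes$gene_type == "lncRNA"]
  for (gid in lnc_ids)
    expect_false(any(ga$annotation$regions$gene_id == gid &
                       ga$annotation$regions$label == "cds"))
})

test_that("a minimal gene config yields exactly four region records", {
  cfg <- sim_config(genome_length = 20000L, n_chroms = 1L, n_genes = 1L,
                    n_histone_like = 0L, n_lncrna = 0L,
                    gene_structure = list(utr5_len = 50L, n_cds_exons = 1L,
                                          cds_exon_len = 200L, n_introns = 1L,
                                          intron_len = 150L, utr3_len = 100L),
                    n_crosslink_sites = 5L, n_contaminant_loci = 0L,
                    seed = 3L)
  ga <- generate_genome_and_annotation(cfg)
  expect_equal(length(ga$annotation$regions), 4L)
  expect_setequal(as.character(ga$annotation$regions$label),
                  c("five_prime_utr", "cds", "intron", "three_prime_utr"))
})

test_that("identical seeds give byte-identical outputs", {
  cfg <- small_config(seed = 21L)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_spyclip_experiment(cfg, outdir = d1)
  simulate_spyclip_experiment(cfg, outdir = d2)
  for (f in c("genome.fa", "annotation.gtf", "reads.fastq", "clip.bed",
              "input.bed", "mirnas.fa", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("emitted read count equals the duplicate ledger total", {
  sim <- small_sim()
  expect_equal(length(sim$clip$aligned_bed),
               sum(sim$clip$truth$duplicate_ledger))
  expect_equal(length(sim$clip$reads_fastq), length(sim$clip$aligned_bed))
})

test_that("every read traces to a truth record and sites match 5' starts", {
  sim <- small_sim()
  bed <- sim$clip$aligned_bed
  mol <- sim$clip$truth$molecules
  expect_true(all(bed$molecule_id %in% mol$molecule_id))
  m <- mol[match(bed$molecule_id, mol$molecule_id), ]
  expect_equal(five_prime_start(bed), m$position)
  site_mol <- mol[mol$origin == "site", ]
  tr <- sim$clip$truth$crosslink_sites
  expect_equal(site_mol$position, tr$position[site_mol$site_index])
})

test_that("zero duplication rate leaves nothing to collapse", {
  cfg <- small_config(seed = 5L, pcr_duplication_rate = 0)
  sim <- simulate_clip_library(cfg,
                               generate_genome_and_annotation(cfg)$genome,
                               generate_genome_and_annotation(cfg)$annotation)
  expect_true(all(sim$truth$duplicate_ledger == 1L))
  dd <- collapse_duplicates(sim$aligned_bed)
  expect_equal(dd$n_duplicates, 0L)
})

test_that("planted motif is recoverable from the genome at every site", {
  sim <- small_sim()
  mp <- sim$clip$truth$planted_motif_positions
  expect_gt(nrow(mp), 0)
  s <- extract_strand_seq(sim$genome, mp$chrom, mp$strand, mp$position, 5L)
  expect_true(all(s == small_config()$motif))
})

test_that("an RNA-alphabet motif is planted as DNA", {
  cfg <- small_config(seed = 9L, motif = "UCUCU")
  expect_equal(cfg$motif, "TCTCT")
  ga <- generate_genome_and_annotation(cfg)
  lib <- simulate_clip_library(cfg, ga$genome, ga$annotation)
  mp <- lib$truth$planted_motif_positions
  s <- extract_strand_seq(lib$genome, mp$chrom, mp$strand, mp$position, 5L)
  expect_true(all(s == "TCTCT"))
})

test_that("plus-strand BED record spans crosslink site to site + insert", {
  sim <- small_sim()
  mol <- sim$clip$truth$molecules
  bed <- sim$clip$aligned_bed
  m <- mol[match(bed$molecule_id, mol$molecule_id), ]
  plus <- as.character(strand(bed)) == "+"
  expect_equal(start(bed)[plus], m$position[plus])
  expect_equal(end(bed)[plus], m$position[plus] + m$insert_len[plus] - 1L)
  minus <- !plus
  expect_equal(end(bed)[minus], m$position[minus])
})

test_that("input starts are uniform over gene space when no contaminants", {
  cfg <- small_config(seed = 31L, n_contaminant_loci = 0L,
                      n_input_reads = 8000L)
  ga <- generate_genome_and_annotation(cfg)
  inp <- simulate_input_library(cfg, ga$genome, ga$annotation)
  expect_equal(nrow(inp$molecules), 8000L)
  # chi-square goodness of fit of 5' starts across region intervals,
  # expected proportional to region width
  p5 <- inp$molecules$position
  reg <- ga$annotation$regions
  hits <- countOverlaps(reg, GRanges(inp$molecules$chrom,
                                     IRanges(p5, p5),
                                     strand = inp$molecules$strand))
  # positions near interval 3' edges are resampled (insert must fit), so
  # drop the few edge-affected intervals from the comparison
  expected <- width(reg) / sum(width(reg)) * sum(hits)
  chi2 <- sum((hits - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = length(reg) - 1))
})

test_that("miRNA 7-mer complement planting matches manual reverse complement", {
  # nt 2-8 of this miRNA are GAGGUAG; the genomic complement is CTACCTC
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  seg <- substr(rna_to_dna(mir), 2, 8)
  expect_equal(seg, "GAGGTAG")
  expect_equal(revcomp_dna(seg), "CTACCTC")
  sim <- small_sim()
  tg <- sim$planted_targets
  expect_gt(nrow(tg), 0)
  ms <- rna_to_dna(as.character(sim$mirnas[tg$mirna]))
  pat <- revcomp_dna(substr(ms, tg$mirna_start, tg$mirna_start + 6L))
  pos <- ifelse(tg$strand == "-", tg$position - tg$target_offset,
                tg$position + tg$target_offset)
  found <- extract_strand_seq(sim$genome, tg$chrom, tg$strand, pos, 7L)
  expect_true(all(found == pat))
})

test_that("planted_target_fraction spans none to all clusters", {
  cfg0 <- small_config(seed = 41L, planted_target_fraction = 0)
  ga <- generate_genome_and_annotation(cfg0)
  m0 <- simulate_mirna_set(cfg0, ga$genome, ga$annotation)
  expect_equal(nrow(m0$planted_targets), 0L)
  cfg1 <- small_config(seed = 41L, planted_target_fraction = 1)
  m1 <- simulate_mirna_set(cfg1, ga$genome, ga$annotation)
  expect_equal(nrow(m1$planted_targets), cfg1$n_crosslink_sites)
  expect_true(all(m1$planted_targets$mirna_start >= 1))
  lens <- nchar(as.character(m1$mirnas[m1$planted_targets$mirna]))
  expect_true(all(m1$planted_targets$mirna_start + 6 <= lens))
})

test_that("all-zero site strength is an empty-library error", {
  cfg <- small_config(seed = 51L, site_strength_mean = 0)
  ga <- generate_genome_and_annotation(cfg)
  expect_error(simulate_clip_library(cfg, ga$genome, ga$annotation),
               "empty library")
})
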