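#' Simulation configuration for synthetic SpyCLIP experiments
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' a small but realistic truncation-CLIP experiment: ~200 crosslink sites at a
#' mean depth of 30 reads per site, 20% background reads placed uniformly over
#' annotated gene space, a PCR duplication rate of 1 expected extra copy per
#' molecule, 10-nt UMIs, and insert lengths spanning a range deliberately wider
#' than the 30-65 nt usable window so the length filter has work to do.
#'
#' @param genome_length Bases per chromosome.
#' @param n_chroms Number of chromosomes.
#' @param n_genes Total genes placed (non-overlapping, random strand).
#' @param gene_structure List with `utr5_len`, `n_cds_exons`, `cds_exon_len`,
#'   `n_introns`, `intron_len`, `utr3_len` for protein-coding genes. Introns
#'   are interleaved between CDS exons; surplus introns sit before the 3'UTR.
#' @param n_histone_like Genes emitted as single-exon, intron-less
#'   "histone_like" protein-coding genes.
#' @param n_lncrna Genes emitted as lncRNAs (exons only, no CDS).
#' @param n_crosslink_sites Planted crosslink sites.
#' @param site_strength_mean Mean reads per site (Poisson).
#' @param motif Planted pentamer (RNA or DNA alphabet) or `NULL` for none.
#' @param motif_offset Offset of the planted motif start 3'-ward of the
#'   crosslink site (0 = motif starts at the site).
#' @param umi_length UMI length in nt.
#' @param insert_length_range `c(min, max)` insert lengths generated.
#' @param insert_length_decay Decay parameter of the truncated geometric
#'   insert-length distribution over `insert_length_range`.
#' @param pcr_duplication_rate Expected extra PCR copies per unique molecule;
#'   copies are drawn as `1 + Poisson(rate)`.
#' @param background_read_fraction Fraction of unique CLIP molecules placed
#'   uniformly over annotated gene space instead of at planted sites.
#' @param n_contaminant_loci Number of rRNA-like high-abundance loci present in
#'   both the CLIP and the input library.
#' @param contaminant_read_fraction Fraction of each library's unique molecules
#'   drawn from the contaminant loci.
#' @param n_input_reads Unique molecules in the universal input library.
#' @param n_mirnas Number of mature miRNAs simulated.
#' @param mirna_length_range `c(min, max)` mature miRNA lengths (min >= 16).
#' @param planted_target_fraction Fraction of crosslink sites receiving a
#'   planted miRNA 7-mer complement.
#' @param mirna_target_offset Offset of the planted 7-mer complement 3'-ward of
#'   the crosslink site; the default keeps it clear of the planted pentamer.
#' @param min_site_separation Minimum distance between planted sites, so each
#'   truth site maps to its own cluster.
#' @param adapter 3' adapter sequence appended to every read.
#' @param seed Integer RNG seed; identical configs give byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       n_chroms = 2L,
                       n_genes = 20L,
                       gene_structure = list(utr5_len = 150L, n_cds_exons = 3L,
                                             cds_exon_len = 250L, n_introns = 2L,
                                             intron_len = 400L, utr3_len = 400L),
                       n_histone_like = 3L,
                       n_lncrna = 3L,
                       n_crosslink_sites = 200L,
                       site_strength_mean = 30,
                       motif = "TCTCT",
                       motif_offset = 0L,
                       umi_length = 10L,
                       insert_length_range = c(20L, 80L),
                       insert_length_decay = 0.05,
                       pcr_duplication_rate = 1.0,
                       background_read_fraction = 0.2,
                       n_contaminant_loci = 2L,
                       contaminant_read_fraction = 0.05,
                       n_input_reads = 20000L,
                       n_mirnas = 20L,
                       mirna_length_range = c(20L, 23L),
                       planted_target_fraction = 0.5,
                       mirna_target_offset = 6L,
                       min_site_separation = 30L,
                       adapter = "AGATCGGAAGAGC",
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_chroms = as.integer(n_chroms),
              n_genes = as.integer(n_genes),
              gene_structure = gene_structure,
              n_histone_like = as.integer(n_histone_like),
              n_lncrna = as.integer(n_lncrna),
              n_crosslink_sites = as.integer(n_crosslink_sites),
              site_strength_mean = site_strength_mean,
              motif = if (is.null(motif)) NULL else rna_to_dna(motif),
              motif_offset = as.integer(motif_offset),
              umi_length = as.integer(umi_length),
              insert_length_range = as.integer(insert_length_range),
              insert_length_decay = insert_length_decay,
              pcr_duplication_rate = pcr_duplication_rate,
              background_read_fraction = background_read_fraction,
              n_contaminant_loci = as.integer(n_contaminant_loci),
              contaminant_read_fraction = contaminant_read_fraction,
              n_input_reads = as.integer(n_input_reads),
              n_mirnas = as.integer(n_mirnas),
              mirna_length_range = as.integer(mirna_length_range),
              planted_target_fraction = planted_target_fraction,
              mirna_target_offset = as.integer(mirna_target_offset),
              min_site_separation = as.integer(min_site_separation),
              adapter = rna_to_dna(adapter),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length > 0, cfg$n_chroms > 0, cfg$n_genes > 0,
            cfg$n_crosslink_sites > 0, cfg$site_strength_mean >= 0,
            cfg$umi_length >= 0,
            length(cfg$insert_length_range) == 2L,
            cfg$insert_length_range[1] >= 1L,
            cfg$insert_length_range[1] <= cfg$insert_length_range[2],
            cfg$pcr_duplication_rate >= 0,
            cfg$background_read_fraction >= 0, cfg$background_read_fraction <= 1,
            cfg$contaminant_read_fraction >= 0, cfg$contaminant_read_fraction <= 1,
            cfg$background_read_fraction + cfg$contaminant_read_fraction < 1,
            cfg$planted_target_fraction >= 0, cfg$planted_target_fraction <= 1,
            cfg$n_histone_like + cfg$n_lncrna <= cfg$n_genes,
            cfg$mirna_length_range[1] >= 16L)
  if (!is.null(cfg$motif) && !grepl("^[ACGT]+$", cfg$motif))
    stop("motif must be over the A/C/G/U/T alphabet")
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Genome + annotation

# One gene's block layout, 5'->3' in transcript orientation.
# Returns data.frame(label, len) with labels among the four region classes
# (lncRNA genes use "exon"/"intron" placeholders that carry no region label).
gene_block_layout <- function(gene_type, gs) {
  if (gene_type == "histone_like") {
    return(data.frame(label = c("five_prime_utr", "cds", "three_prime_utr"),
                      len = c(50L, 400L, 100L)))
  }
  if (gene_type == "lncRNA") {
    return(data.frame(label = c("lnc_exon", "lnc_intron", "lnc_exon"),
                      len = c(400L, 300L, 400L)))
  }
  labs <- "five_prime_utr"
  lens <- gs$utr5_len
  n_int <- gs$n_introns
  for (i in seq_len(gs$n_cds_exons)) {
    labs <- c(labs, "cds"); lens <- c(lens, gs$cds_exon_len)
    if (i < gs$n_cds_exons && n_int > 0) {
      labs <- c(labs, "intron"); lens <- c(lens, gs$intron_len)
      n_int <- n_int - 1L
    }
  }
  while (n_int > 0) {  # surplus introns before the 3'UTR
    labs <- c(labs, "intron"); lens <- c(lens, gs$intron_len)
    n_int <- n_int - 1L
  }
  labs <- c(labs, "three_prime_utr"); lens <- c(lens, gs$utr3_len)
  data.frame(label = labs, len = as.integer(lens))
}

#' Generate a toy genome and gene annotation
#'
#' Lays out non-overlapping genes with 5'UTR/CDS/intron/3'UTR blocks on random
#' strands over random uppercase A/C/G/T chromosomes. A configurable subset of
#' genes is "histone_like" (single exon, no intron) and another "lncRNA" (no
#' CDS). Also picks the rRNA-like contaminant loci shared by the CLIP and
#' input simulators.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named `DNAStringSet`) and `annotation`
#'   (an `annotation_model`).
#' @export
generate_genome_and_annotation <- function(config) {
  validate_sim_config(config)
  gs <- config$gene_structure
  set.seed(child_seed(config$seed, 1L))
  genome <- DNAStringSet(vapply(seq_len(config$n_chroms),
                                function(i) random_dna(config$genome_length),
                                character(1)))
  names(genome) <- paste0("chr", seq_len(config$n_chroms))

  types <- c(rep("histone_like", config$n_histone_like),
             rep("lncRNA", config$n_lncrna),
             rep("protein_coding",
                 config$n_genes - config$n_histone_like - config$n_lncrna))
  layouts <- lapply(types, gene_block_layout, gs = gs)
  glens <- vapply(layouts, function(x) sum(x$len), integer(1))
  if (any(glens + 200L > config$genome_length))
    stop("gene blocks exceed chromosome length; increase genome_length")

  # non-overlapping placement with a 100-bp margin, rejection sampling
  occupied <- vector("list", config$n_chroms)
  names(occupied) <- names(genome)
  for (ch in names(genome)) occupied[[ch]] <- IRanges()
  chrom <- character(config$n_genes)
  gstart <- integer(config$n_genes)
  gstrand <- character(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      ch <- sample(names(genome), 1L)
      s <- sample.int(config$genome_length - glens[i] - 100L, 1L) + 50L
      cand <- IRanges(s - 100L, s + glens[i] + 100L)
      if (!any(overlapsAny(cand, occupied[[ch]]))) {
        occupied[[ch]] <- c(occupied[[ch]], cand)
        chrom[i] <- ch; gstart[i] <- s
        gstrand[i] <- sample(c("+", "-"), 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place gene ", i, "; genome too small (sizing error)")
  }

  # expand layouts to genomic intervals; block order follows transcript
  # orientation, so minus-strand genes lay blocks right-to-left
  region_rows <- list()
  exon_rows <- list()
  for (i in seq_len(config$n_genes)) {
    lay <- layouts[[i]]
    n <- nrow(lay)
    ord <- if (gstrand[i] == "+") seq_len(n) else rev(seq_len(n))
    lens <- lay$len[ord]
    starts <- gstart[i] + cumsum(c(0L, lens[-length(lens)]))
    ends <- starts + lens - 1L
    # map back to transcript order
    block_start <- integer(n); block_end <- integer(n)
    block_start[ord] <- starts; block_end[ord] <- ends
    gid <- sprintf("gene%03d", i)
    tid <- sprintf("tx%03d", i)
    is_intron <- lay$label %in% c("intron", "lnc_intron")
    lab <- lay$label
    lab[lab == "lnc_intron"] <- "intron"
    keep_region <- lay$label != "lnc_exon"  # lncRNA exons carry no region label
    region_rows[[i]] <- data.frame(chrom = chrom[i], start = block_start[keep_region],
                                   end = block_end[keep_region], strand = gstrand[i],
                                   label = lab[keep_region], gene_id = gid,
                                   stringsAsFactors = FALSE)
    exon_rows[[i]] <- data.frame(chrom = chrom[i], start = block_start[!is_intron],
                                 end = block_end[!is_intron], strand = gstrand[i],
                                 label = lay$label[!is_intron], gene_id = gid,
                                 transcript_id = tid, stringsAsFactors = FALSE)
  }
  regions_df <- do.call(rbind, region_rows)
  exons_df <- do.call(rbind, exon_rows)

  genes <- GRanges(chrom, IRanges(gstart, gstart + glens - 1L), strand = gstrand,
                   gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
                   gene_type = types)
  seqlevels(genes) <- names(genome)

  regions <- GRanges(regions_df$chrom, IRanges(regions_df$start, regions_df$end),
                     strand = regions_df$strand, label = regions_df$label,
                     gene_id = regions_df$gene_id)
  seqlevels(regions) <- names(genome)

  # merge adjacent exonic blocks (UTR+CDS share an exon) into exon features
  exons <- GRanges(exons_df$chrom, IRanges(exons_df$start, exons_df$end),
                   strand = exons_df$strand, gene_id = exons_df$gene_id,
                   transcript_id = exons_df$transcript_id)
  merged <- GenomicRanges::reduce(split(exons, exons$transcript_id))
  tx_ids <- rep(names(merged), elementNROWS(merged))
  exons <- unlist(merged, use.names = FALSE)
  exons$transcript_id <- tx_ids
  exons$gene_id <- exons_df$gene_id[match(tx_ids, exons_df$transcript_id)]
  seqlevels(exons) <- names(genome)

  annotation <- new_annotation_model(genes = genes, regions = regions,
                                     exons = exons,
                                     chrom_lengths = setNames(width(genome),
                                                              names(genome)))

  # contaminant loci: single 5'-start positions inside annotated gene space
  if (config$n_contaminant_loci > 0) {
    pool <- annotation$regions
    pick <- sample.int(length(pool), config$n_contaminant_loci, replace = TRUE)
    pos <- start(pool)[pick] +
      vapply(width(pool)[pick], function(w) sample.int(w, 1L) - 1L, integer(1))
    annotation$contaminant_loci <- GRanges(seqnames(pool)[pick],
                                           IRanges(pos, pos),
                                           strand = strand(pool)[pick])
  } else {
    annotation$contaminant_loci <- GRanges()
  }
  list(genome = genome, annotation = annotation)
}

# ---------------------------------------------------------------------------
# Crosslink sites and planting

# Deterministic site choice shared by the CLIP and miRNA simulators.
choose_crosslink_sites <- function(config, annotation) {
  set.seed(child_seed(config$seed, 2L))
  max_len <- config$insert_length_range[2]
  sep <- config$min_site_separation
  pool <- annotation$regions
  pool_chrom <- as.character(seqnames(pool))
  pool_strand <- as.character(strand(pool))
  n_want <- config$n_crosslink_sites
  ch_v <- character(n_want); st_v <- character(n_want)
  pos_v <- integer(n_want); cls_v <- character(n_want)
  n_found <- 0L
  for (try in seq_len(n_want * 60L)) {
    if (n_found >= n_want) break
    i <- sample.int(length(pool), 1L)
    pos <- start(pool)[i] + sample.int(width(pool)[i], 1L) - 1L
    ch <- pool_chrom[i]; st <- pool_strand[i]
    lo <- if (st == "-") pos - max_len + 1L else pos
    hi <- if (st == "-") pos else pos + max_len - 1L
    if (lo < 1L || hi > annotation$chrom_lengths[ch]) next
    if (n_found > 0L) {
      sel <- seq_len(n_found)
      if (any(ch_v[sel] == ch & abs(pos_v[sel] - pos) <= 2L * sep)) next
    }
    n_found <- n_found + 1L
    ch_v[n_found] <- ch; st_v[n_found] <- st
    pos_v[n_found] <- pos; cls_v[n_found] <- pool$label[i]
  }
  if (n_found < n_want)
    stop("could not place ", n_want,
         " crosslink sites with the requested separation")
  data.frame(chrom = ch_v, strand = st_v, position = pos_v,
             annotation_class = cls_v, stringsAsFactors = FALSE)
}

# Overwrite genome sequence so the strand-aware window starting `offset` bases
# 3'-ward of each site reads `motif_dna` (5'->3' on the site strand).
plant_sequence_at <- function(genome, chrom, strand, position, offset, motif_dna) {
  k <- nchar(motif_dna)
  lo <- ifelse(strand == "-", position - offset - k + 1L, position + offset)
  hi <- lo + k - 1L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    vals <- ifelse(strand[idx] == "-", revcomp_dna(motif_dna[idx]), motif_dna[idx])
    genome[[ch]] <- Biostrings::replaceAt(genome[[ch]],
                                          IRanges(lo[idx], hi[idx]),
                                          DNAStringSet(vals))
  }
  genome
}

# Truncated geometric insert lengths over [min, max].
rtrunc_geom <- function(n, range, decay) {
  vals <- range[1]:range[2]
  p <- (1 - decay)^(vals - range[1]) * decay
  sample(vals, n, replace = TRUE, prob = p / sum(p))
}

# Draw one library's unique molecules given 5'-start positions.
build_molecules <- function(config, genome, df) {
  n <- nrow(df)
  max_len <- config$insert_length_range[2]
  len <- rtrunc_geom(n, config$insert_length_range, config$insert_length_decay)
  # inserts must fit inside the chromosome; site positions were pre-checked
  clen <- setNames(width(genome), names(genome))[df$chrom]
  room <- ifelse(df$strand == "-", df$position, clen - df$position + 1L)
  len <- pmin(len, room)
  umi <- random_umis(n, config$umi_length)
  copies <- 1L + rpois(n, config$pcr_duplication_rate)
  cbind(df, data.frame(insert_len = len, umi = umi, copies = copies,
                       stringsAsFactors = FALSE))
}

molecules_to_bed <- function(mol, library_id) {
  starts <- ifelse(mol$strand == "-", mol$position - mol$insert_len + 1L, mol$position)
  ends <- starts + mol$insert_len - 1L
  idx <- rep(seq_len(nrow(mol)), mol$copies)
  copy_n <- sequence(mol$copies)
  gr <- GRanges(mol$chrom[idx], IRanges(starts[idx], ends[idx]),
                strand = mol$strand[idx])
  gr$name <- paste0(mol$molecule_id[idx], "_c", copy_n, ":", mol$umi[idx])
  gr$score <- 0L
  gr$umi <- mol$umi[idx]
  gr$library_id <- library_id
  gr$molecule_id <- mol$molecule_id[idx]
  gr
}

#' Simulate a CLIP library with a complete ground-truth ledger
#'
#' Each unique molecule is a UMI, an insert whose genomic 5' start is its
#' crosslink site (the insert extends 3'-ward along the transcript strand),
#' and a 3' adapter. PCR copies are drawn as `1 + Poisson(rate)` per molecule.
#' Background molecules are placed uniformly over annotated gene space, and
#' contaminant molecules at the shared rRNA-like loci. If a motif is
#' configured it is written into the genome at every planted site before
#' inserts are extracted, so the returned (possibly modified) genome and the
#' reads agree.
#'
#' @param config A [sim_config()].
#' @param genome,annotation Output of [generate_genome_and_annotation()].
#' @param sites Optional precomputed site table (internal use); by default the
#'   deterministic site choice for `config` is used.
#' @param library_id Library label carried on every read.
#' @return List with `genome` (motif-planted), `reads_fastq` (named
#'   `DNAStringSet` of full raw reads), `aligned_bed` (`GRanges`, one record
#'   per PCR copy), and `truth` (crosslink sites, molecule ledger, duplicate
#'   ledger, planted motif positions).
#' @export
simulate_clip_library <- function(config, genome, annotation, sites = NULL,
                                  library_id = "clip") {
  validate_sim_config(config)
  if (is.null(sites)) sites <- choose_crosslink_sites(config, annotation)
  if (!is.null(config$motif)) {
    n <- nrow(sites)
    genome <- plant_sequence_at(genome, sites$chrom, sites$strand, sites$position,
                                rep(config$motif_offset, n),
                                rep(config$motif, n))
    motif_positions <- data.frame(
      chrom = sites$chrom, strand = sites$strand,
      position = ifelse(sites$strand == "-",
                        sites$position - config$motif_offset,
                        sites$position + config$motif_offset))
  } else {
    motif_positions <- data.frame(chrom = character(), strand = character(),
                                  position = integer())
  }

  set.seed(child_seed(config$seed, 3L))
  strength <- rpois(nrow(sites), config$site_strength_mean)
  if (all(strength == 0))
    stop("all planted sites have zero strength; empty library")
  sites$planted_read_count <- strength

  n_site_mol <- sum(strength)
  frac_sig <- 1 - config$background_read_fraction - config$contaminant_read_fraction
  n_total <- round(n_site_mol / frac_sig)
  n_bg <- round(n_total * config$background_read_fraction)
  n_cont <- n_total - n_site_mol - n_bg

  site_idx <- rep(seq_len(nrow(sites)), strength)
  mol <- data.frame(chrom = sites$chrom[site_idx],
                    strand = sites$strand[site_idx],
                    position = sites$position[site_idx],
                    origin = "site", site_index = site_idx,
                    stringsAsFactors = FALSE)
  if (n_bg > 0) {
    bg <- sample_region_positions(config, genome, annotation, n_bg)
    bg$origin <- "background"; bg$site_index <- NA_integer_
    mol <- rbind(mol, bg)
  }
  if (n_cont > 0 && length(annotation$contaminant_loci) > 0) {
    loci <- annotation$contaminant_loci
    pick <- sample.int(length(loci), n_cont, replace = TRUE)
    mol <- rbind(mol, data.frame(chrom = as.character(seqnames(loci))[pick],
                                 strand = as.character(strand(loci))[pick],
                                 position = start(loci)[pick],
                                 origin = "contaminant", site_index = NA_integer_,
                                 stringsAsFactors = FALSE))
  }
  mol <- build_molecules(config, genome, mol)
  mol$molecule_id <- sprintf("%s_m%06d", library_id, seq_len(nrow(mol)))

  bed <- molecules_to_bed(mol, library_id)
  seqlevels(bed) <- names(genome)

  insert_seq <- extract_strand_seq(genome, mol$chrom, mol$strand, mol$position,
                                   mol$insert_len)
  full <- paste0(mol$umi, insert_seq, config$adapter)
  idx <- rep(seq_len(nrow(mol)), mol$copies)
  fastq <- DNAStringSet(full[idx])
  names(fastq) <- bed$name

  truth <- list(crosslink_sites = sites,
                molecules = mol,
                duplicate_ledger = setNames(mol$copies, mol$molecule_id),
                planted_motif_positions = motif_positions)
  list(genome = genome, reads_fastq = fastq, aligned_bed = bed, truth = truth)
}

# Uniform 5'-start positions over annotated gene space (region intervals),
# leaving room for a maximal insert; strand follows the gene.
sample_region_positions <- function(config, genome, annotation, n) {
  pool <- annotation$regions
  max_len <- config$insert_length_range[2]
  w <- width(pool)
  out <- data.frame(chrom = character(0), strand = character(0),
                    position = integer(0), stringsAsFactors = FALSE)
  while (nrow(out) < n) {
    need <- n - nrow(out)
    i <- sample.int(length(pool), need, replace = TRUE, prob = w)
    pos <- start(pool)[i] +
      vapply(w[i], function(x) sample.int(x, 1L) - 1L, integer(1))
    ch <- as.character(seqnames(pool))[i]
    st <- as.character(strand(pool))[i]
    clen <- setNames(width(genome), names(genome))[ch]
    ok <- ifelse(st == "-", pos - max_len + 1L >= 1L, pos + max_len - 1L <= clen)
    out <- rbind(out, data.frame(chrom = ch[ok], strand = st[ok],
                                 position = pos[ok], stringsAsFactors = FALSE))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate the universal input library
#'
#' Read 5' starts are uniform over annotated gene space (no planted sites),
#' with the same UMI, insert-length and PCR-duplication conventions as the
#' CLIP library, plus an optional share of reads at the shared rRNA-like
#' contaminant loci.
#'
#' @inheritParams simulate_clip_library
#' @return List with `aligned_bed` (`GRanges`) and `molecules` (ledger).
#' @export
simulate_input_library <- function(config, genome, annotation,
                                   library_id = "input") {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 4L))
  n <- config$n_input_reads
  n_cont <- if (length(annotation$contaminant_loci) > 0)
    round(n * config$contaminant_read_fraction) else 0L
  n_uni <- n - n_cont
  mol <- sample_region_positions(config, genome, annotation, n_uni)
  mol$origin <- "background"; mol$site_index <- NA_integer_
  if (n_cont > 0) {
    loci <- annotation$contaminant_loci
    pick <- sample.int(length(loci), n_cont, replace = TRUE)
    mol <- rbind(mol, data.frame(chrom = as.character(seqnames(loci))[pick],
                                 strand = as.character(strand(loci))[pick],
                                 position = start(loci)[pick],
                                 origin = "contaminant", site_index = NA_integer_,
                                 stringsAsFactors = FALSE))
  }
  mol <- build_molecules(config, genome, mol)
  mol$molecule_id <- sprintf("%s_m%06d", library_id, seq_len(nrow(mol)))
  bed <- molecules_to_bed(mol, library_id)
  seqlevels(bed) <- names(genome)
  list(aligned_bed = bed, molecules = mol)
}

#' Simulate a mature miRNA set and plant target complements
#'
#' Generates random RNA-alphabet mature miRNA sequences and, for a configured
#' fraction of crosslink-site loci, writes the DNA reverse complement of one
#' randomly chosen 7-mer of one miRNA into the genome a fixed offset 3'-ward
#' of the site, recording the miRNA name and 1-based 7-mer start.
#'
#' @inheritParams simulate_clip_library
#' @return List with `mirnas` (named `RNAStringSet`), `genome` (with
#'   complements planted) and `planted_targets` (data.frame ledger).
#' @export
simulate_mirna_set <- function(config, genome, annotation, sites = NULL) {
  validate_sim_config(config)
  if (is.null(sites)) sites <- choose_crosslink_sites(config, annotation)
  set.seed(child_seed(config$seed, 5L))
  lens <- sample(config$mirna_length_range[1]:config$mirna_length_range[2],
                 config$n_mirnas, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("mir-%03d", seq_len(config$n_mirnas))
  mirnas <- RNAStringSet(seqs)

  k <- round(config$planted_target_fraction * nrow(sites))
  if (k > 0) {
    chosen <- sample.int(nrow(sites), k)
    mi <- sample.int(config$n_mirnas, k, replace = TRUE)
    s <- vapply(lens[mi], function(L) sample.int(L - 6L, 1L), integer(1))
    if (any(s + 6L > lens[mi])) stop("7-mer start beyond miRNA length")
    seg7 <- substr(rna_to_dna(seqs[mi]), s, s + 6L)
    target_dna <- revcomp_dna(seg7)
    genome <- plant_sequence_at(genome, sites$chrom[chosen],
                                sites$strand[chosen], sites$position[chosen],
                                rep(config$mirna_target_offset, k), target_dna)
    targets <- data.frame(chrom = sites$chrom[chosen],
                          strand = sites$strand[chosen],
                          position = sites$position[chosen],
                          mirna = names(seqs)[mi],
                          mirna_start = s,
                          target_offset = config$mirna_target_offset,
                          stringsAsFactors = FALSE)
  } else {
    targets <- data.frame(chrom = character(), strand = character(),
                          position = integer(), mirna = character(),
                          mirna_start = integer(), target_offset = integer())
  }
  list(mirnas = mirnas, genome = genome, planted_targets = targets)
}

#' Run the whole generator in one call
#'
#' Generates genome and annotation, chooses crosslink sites, plants the miRNA
#' target complements and binding motif, then emits the CLIP and input
#' libraries from the final genome so reads, genome and truth all agree.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, all standard files
#'   (genome.fa, annotation.gtf, reads.fastq, clip.bed, input.bed, mirnas.fa,
#'   truth*.tsv) are written there.
#' @return List with `genome`, `annotation`, `sites`, `mirnas`,
#'   `planted_targets`, `clip` and `input` (the library objects).
#' @export
simulate_spyclip_experiment <- function(config, outdir = NULL) {
  ga <- generate_genome_and_annotation(config)
  sites <- choose_crosslink_sites(config, ga$annotation)
  mir <- simulate_mirna_set(config, ga$genome, ga$annotation, sites = sites)
  clip <- simulate_clip_library(config, mir$genome, ga$annotation, sites = sites)
  input <- simulate_input_library(config, clip$genome, ga$annotation)
  res <- list(genome = clip$genome, annotation = ga$annotation, sites = sites,
              mirnas = mir$mirnas, planted_targets = mir$planted_targets,
              clip = clip, input = input)
  if (!is.null(outdir)) write_simulation(res, outdir)
  res
}

#' Write a simulated experiment to standard file formats
#'
#' @param sim Output of [simulate_spyclip_experiment()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             annotation = file.path(outdir, "annotation.gtf"),
             reads = file.path(outdir, "reads.fastq"),
             clip_bed = file.path(outdir, "clip.bed"),
             input_bed = file.path(outdir, "input.bed"),
             mirnas = file.path(outdir, "mirnas.fa"),
             truth_sites = file.path(outdir, "truth_sites.tsv"),
             truth_molecules = file.path(outdir, "truth.tsv"),
             truth_targets = file.path(outdir, "truth_targets.tsv"))
  writeXStringSet(sim$genome, paths["genome"], width = 60L)
  write_annotation_gtf(sim$annotation, paths["annotation"])
  qual <- BStringSet(strrep("I", width(sim$clip$reads_fastq)))
  writeXStringSet(sim$clip$reads_fastq, paths["reads"], format = "fastq",
                  qualities = qual)
  write_bed6(sim$clip$aligned_bed, paths["clip_bed"])
  write_bed6(sim$input$aligned_bed, paths["input_bed"])
  writeXStringSet(sim$mirnas, paths["mirnas"], width = 60L)
  write.table(sim$clip$truth$crosslink_sites, paths["truth_sites"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$clip$truth$molecules, paths["truth_molecules"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$planted_targets, paths["truth_targets"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
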