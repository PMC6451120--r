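#' Quantify mature miRNAs from IP small-RNA reads
#'
#' A trimmed read counts for a miRNA if it equals the DNA form of the mature
#' sequence truncated by up to 2 nt at the 3' end, or extended by up to 2 nt
#' that are templated by the miRNA's downstream genomic sequence. Reads
#' matching several miRNAs are counted fractionally (1/k) by default. Ranks
#' are assigned by descending count, ties broken lexicographically by name.
#'
#' @param small_rna_reads Character vector of adapter-trimmed reads (DNA).
#' @param mirnas Named `RNAStringSet` or named character vector (RNA).
#' @param genome_3p_context Optional named character vector: for each miRNA,
#'   at least 2 nt of downstream genomic sequence (DNA). Extensions are
#'   disallowed, with a warning, for miRNAs lacking context.
#' @param count_mode `"fractional"` (1/k per ambiguous read) or `"first"`
#'   (assign to the first matching miRNA in input order).
#' @return data.frame with name, count, rank.
#' @export
count_mirnas <- function(small_rna_reads, mirnas,
                         genome_3p_context = NULL,
                         count_mode = c("fractional", "first")) {
  count_mode <- match.arg(count_mode)
  mseq <- rna_to_dna(as.character(mirnas))
  mnames <- names(mirnas)
  stopifnot(!is.null(mnames))
  variants <- list()
  missing_ctx <- character(0)
  for (i in seq_along(mseq)) {
    s <- mseq[i]; L <- nchar(s)
    v <- c(s, substr(s, 1L, L - 1L), substr(s, 1L, L - 2L))
    ctx <- genome_3p_context[[mnames[i]]]
    if (!is.null(ctx) && nchar(ctx) >= 1L) {
      ctx <- rna_to_dna(ctx)
      v <- c(v, paste0(s, substr(ctx, 1L, 1L)))
      if (nchar(ctx) >= 2L) v <- c(v, paste0(s, substr(ctx, 1L, 2L)))
    } else {
      missing_ctx <- c(missing_ctx, mnames[i])
    }
    variants[[i]] <- data.frame(variant = unique(v), name = mnames[i],
                                stringsAsFactors = FALSE)
  }
  if (length(missing_ctx) && is.null(genome_3p_context))
    warning("no genomic 3' context supplied; +1/+2 templated extensions disallowed")
  else if (length(missing_ctx))
    warning("missing 3' context for ", length(missing_ctx),
            " miRNA(s); extensions disallowed for them")
  vmap <- do.call(rbind, variants)
  reads <- rna_to_dna(small_rna_reads)
  counts <- setNames(numeric(length(mnames)), mnames)
  by_variant <- split(vmap$name, vmap$variant)
  hits <- by_variant[reads]
  for (h in hits) {
    if (is.null(h)) next
    h <- unique(h)
    if (count_mode == "first") {
      first <- h[which.min(match(h, mnames))]
      counts[first] <- counts[first] + 1
    } else {
      counts[h] <- counts[h] + 1 / length(h)
    }
  }
  ord <- order(-counts, mnames)
  data.frame(name = mnames[ord], count = as.numeric(counts[ord]),
             rank = seq_along(mnames), stringsAsFactors = FALSE)
}

#' Extract strand-aware cluster sequences
#'
#' Returns the genomic sequence of each cluster span, extended by `flank`
#' bases on both sides, reading 5'->3' on the cluster strand. Clusters running
#' off the chromosome yield NA.
#'
#' @param clusters Cluster `GRanges`.
#' @param genome Named `DNAStringSet`.
#' @param flank Bases added on each side.
#' @return Named character vector (names = cluster IDs).
#' @export
cluster_sequences <- function(clusters, genome, flank = 30L) {
  ch <- as.character(seqnames(clusters))
  st <- as.character(strand(clusters))
  w <- width(clusters) + 2L * flank
  p0 <- ifelse(st == "-", end(clusters) + flank, start(clusters) - flank)
  seqs <- extract_strand_seq(genome, ch, st, p0, w)
  names(seqs) <- if (!is.null(clusters$cluster_id)) clusters$cluster_id
                 else paste0("cl", seq_along(clusters))
  seqs
}

#' Scan clusters for successive miRNA 7-mer complements
#'
#' For each miRNA and each 1-based start position s (1 .. length-6), the DNA
#' reverse complement of the miRNA 7-mer starting at s is searched in every
#' cluster sequence. The per-start percentage is the share of clusters with at
#' least one hit at that s from at least one of the supplied miRNAs.
#'
#' @param cluster_seqs Named character vector of strand-aware cluster
#'   sequences (see [cluster_sequences()]); NA entries are skipped.
#' @param mirnas Named `RNAStringSet`/character (RNA), typically the top-N by
#'   expression rank.
#' @return List with `hits` (data.frame: cluster, mirna, mirna_start,
#'   target_offset) and `per_start` (data.frame: mirna_start, n_clusters_hit,
#'   pct, n_mirnas_scanned).
#' @export
scan_seven_mers <- function(cluster_seqs, mirnas) {
  ok <- !is.na(cluster_seqs)
  seqs <- DNAStringSet(cluster_seqs[ok])
  n_clusters <- length(cluster_seqs)
  mseq <- rna_to_dna(as.character(mirnas))
  mnames <- names(mirnas)
  hits <- list()
  for (i in seq_along(mseq)) {
    L <- nchar(mseq[i])
    if (L < 7L) next
    for (s in seq_len(L - 6L)) {
      pat <- revcomp_dna(substr(mseq[i], s, s + 6L))
      m <- Biostrings::vmatchPattern(pat, seqs)
      cnt <- elementNROWS(m)
      if (!any(cnt > 0)) next
      which_cl <- rep(seq_along(seqs), cnt)
      hits[[length(hits) + 1L]] <- data.frame(
        cluster = names(seqs)[which_cl],
        mirna = mnames[i], mirna_start = s,
        target_offset = unlist(lapply(m, start)),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(cluster = character(), mirna = character(),
                          mirna_start = integer(), target_offset = integer())
  max_s <- max(c(0L, nchar(mseq) - 6L))
  per_start <- do.call(rbind, lapply(seq_len(max_s), function(s) {
    h <- hits[hits$mirna_start == s, ]
    data.frame(mirna_start = s,
               n_clusters_hit = length(unique(h$cluster)),
               pct = 100 * length(unique(h$cluster)) / n_clusters,
               n_mirnas_scanned = sum(nchar(mseq) - 6L >= s))
  }))
  list(hits = hits, per_start = per_start)
}

#' Seed-complement density around cluster summits
#'
#' For every position of a window centered on the cluster summit, counts the
#' starts of complements of the miRNA seed region (nucleotides 2-8) summed
#' over clusters and miRNAs, normalised per cluster.
#'
#' @param clusters Cluster `GRanges` with `summit`.
#' @param genome Named `DNAStringSet`.
#' @param mirnas Named `RNAStringSet`/character (RNA), typically the top-N.
#' @param window Window width in nt centered on the summit (default 20).
#' @return data.frame with `offset` (relative to summit, `-window/2` ..
#'   `window/2 - 1`) and `density` (seed-complement starts per cluster).
#' @export
seed_density <- function(clusters, genome, mirnas, window = 20L) {
  half <- window %/% 2L
  ch <- as.character(seqnames(clusters))
  st <- as.character(strand(clusters))
  p0 <- ifelse(st == "-", clusters$summit + half, clusters$summit - half)
  # extend by 6 so a 7-mer starting at the last window position fits
  seqs <- extract_strand_seq(genome, ch, st, p0, window + 6L)
  seqs <- seqs[!is.na(seqs)]
  n_cl <- length(seqs)
  if (n_cl == 0) stop("no clusters with in-bounds summit windows")
  dss <- DNAStringSet(seqs)
  counts <- numeric(window)
  for (m in as.character(mirnas)) {
    seed <- revcomp_dna(rna_to_dna(substr(m, 2L, 8L)))
    starts <- unlist(lapply(Biostrings::vmatchPattern(seed, dss), start))
    starts <- starts[starts <= window]
    if (length(starts))
      counts <- counts + tabulate(starts, nbins = window)
  }
  data.frame(offset = seq(-half, half - 1L), density = counts / n_cl)
}

#' HAR-enrichment calls on combined cluster loci
#'
#' Cluster loci from the untreated (WT) and harringtonine (HAR) conditions are
#' combined by single-linkage overlap union (same gap window as cluster
#' calling), per-condition abundance is recomputed on the combined loci from
#' the member clusters' read counts, and loci whose HAR abundance is at least
#' `fold` times the WT abundance are flagged HAR enriched. A locus absent from
#' one condition gets a pseudocount there.
#'
#' @param clusters_wt,clusters_har Cluster `GRanges` with `read_count` and
#'   `rpm` (totals read from [quantify_rpm()] metadata unless given).
#' @param fold Enrichment threshold (default 2).
#' @param window Gap (nt) merged when combining loci.
#' @param total_wt,total_har Library totals; default from metadata.
#' @param pseudocount_reads Reads assigned to a locus missing from a condition.
#' @return `GRanges` of combined loci with `rpm_wt`, `rpm_har`, `fold_change`
#'   and `har_enriched`.
#' @export
har_enrichment <- function(clusters_wt, clusters_har, fold = 2,
                           window = 3L, total_wt = NULL, total_har = NULL,
                           pseudocount_reads = 1) {
  if (is.null(total_wt)) total_wt <- S4Vectors::metadata(clusters_wt)$total_mapped
  if (is.null(total_har)) total_har <- S4Vectors::metadata(clusters_har)$total_mapped
  if (is.null(total_wt) || is.null(total_har))
    stop("library totals not found; run quantify_rpm() or pass totals")
  combined <- GenomicRanges::reduce(c(granges(clusters_wt), granges(clusters_har)),
                                    min.gapwidth = window + 1L,
                                    ignore.strand = FALSE)
  locus_rpm <- function(clusters, total) {
    hits <- findOverlaps(combined, clusters, ignore.strand = FALSE)
    cnt <- rep(0, length(combined))
    agg <- tapply(clusters$read_count[subjectHits(hits)], queryHits(hits), sum)
    cnt[as.integer(names(agg))] <- agg
    cnt[cnt == 0] <- pseudocount_reads
    cnt * 1e6 / total
  }
  combined$rpm_wt <- locus_rpm(clusters_wt, total_wt)
  combined$rpm_har <- locus_rpm(clusters_har, total_har)
  combined$fold_change <- combined$rpm_har / combined$rpm_wt
  combined$har_enriched <- combined$fold_change >= fold
  combined
}

#' Hook for external hybridization-energy computation
#'
#' Emits (miRNA, target) pairs in the convention expected by an external
#' duplex minimum-free-energy program (two FASTA files plus a pair table), and
#' parses the external output back into a table. No energy model is
#' implemented internally; when the external program is absent the run step is
#' skipped with a warning.
#'
#' @param pairs data.frame with `mirna`, `mirna_seq` (RNA), `target_id`,
#'   `target_seq` (DNA or RNA).
#' @param dir Directory for the pair files.
#' @return Paths of the written files (`mirnas.fa`, `targets.fa`,
#'   `pairs.tsv`), invisibly for `mfe_write_pairs`.
#' @export
mfe_write_pairs <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mirnas = file.path(dir, "mfe_mirnas.fa"),
             targets = file.path(dir, "mfe_targets.fa"),
             pairs = file.path(dir, "mfe_pairs.tsv"))
  um <- !duplicated(pairs$mirna)
  writeLines(as.vector(rbind(paste0(">", pairs$mirna[um]),
                             dna_to_rna(pairs$mirna_seq[um]))), paths["mirnas"])
  ut <- !duplicated(pairs$target_id)
  writeLines(as.vector(rbind(paste0(">", pairs$target_id[ut]),
                             rna_to_dna(pairs$target_seq[ut]))), paths["targets"])
  write.table(pairs, paths["pairs"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname mfe_write_pairs
#' @export
mfe_read_pairs <- function(dir) {
  read.table(file.path(dir, "mfe_pairs.tsv"), sep = "\t", header = TRUE,
             colClasses = "character")
}

#' @rdname mfe_write_pairs
#' @param program Name of the external hybridization program.
#' @export
mfe_hook <- function(pairs, dir, program = "RNAhybrid") {
  paths <- mfe_write_pairs(pairs, dir)
  if (Sys.which(program) == "") {
    warning("external program '", program, "' not found; hook skipped")
    return(invisible(NULL))
  }
  out <- system2(program, c("-t", paths["targets"], "-q", paths["mirnas"], "-c"),
                 stdout = TRUE)
  writeLines(out, file.path(dir, "mfe_output.txt"))
  invisible(out)
}
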