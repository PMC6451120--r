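#' Pentamer z-score enrichment around cluster summits
#'
#' Counts occurrences of all 1024 pentamers in strand-aware windows
#' (default [-10,+10]) around the summit of each specific cluster, and
#' compares each count to its distribution over random draws in which every
#' cluster window is replaced by an equally sized window sampled uniformly
#' from regions of the same annotation class. The z-score is
#' (observed - background mean) / background sd; pentamers at or above the
#' threshold (200 by default) are called binding motifs.
#'
#' @param clusters Cluster `GRanges` with a `summit` column.
#' @param genome Named `DNAStringSet`.
#' @param annotation An `annotation_model`.
#' @param categories Optional annotation class per cluster; computed with
#'   [assign_category()] (splicing order) when omitted. Intergenic clusters
#'   are dropped with a warning since they have no matched background space.
#' @param window Integer pair: offsets around the summit (default c(-10, 10)).
#' @param n_random_draws Background draws (default 100).
#' @param z_threshold Motif-call threshold on the z-score.
#' @param seed Optional RNG seed for the background sampling.
#' @return data.frame with pentamer, observed, bg_mean, bg_sd, z, is_motif,
#'   sorted by decreasing z.
#' @export
pentamer_zscores <- function(clusters, genome, annotation, categories = NULL,
                             window = c(-10L, 10L), n_random_draws = 100L,
                             z_threshold = 200, seed = NULL) {
  if (is.null(categories))
    categories <- assign_category(clusters, annotation, category_order_splicing)
  keep <- categories != "intergenic"
  if (!all(keep)) {
    warning(sum(!keep), " intergenic clusters dropped (no matched background)")
    clusters <- clusters[keep]; categories <- categories[keep]
  }
  if (length(clusters) == 0) stop("no clusters with an annotation class")
  for (cl in unique(categories)) {
    if (!any(annotation$regions$label == cl))
      stop("no background space available for annotation class '", cl, "'")
  }
  wlen <- window[2] - window[1] + 1L
  if (!is.null(seed)) set.seed(seed)

  chrom <- as.character(seqnames(clusters))
  str <- as.character(strand(clusters))
  # 5'-most base of the strand-aware window
  p0 <- ifelse(str == "-", clusters$summit - window[1],
               clusters$summit + window[1])
  obs_seq <- extract_strand_seq(genome, chrom, str, p0, wlen)
  obs_seq <- obs_seq[!is.na(obs_seq)]
  observed <- colSums(oligonucleotideFrequency(DNAStringSet(obs_seq), 5L))

  # background: per draw, one same-width window per cluster from the
  # cluster's own annotation class
  n <- length(clusters)
  total <- n * n_random_draws
  bg_chrom <- character(total); bg_str <- character(total)
  bg_pos <- integer(total)
  idx0 <- 0L
  for (cl in unique(categories)) {
    members <- which(categories == cl)
    m <- length(members) * n_random_draws
    pool <- annotation$regions[annotation$regions$label == cl]
    i <- sample.int(length(pool), m, replace = TRUE, prob = width(pool))
    center <- start(pool)[i] +
      vapply(width(pool)[i], function(w) sample.int(w, 1L) - 1L, integer(1))
    st <- as.character(strand(pool))[i]
    sel <- idx0 + seq_len(m)
    bg_chrom[sel] <- as.character(seqnames(pool))[i]
    bg_str[sel] <- st
    bg_pos[sel] <- ifelse(st == "-", center - window[1], center + window[1])
    idx0 <- idx0 + m
  }
  draw_id <- rep(seq_len(n_random_draws), times = total / n_random_draws)
  bg_seq <- extract_strand_seq(genome, bg_chrom, bg_str, bg_pos, wlen)
  ok <- !is.na(bg_seq)
  counts <- oligonucleotideFrequency(DNAStringSet(bg_seq[ok]), 5L)
  per_draw <- rowsum(counts, group = draw_id[ok])
  bg_mean <- colMeans(per_draw)
  bg_sd <- apply(per_draw, 2L, stats::sd)
  z <- (observed - bg_mean) / bg_sd
  z[bg_sd == 0] <- NA_real_
  out <- data.frame(pentamer = names(observed), observed = as.numeric(observed),
                    bg_mean = as.numeric(bg_mean), bg_sd = as.numeric(bg_sd),
                    z = as.numeric(z),
                    is_motif = !is.na(z) & z >= z_threshold,
                    stringsAsFactors = FALSE)
  out[order(-out$z), ]
}

#' Positional motif coverage across clusters
#'
#' Binary per-base coverage by any motif occurrence over each cluster span
#' plus flanks, on the cluster strand, with clusters ranked by span length
#' (shortest first) for length-sorted summaries. Positions outside the
#' chromosome are NA.
#'
#' @param clusters Cluster `GRanges`.
#' @param motif_set Character vector of motifs (DNA alphabet).
#' @param genome Named `DNAStringSet`.
#' @param flank Bases added on each side of the cluster span.
#' @return data.frame with cluster_id, length_rank, rel_pos (1-based within
#'   the extracted window), region (flank5/cluster/flank3) and covered.
#' @export
motif_coverage <- function(clusters, motif_set, genome, flank = 20L) {
  stopifnot(length(motif_set) > 0)
  motif_set <- rna_to_dna(motif_set)
  len_rank <- rank(width(clusters), ties.method = "first")
  rows <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    ch <- as.character(seqnames(clusters))[i]
    st <- as.character(strand(clusters))[i]
    w <- width(clusters)[i] + 2L * flank
    p0 <- if (st == "-") end(clusters)[i] + flank else start(clusters)[i] - flank
    seqi <- extract_strand_seq(genome, ch, st, p0, w)
    covered <- rep(NA, w)
    if (!is.na(seqi)) {
      covered <- rep(FALSE, w)
      for (m in motif_set) {
        hits <- gregexpr(m, seqi, fixed = TRUE)[[1]]
        if (hits[1] != -1L)
          for (h in hits) covered[h:(h + nchar(m) - 1L)] <- TRUE
      }
    }
    region <- rep("cluster", w)
    region[seq_len(flank)] <- "flank5"
    region[(w - flank + 1L):w] <- "flank3"
    rows[[i]] <- data.frame(
      cluster_id = if (!is.null(clusters$cluster_id)) clusters$cluster_id[i] else i,
      length_rank = len_rank[i], rel_pos = seq_len(w),
      region = region, covered = covered, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Expand the crosslink-motif tetramer set
#'
#' `"all_pyrimidine"` means the 16 tetramers over {C, T}; a custom character
#' vector of tetramers may be supplied instead.
#'
#' @param cl_set `"all_pyrimidine"` or a character vector of tetramers.
#' @return Character vector of DNA tetramers.
#' @export
expand_cl_set <- function(cl_set) {
  if (identical(cl_set, "all_pyrimidine"))
    return(all_kmers(4L, c("C", "T")))
  cl_set <- rna_to_dna(cl_set)
  stopifnot(all(nchar(cl_set) == 4L))
  cl_set
}

#' Crosslink-motif positional profile
#'
#' For each offset relative to the crosslink site (the read's strand-aware 5'
#' start; positive offsets run 3'-ward into the insert), the fraction of reads
#' whose genomic tetramer starting at that offset belongs to the
#' crosslink-motif set. Reads whose tetramer would fall outside the
#' chromosome are skipped at that offset and tallied.
#'
#' @param usable Deduplicated `GRanges` of mapped reads.
#' @param genome Named `DNAStringSet`.
#' @param cl_set See [expand_cl_set()].
#' @param range Integer pair of offsets (default c(-30, 30)).
#' @return data.frame with offset, fraction_with_cl, n_used, n_skipped.
#' @export
cl_profile <- function(usable, genome, cl_set = "all_pyrimidine",
                       range = c(-30L, 30L)) {
  tets <- expand_cl_set(cl_set)
  p5 <- five_prime_start(usable)
  chrom <- as.character(seqnames(usable))
  str <- as.character(strand(usable))
  offsets <- range[1]:range[2]
  res <- lapply(offsets, function(o) {
    pos <- ifelse(str == "-", p5 - o, p5 + o)
    tet <- extract_strand_seq(genome, chrom, str, pos, 4L)
    used <- !is.na(tet)
    data.frame(offset = o,
               fraction_with_cl = if (any(used)) mean(tet[used] %in% tets) else NA_real_,
               n_used = sum(used), n_skipped = sum(!used))
  })
  do.call(rbind, res)
}
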