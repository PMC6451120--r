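#' Call crosslink sites from usable reads
#'
#' In a truncation-based library the 3' end of the insert cDNA is the
#' protein-RNA crosslink position, so each distinct strand-aware read 5' start
#' is one candidate crosslink site; its read count is the number of usable
#' reads sharing that start.
#'
#' @param usable Deduplicated `GRanges` of mapped reads.
#' @return Width-1 `GRanges` of sites with a `read_count` column, sorted.
#' @export
call_crosslink_sites <- function(usable) {
  if (length(usable) == 0) {
    out <- GRanges()
    out$read_count <- integer(0)
    return(out)
  }
  p5 <- five_prime_start(usable)
  key <- paste(as.character(seqnames(usable)), as.character(strand(usable)),
               p5, sep = "|")
  tab <- table(key)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  strand <- vapply(parts, `[`, character(1), 2L)
  pos <- as.integer(vapply(parts, `[`, character(1), 3L))
  gr <- GRanges(chrom, IRanges(pos, pos), strand = strand,
                read_count = as.integer(tab))
  sort(gr, ignore.strand = TRUE)
}

#' Cluster crosslink sites by single-linkage chaining
#'
#' Consecutive sites on the same chromosome and strand whose positions differ
#' by at most `window` nt join one cluster (3 nt by default). The cluster span
#' covers its member sites; the summit is the member with the maximal read
#' count (leftmost on ties).
#'
#' @param sites Width-1 `GRanges` from [call_crosslink_sites()].
#' @param window Maximum gap (nt) chaining two sites into one cluster.
#' @return `GRanges` of clusters with `cluster_id`, `summit`, `read_count`
#'   and `n_sites` columns.
#' @export
cluster_sites <- function(sites, window = 3L) {
  if (length(sites) == 0) {
    out <- GRanges()
    out$cluster_id <- character(0); out$summit <- integer(0)
    out$read_count <- integer(0); out$n_sites <- integer(0)
    return(out)
  }
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   strand = as.character(strand(sites)),
                   pos = start(sites), count = sites$read_count,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$strand, df$pos), ]
  new_grp <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                     df$strand[-1] != df$strand[-nrow(df)] |
                     (df$pos[-1] - df$pos[-nrow(df)]) > window)
  grp <- cumsum(new_grp)
  agg <- lapply(split(seq_len(nrow(df)), grp), function(i) {
    counts <- df$count[i]
    best <- i[which.max(counts)]  # which.max takes the leftmost tie
    list(chrom = df$chrom[i[1]], strand = df$strand[i[1]],
         start = min(df$pos[i]), end = max(df$pos[i]),
         summit = df$pos[best], read_count = sum(counts),
         n_sites = length(i))
  })
  gr <- GRanges(vapply(agg, `[[`, character(1), "chrom"),
                IRanges(vapply(agg, `[[`, numeric(1), "start"),
                        vapply(agg, `[[`, numeric(1), "end")),
                strand = vapply(agg, `[[`, character(1), "strand"))
  gr$summit <- as.integer(vapply(agg, `[[`, numeric(1), "summit"))
  gr$read_count <- as.integer(vapply(agg, `[[`, numeric(1), "read_count"))
  gr$n_sites <- as.integer(vapply(agg, `[[`, numeric(1), "n_sites"))
  gr <- sort(gr, ignore.strand = TRUE)
  gr$cluster_id <- sprintf("cl%05d", seq_along(gr))
  gr
}

#' Normalise cluster read counts to RPM
#'
#' RPM = reads per million genome-mapped usable reads of the cluster's own
#' library; the library total is stored as metadata for downstream use.
#'
#' @param clusters Cluster `GRanges` with `read_count`.
#' @param total_mapped Total genome-mapped usable reads in the library.
#' @return Clusters with an `rpm` column.
#' @export
quantify_rpm <- function(clusters, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be positive")
  clusters$rpm <- clusters$read_count * 1e6 / total_mapped
  S4Vectors::metadata(clusters)$total_mapped <- total_mapped
  clusters
}

#' Call RBP-specific clusters by input deduction
#'
#' For each CLIP cluster, the input abundance is the RPM of input-library read
#' 5' starts falling inside the cluster span on the same strand (each library
#' normalised by its own total). Clusters with a fold enrichment of at least
#' `threshold` (15 by default) over the input are RBP-specific. Clusters with
#' no input reads receive `pseudocount_reads` input reads so the fold stays
#' finite.
#'
#' @param clip_clusters Cluster `GRanges` with `rpm` (see [quantify_rpm()]).
#' @param input_reads Deduplicated input `GRanges`.
#' @param input_total Total usable input reads; defaults to
#'   `length(input_reads)`.
#' @param threshold Minimum fold enrichment for a specific call.
#' @param pseudocount_reads Input reads substituted when a cluster has none.
#' @return Clusters with `input_rpm`, `fold_enrichment` and `specific` columns.
#' @export
deduct_input <- function(clip_clusters, input_reads, input_total = NULL,
                         threshold = 15, pseudocount_reads = 1) {
  if (is.null(clip_clusters$rpm))
    stop("clip_clusters must carry rpm; run quantify_rpm() first")
  if (is.null(input_total)) input_total <- length(input_reads)
  p5 <- five_prime_start(input_reads)
  starts <- GRanges(seqnames(input_reads), IRanges(p5, p5),
                    strand = strand(input_reads))
  n_in <- countOverlaps(clip_clusters, starts, ignore.strand = FALSE)
  n_eff <- ifelse(n_in == 0, pseudocount_reads, n_in)
  clip_clusters$input_rpm <- n_eff * 1e6 / input_total
  clip_clusters$fold_enrichment <- clip_clusters$rpm / clip_clusters$input_rpm
  clip_clusters$specific <- clip_clusters$fold_enrichment >= threshold
  clip_clusters
}

#' Replicate reproducibility of cluster abundances
#'
#' Cluster loci of two replicate samples are matched by any-overlap on the
#' same strand (union loci); loci absent from one sample get a pseudocount
#' abundance. Returns the Pearson correlation of log10 RPM over the union.
#'
#' @param clusters_a,clusters_b Cluster `GRanges` with `rpm` from
#'   [quantify_rpm()] (library totals read from metadata unless given).
#' @param total_a,total_b Library totals; default from cluster metadata.
#' @param pseudocount_reads Reads assigned to a locus missing from a sample.
#' @return Pearson correlation coefficient.
#' @export
replicate_reproducibility <- function(clusters_a, clusters_b,
                                      total_a = NULL, total_b = NULL,
                                      pseudocount_reads = 1) {
  if (is.null(total_a)) total_a <- S4Vectors::metadata(clusters_a)$total_mapped
  if (is.null(total_b)) total_b <- S4Vectors::metadata(clusters_b)$total_mapped
  if (is.null(total_a) || is.null(total_b))
    stop("library totals not found; run quantify_rpm() or pass totals")
  loci <- GenomicRanges::reduce(c(granges(clusters_a), granges(clusters_b)),
                                ignore.strand = FALSE)
  if (length(loci) < 3) stop("fewer than 3 union loci")
  locus_rpm <- function(clusters, total) {
    hits <- findOverlaps(loci, clusters, ignore.strand = FALSE)
    cnt <- rep(0, length(loci))
    agg <- tapply(clusters$read_count[subjectHits(hits)], queryHits(hits), sum)
    cnt[as.integer(names(agg))] <- agg
    cnt[cnt == 0] <- pseudocount_reads
    cnt * 1e6 / total
  }
  a <- locus_rpm(clusters_a, total_a)
  b <- locus_rpm(clusters_b, total_b)
  stats::cor(log10(a), log10(b), method = "pearson")
}
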