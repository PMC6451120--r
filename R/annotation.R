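#' Category precedence orders
#'
#' Cluster classification uses an RBP-appropriate precedence: splicing
#' regulators (PTBP1/RBFOX2-style) are classified intron first, while
#' AGO2-style clusters are classified CDS first.
#'
#' @format Character vectors of the four region labels.
#' @export
category_order_splicing <- c("intron", "three_prime_utr", "cds", "five_prime_utr")

#' @rdname category_order_splicing
#' @export
category_order_ago2 <- c("cds", "three_prime_utr", "five_prime_utr", "intron")

region_labels <- c("five_prime_utr", "cds", "intron", "three_prime_utr")

#' Construct an annotation model
#'
#' The container used by every downstream stage: gene spans with
#' `gene_id`/`gene_type`, region intervals labelled with one of the four
#' element classes, and per-transcript exon chains.
#'
#' @param genes `GRanges` with `gene_id` and `gene_type`
#'   (`protein_coding`, `histone_like`, `lncRNA`).
#' @param regions `GRanges` with a `label` column over
#'   five_prime_utr/cds/intron/three_prime_utr and a `gene_id`.
#' @param exons `GRanges` with `gene_id` and `transcript_id`.
#' @param chrom_lengths Named integer vector of chromosome lengths; inferred
#'   from the furthest annotated base when omitted.
#' @return An object of class `annotation_model`.
#' @export
new_annotation_model <- function(genes, regions, exons, chrom_lengths = NULL) {
  stopifnot(all(regions$label %in% region_labels))
  if (is.null(chrom_lengths)) {
    ends <- tapply(end(regions), as.character(seqnames(regions)), max)
    chrom_lengths <- setNames(as.integer(ends), names(ends))
  }
  lens <- vapply(region_labels, function(lab) {
    sum(width(GenomicRanges::reduce(regions[regions$label == lab])))
  }, numeric(1))
  structure(list(genes = genes, regions = regions, exons = exons,
                 region_total_lengths = lens,
                 chrom_lengths = chrom_lengths,
                 contaminant_loci = GRanges()),
            class = "annotation_model")
}

#' @export
print.annotation_model <- function(x, ...) {
  cat("annotation_model:", length(x$genes), "genes,",
      length(x$regions), "region intervals,",
      length(unique(x$exons$transcript_id)), "transcripts\n")
  invisible(x)
}

#' Write an annotation model as GTF
#'
#' Emits gene/transcript/exon/CDS/five_prime_utr/three_prime_utr features with
#' `gene_id`, `transcript_id` and `gene_type` attributes (GENCODE dialect).
#' Introns are implied by the exon chain, not written.
#'
#' @param annotation An `annotation_model`.
#' @param path Output GTF path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  genes <- annotation$genes
  exons <- annotation$exons
  gene_type <- setNames(genes$gene_type, genes$gene_id)
  tx_of_gene <- setNames(exons$transcript_id, exons$gene_id)

  grs <- list()
  g <- genes
  g$type <- "gene"; g$transcript_id <- NA_character_
  grs$gene <- g

  tx_split <- split(exons, exons$transcript_id)
  tx <- unlist(range(tx_split))
  tx_meta <- exons[!duplicated(exons$transcript_id)]
  tx_meta <- tx_meta[match(names(tx), tx_meta$transcript_id)]
  mcols(tx) <- DataFrame(gene_id = tx_meta$gene_id,
                         gene_type = gene_type[tx_meta$gene_id],
                         type = "transcript",
                         transcript_id = names(tx))
  names(tx) <- NULL
  grs$tx <- tx

  e <- exons
  mcols(e) <- DataFrame(gene_id = exons$gene_id,
                        gene_type = gene_type[exons$gene_id],
                        type = "exon", transcript_id = exons$transcript_id)
  grs$exon <- e

  for (lab in c("cds", "five_prime_utr", "three_prime_utr")) {
    r <- annotation$regions[annotation$regions$label == lab]
    if (!length(r)) next
    feat <- if (lab == "cds") "CDS" else lab
    mcols(r) <- DataFrame(gene_id = r$gene_id,
                          gene_type = gene_type[r$gene_id],
                          type = feat,
                          transcript_id = unname(tx_of_gene[r$gene_id]))
    if (lab == "cds") {
      # GTF frame: bases to skip to reach the first complete codon
      phase <- rep(NA_integer_, length(r))
      for (gid in unique(r$gene_id)) {
        idx <- which(r$gene_id == gid)
        idx <- idx[order(start(r)[idx])]
        if (as.character(strand(r))[idx[1]] == "-") idx <- rev(idx)
        before <- cumsum(c(0L, width(r)[idx][-length(idx)]))
        phase[idx] <- (3L - before %% 3L) %% 3L
      }
      r$phase <- phase
    }
    grs[[lab]] <- r
  }
  out <- suppressWarnings(do.call(c, unname(grs)))
  out <- sort(out, ignore.strand = TRUE)
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read a GENCODE-dialect GTF into an annotation model
#'
#' Uses gene/exon/CDS/five_prime_utr/three_prime_utr features and the
#' `gene_id`, `transcript_id`, `gene_type` attributes. Introns are derived per
#' transcript as the gaps between its exons.
#'
#' @param path GTF file.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return An `annotation_model`.
#' @export
read_annotation <- function(path, chrom_lengths = NULL) {
  gtf <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gtf$type)
  genes <- gtf[type == "gene"]
  mcols(genes) <- DataFrame(gene_id = genes$gene_id, gene_type = genes$gene_type)
  exons <- gtf[type == "exon"]
  mcols(exons) <- DataFrame(gene_id = exons$gene_id,
                            transcript_id = exons$transcript_id)

  rl <- list()
  for (feat in c("CDS", "five_prime_utr", "three_prime_utr")) {
    r <- gtf[type == feat]
    if (!length(r)) next
    lab <- if (feat == "CDS") "cds" else feat
    mcols(r) <- DataFrame(label = lab, gene_id = r$gene_id)
    rl[[feat]] <- r
  }
  # introns: per-transcript gaps between exons
  ex_by_tx <- split(exons, exons$transcript_id)
  introns <- psetdiff(unlist(range(ex_by_tx)), ex_by_tx)
  introns <- unlist(introns)
  if (length(introns)) {
    gid <- exons$gene_id[match(names(introns), exons$transcript_id)]
    mcols(introns) <- DataFrame(label = "intron", gene_id = gid)
    names(introns) <- NULL
    rl$intron <- introns
  }
  regions <- suppressWarnings(do.call(c, unname(rl)))
  new_annotation_model(genes = genes, regions = regions, exons = exons,
                       chrom_lengths = chrom_lengths)
}

#' Assign clusters to genomic element categories
#'
#' The first label in `order` whose region intervals overlap the cluster span
#' (>= 1 shared base, same strand) wins; clusters overlapping nothing are
#' "intergenic". Multi-label bases are resolved by the same precedence.
#'
#' @param clusters `GRanges` of clusters.
#' @param annotation An `annotation_model`.
#' @param order Character permutation of the four labels, e.g.
#'   [category_order_splicing] or [category_order_ago2].
#' @return Character vector of categories, one per cluster.
#' @export
assign_category <- function(clusters, annotation, order = category_order_splicing) {
  stopifnot(setequal(order, region_labels))
  out <- rep("intergenic", length(clusters))
  unassigned <- rep(TRUE, length(clusters))
  for (lab in order) {
    r <- annotation$regions[annotation$regions$label == lab]
    hit <- overlapsAny(clusters, r, ignore.strand = FALSE)
    take <- unassigned & hit
    out[take] <- lab
    unassigned <- unassigned & !take
  }
  out
}

#' Distribution of clusters over element categories
#'
#' @inheritParams assign_category
#' @param size_corrected When `TRUE`, each label's count is divided by the
#'   label's total annotated length before renormalising to sum 1 (a density,
#'   as in region-size-corrected distributions); intergenic clusters are
#'   excluded from the corrected mode since intergenic space has no defined
#'   length here.
#' @return Named numeric vector of fractions.
#' @export
category_distribution <- function(clusters, annotation,
                                  order = category_order_splicing,
                                  size_corrected = FALSE) {
  if (length(clusters) == 0) stop("empty cluster set")
  cat <- assign_category(clusters, annotation, order)
  if (!size_corrected) {
    tab <- table(factor(cat, levels = c(order, "intergenic")))
    return(setNames(as.numeric(tab) / length(clusters), names(tab)))
  }
  counts <- table(factor(cat[cat != "intergenic"], levels = order))
  dens <- as.numeric(counts) / annotation$region_total_lengths[order]
  dens[!is.finite(dens)] <- 0
  setNames(dens / sum(dens), order)
}

#' Histone-gene overlap among top clusters
#'
#' Clusters are ranked by read count (descending; coordinate order breaks
#' ties) and flagged for any-overlap with a histone-like gene on the same
#' strand. Used for SLBP-style analyses where essentially all true signal is
#' expected inside replication-dependent histone mRNAs.
#'
#' @param clusters `GRanges` with a `read_count` column.
#' @param annotation An `annotation_model` containing `histone_like` genes.
#' @param top_n Number of top clusters to summarise.
#' @return List with `n_overlapping_histone` (count among the top `top_n`) and
#'   `flags` (data.frame of rank, cluster locus, histone flag).
#' @export
histone_overlap <- function(clusters, annotation, top_n = 200L) {
  if (length(clusters) == 0 || top_n == 0)
    return(list(n_overlapping_histone = 0L,
                flags = data.frame(rank = integer(), histone = logical())))
  ord <- order(-clusters$read_count, as.character(seqnames(clusters)),
               start(clusters))
  cl <- clusters[ord]
  histones <- annotation$genes[annotation$genes$gene_type == "histone_like"]
  flag <- if (length(histones)) overlapsAny(cl, histones, ignore.strand = FALSE)
          else rep(FALSE, length(cl))
  if (top_n > length(cl)) {
    warning("top_n exceeds cluster count; using all ", length(cl), " clusters")
    top_n <- length(cl)
  }
  list(n_overlapping_histone = sum(flag[seq_len(top_n)]),
       flags = data.frame(rank = seq_along(cl),
                          chrom = as.character(seqnames(cl)),
                          start = start(cl), end = end(cl),
                          strand = as.character(strand(cl)),
                          read_count = cl$read_count,
                          histone = flag))
}
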