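#' Write mapped reads or clusters as BED6
#'
#' BED output is 0-based half-open; the name field carries
#' `"<readID>:<UMI>"` for reads (or the cluster ID for clusters) and the score
#' column the read count (0 for raw reads).
#'
#' @param gr `GRanges` with `name` and `score` metadata columns.
#' @param path Output path.
#' @export
write_bed6 <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   name = if (!is.null(gr$name)) gr$name else ".",
                   score = if (!is.null(gr$score)) gr$score else 0L,
                   strand = as.character(strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned reads from BED6
#'
#' The name field is parsed as `"<readID>:<UMI>"`; the UMI is everything after
#' the last colon.
#'
#' @param path BED6 file of uniquely aligned reads.
#' @param library_id Label attached to every read.
#' @return `GRanges` with `name`, `umi` and `library_id` columns.
#' @export
read_mapped_bed <- function(path, library_id = basename(path)) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand)
  gr$name <- df$name
  gr$score <- df$score
  gr$umi <- sub("^.*:", "", df$name)
  gr$library_id <- library_id
  gr
}

#' Read FASTQ into a named DNAStringSet
#'
#' @param path FASTQ file.
#' @return `DNAStringSet` named by read ID.
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write clusters as a TSV (and optionally a BED6+ twin)
#'
#' @param clusters Cluster `GRanges` (1-based internally; the TSV keeps
#'   1-based inclusive coordinates, the BED twin is 0-based half-open).
#' @param path Output TSV path.
#' @param bed_path Optional BED path.
#' @export
write_clusters <- function(clusters, path, bed_path = NULL) {
  df <- data.frame(chrom = as.character(seqnames(clusters)),
                   start = start(clusters), end = end(clusters),
                   strand = as.character(strand(clusters)),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(mcols(clusters)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    gr <- clusters
    gr$name <- if (!is.null(clusters$cluster_id)) clusters$cluster_id
               else paste0("cl", seq_along(clusters))
    gr$score <- clusters$read_count
    write_bed6(gr, bed_path)
  }
  invisible(path)
}
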