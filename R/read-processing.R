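#' Extract the 5' UMI from raw reads
#'
#' The first `umi_length` bases of each read are the unique molecular
#' identifier added during library construction; they are removed and recorded
#' as the read identity.
#'
#' @param sequence Character vector of read sequences.
#' @param umi_length UMI length in nt (default 10).
#' @return data.frame with `umi`, `remainder`, `rejected`, `reason`
#'   (`"too_short_for_umi"` for reads shorter than the UMI).
#' @export
extract_umi <- function(sequence, umi_length = 10L) {
  n <- nchar(sequence)
  rejected <- n < umi_length
  data.frame(umi = ifelse(rejected, NA_character_,
                          substr(sequence, 1L, umi_length)),
             remainder = ifelse(rejected, NA_character_,
                                substr(sequence, umi_length + 1L, n)),
             rejected = rejected,
             reason = ifelse(rejected, "too_short_for_umi", ""),
             stringsAsFactors = FALSE)
}

# mismatches between two equal-length strings
n_mismatch <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Trim the 3' adapter from reads
#'
#' Finds the leftmost occurrence of the adapter: either the full adapter
#' anywhere in the read or a prefix of it anchored at the read's 3' end, with
#' length >= `min_overlap` and a mismatch rate <= `max_mismatch_rate`.
#' Everything from that position on is removed. Reads with no qualifying
#' occurrence are returned unchanged and flagged untrimmed.
#'
#' @param sequence Character vector of reads (UMI already removed).
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum matched adapter prefix length.
#' @param max_mismatch_rate Maximum fraction of mismatched bases in the match.
#' @return data.frame with `trimmed` and `untrimmed` (logical flag).
#' @export
trim_adapter <- function(sequence, adapter, min_overlap = 3L,
                         max_mismatch_rate = 0.1) {
  stopifnot(nchar(adapter) > 0)
  A <- nchar(adapter)
  a_raw <- charToRaw(adapter)
  trim_one <- function(s) {
    L <- nchar(s)
    if (L == 0L) return(0L)
    s_raw <- charToRaw(s)
    for (i in seq_len(L)) {
      k <- min(A, L - i + 1L)
      if (k < min_overlap) break
      mism <- sum(s_raw[i:(i + k - 1L)] != a_raw[1:k])
      if (mism <= floor(max_mismatch_rate * k)) return(i - 1L)
    }
    -1L
  }
  cut <- vapply(sequence, trim_one, integer(1), USE.NAMES = FALSE)
  data.frame(trimmed = ifelse(cut >= 0L, substr(sequence, 1L, cut), sequence),
             untrimmed = cut < 0L,
             stringsAsFactors = FALSE)
}

#' Insert-length filter
#'
#' Inserts shorter than 30 nt or longer than 65 nt are discarded; both bounds
#' are inclusive keeps.
#'
#' @param insert Character vector of trimmed inserts.
#' @param min_len,max_len Inclusive usable length bounds.
#' @return Logical keep vector.
#' @export
filter_by_length <- function(insert, min_len = 30L, max_len = 65L) {
  n <- nchar(insert)
  n >= min_len & n <= max_len
}

#' Process raw reads to usable inserts
#'
#' UMI extraction, 3' adapter trimming and insert-length filtering in one
#' pass, with per-read bookkeeping for the composition report.
#'
#' @param fastq Named `DNAStringSet` or named character vector of raw reads.
#' @param adapter 3' adapter sequence.
#' @param umi_length UMI length.
#' @param min_len,max_len Usable insert-length bounds.
#' @param min_overlap,max_mismatch_rate Adapter-trimming policy.
#' @return List with `processed` (data.frame: read_id, umi, insert, untrimmed)
#'   and `counts` (total, too_short_for_umi, length_filtered, kept).
#' @export
process_reads <- function(fastq, adapter, umi_length = 10L,
                          min_len = 30L, max_len = 65L,
                          min_overlap = 3L, max_mismatch_rate = 0.1) {
  seqs <- as.character(fastq)
  ids <- names(fastq)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  u <- extract_umi(seqs, umi_length)
  keep1 <- !u$rejected
  tr <- trim_adapter(u$remainder[keep1], adapter, min_overlap, max_mismatch_rate)
  keep2 <- filter_by_length(tr$trimmed, min_len, max_len)
  processed <- data.frame(read_id = ids[keep1][keep2],
                          umi = u$umi[keep1][keep2],
                          insert = tr$trimmed[keep2],
                          untrimmed = tr$untrimmed[keep2],
                          stringsAsFactors = FALSE)
  list(processed = processed,
       counts = c(total = length(seqs),
                  too_short_for_umi = sum(u$rejected),
                  length_filtered = sum(!keep2),
                  kept = nrow(processed)))
}

dedup_key <- function(reads, key = c("five_prime", "span")) {
  key <- match.arg(key)
  p5 <- five_prime_start(reads)
  base <- paste(as.character(seqnames(reads)), as.character(strand(reads)),
                p5, reads$umi, sep = "|")
  if (key == "span")
    base <- paste(base, start(reads), end(reads), sep = "|")
  base
}

#' Collapse PCR duplicates
#'
#' Reads mapped to the same genomic position with identical UMIs are PCR
#' duplicates and are collapsed to a single representative (the first in
#' coordinate-sorted order). "Same genomic position" defaults to the
#' strand-aware 5' start -- the position that defines the crosslink site --
#' with a full-span alternative available.
#'
#' @param reads `GRanges` of uniquely mapped reads with a `umi` column.
#' @param key `"five_prime"` (chrom, strand, 5' start, UMI) or `"span"`
#'   (additionally the full span).
#' @return List with `usable` (`GRanges`) and `n_duplicates`.
#' @export
collapse_duplicates <- function(reads, key = c("five_prime", "span")) {
  if (length(reads) == 0)
    return(list(usable = reads, n_duplicates = 0L))
  sorted <- sort(reads, ignore.strand = TRUE)
  k <- dedup_key(sorted, key)
  usable <- sorted[!duplicated(k)]
  list(usable = usable, n_duplicates = length(reads) - length(usable))
}

#' Read composition report
#'
#' Tabulates the fate of sequenced reads the way CLIP library QC is usually
#' reported: total, uniquely mapped, PCR duplicates, and usable reads
#' (usable = uniquely mapped - duplicates), with fractions of the total.
#'
#' @param total Total sequenced reads.
#' @param uniquely_mapped Uniquely mapped reads.
#' @param pcr_duplicates Reads collapsed as PCR duplicates.
#' @return data.frame of category, count, fraction.
#' @export
read_composition <- function(total, uniquely_mapped, pcr_duplicates) {
  stopifnot(uniquely_mapped <= total, pcr_duplicates <= uniquely_mapped)
  usable <- uniquely_mapped - pcr_duplicates
  counts <- c(total = total, uniquely_mapped = uniquely_mapped,
              pcr_duplicates = pcr_duplicates, usable = usable)
  data.frame(category = names(counts), count = as.numeric(counts),
             fraction = as.numeric(counts) / total,
             stringsAsFactors = FALSE)
}

#' Library saturation curve
#'
#' Random subsamples of the mapped reads (without replacement) are
#' deduplicated to estimate the usable-read ratio at increasing analogic
#' sequencing depths.
#'
#' @param reads `GRanges` of uniquely mapped reads with a `umi` column.
#' @param depths Integer vector of subsample sizes (each <= total reads).
#' @param seed Optional RNG seed for the subsampling.
#' @param key Duplicate key, see [collapse_duplicates()].
#' @return data.frame with `depth` and `usable_fraction`.
#' @export
saturation_curve <- function(reads, depths, seed = NULL,
                             key = c("five_prime", "span")) {
  if (any(depths > length(reads)))
    stop("requested depth exceeds available reads")
  if (!is.null(seed)) set.seed(seed)
  frac <- vapply(depths, function(d) {
    sub <- reads[sample.int(length(reads), d)]
    length(collapse_duplicates(sub, key)$usable) / d
  }, numeric(1))
  data.frame(depth = depths, usable_fraction = frac)
}
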