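#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom Biostrings DNAStringSet RNAStringSet DNAString reverseComplement
#'   subseq extractAt oligonucleotideFrequency writeXStringSet readDNAStringSet
#'   readRNAStringSet quality BStringSet
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths "seqlevels<-"
#' @importFrom stats rpois runif setNames
#' @importFrom utils write.table read.table
NULL

#' Strand-aware 5' start of mapped reads
#'
#' The crosslink site of a truncation-based CLIP read is its genomic 5' end:
#' `start` on the plus strand, `end` on the minus strand (1-based, inclusive).
#'
#' @param reads A `GRanges` of mapped reads.
#' @return Integer vector of 5'-start positions.
#' @export
five_prime_start <- function(reads) {
  ifelse(as.character(strand(reads)) == "-",
         GenomicRanges::end(reads),
         GenomicRanges::start(reads))
}

#' Convert between RNA and DNA alphabets
#'
#' Sequences are stored as DNA throughout the pipeline; miRNAs as RNA.
#' Conversion happens only at comparison boundaries.
#'
#' @param x Character vector of sequences.
#' @return Character vector in the other alphabet (uppercased).
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @rdname rna_to_dna
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# Strand-aware sequence extraction: the window starts at `pos` and extends
# `len` bases 3'-ward along `strand`; minus-strand windows are
# reverse-complemented so the returned string reads 5'->3' on the read strand.
# Out-of-chromosome windows return NA.
extract_strand_seq <- function(genome, chrom, strand, pos, len) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  if (length(len) == 1L) len <- rep(len, n)
  out <- rep(NA_character_, n)
  lo <- ifelse(strand == "-", pos - len + 1L, pos)
  hi <- ifelse(strand == "-", pos, pos + len - 1L)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    clen <- length(genome[[ch]])
    ok <- idx[lo[idx] >= 1L & hi[idx] <= clen]
    if (!length(ok)) next
    seqs <- extractAt(genome[[ch]], IRanges(lo[ok], hi[ok]))
    seqs <- DNAStringSet(seqs)
    minus <- strand[ok] == "-"
    if (any(minus)) seqs[minus] <- reverseComplement(seqs[minus])
    out[ok] <- as.character(seqs)
  }
  out
}

# Deterministic child seed so that independent stages driven by one master
# seed do not reuse the same random stream. Kept below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347L) %% 2147483647)
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

random_umis <- function(n, len) {
  if (len == 0L) return(rep("", n))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

# All k-mers over an alphabet, in lexicographic order.
all_kmers <- function(k, alphabet = c("A", "C", "G", "T")) {
  if (k == 0L) return("")
  grid <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder for lexicographic
  apply(grid[, k:1, drop = FALSE], 1L, paste, collapse = "")
}
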