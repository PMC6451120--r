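#' Build transcript models for metagene analysis
#'
#' One representative transcript per gene (the longest mature sequence), with
#' ordered exon blocks and -- for coding genes -- the 5'UTR/CDS/3'UTR span
#' lengths in spliced transcript coordinates.
#'
#' @param annotation An `annotation_model`.
#' @return List of transcript models (`transcript_id`, `gene_id`, `gene_type`,
#'   `chrom`, `strand`, `exons` as genomic `IRanges`, `tx_len`, and
#'   `region_lens = c(utr5, cds, utr3)` for coding genes).
#' @export
build_transcript_models <- function(annotation) {
  exons <- annotation$exons
  genes <- annotation$genes
  gene_type <- setNames(genes$gene_type, genes$gene_id)
  models <- list()
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid]
    gid <- e$gene_id[1]
    models[[tid]] <- list(transcript_id = tid, gene_id = gid,
                          gene_type = unname(gene_type[gid]),
                          chrom = as.character(seqnames(e))[1],
                          strand = as.character(strand(e))[1],
                          exons = sort(ranges(e)),
                          tx_len = sum(width(e)))
  }
  # one representative (longest) transcript per gene
  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  models <- lapply(by_gene, function(ms) {
    ms[[which.max(vapply(ms, `[[`, numeric(1), "tx_len"))]]
  })
  # region spans in transcript coordinates for coding genes
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (!m$gene_type %in% c("protein_coding", "histone_like")) next
    reg <- annotation$regions[annotation$regions$gene_id == m$gene_id]
    lens <- c(utr5 = sum(width(reg[reg$label == "five_prime_utr"])),
              cds = sum(width(reg[reg$label == "cds"])),
              utr3 = sum(width(reg[reg$label == "three_prime_utr"])))
    models[[i]]$region_lens <- lens
  }
  unname(models)
}

#' Project genomic positions onto spliced transcript coordinates
#'
#' Maps strand-aware genomic positions (e.g. crosslink sites) through a
#' transcript's exon chain to 0-based coordinates along the spliced transcript
#' in 5'->3' orientation. Positions in introns or outside the transcript
#' return NA.
#'
#' @param positions Integer vector of genomic positions (1-based).
#' @param transcript One model from [build_transcript_models()].
#' @return Integer vector of 0-based transcript coordinates (NA if intronic or
#'   outside).
#' @export
project_to_transcript <- function(positions, transcript) {
  ex <- transcript$exons  # sorted ascending genomic
  starts <- start(ex); ends <- end(ex); w <- width(ex)
  if (transcript$strand == "+") {
    cum <- cumsum(c(0L, w[-length(w)]))
    out <- rep(NA_integer_, length(positions))
    for (j in seq_along(ex)) {
      in_ex <- positions >= starts[j] & positions <= ends[j]
      out[in_ex] <- cum[j] + (positions[in_ex] - starts[j])
    }
  } else {
    # transcript 5' end is the highest genomic coordinate
    ordj <- rev(seq_along(ex))
    cum <- cumsum(c(0L, w[ordj][-length(w)]))
    out <- rep(NA_integer_, length(positions))
    for (k in seq_along(ordj)) {
      j <- ordj[k]
      in_ex <- positions >= starts[j] & positions <= ends[j]
      out[in_ex] <- cum[k] + (ends[j] - positions[in_ex])
    }
  }
  out
}

#' Length-normalised metagene profile
#'
#' Maps read crosslink sites (strand-aware 5' starts) onto transcript
#' coordinates and bins them into a fixed number of equal parts: 50 each for
#' the 5'UTR, CDS and 3'UTR of coding transcripts (concatenated to 150 bins),
#' or 150 parts across the whole transcript for lncRNAs. Per-transcript bin
#' counts are normalised to sum 1 before summation so long or deep genes do
#' not dominate (`normalize = FALSE` gives raw summed counts).
#'
#' @param reads `GRanges` of usable reads (typically those in specific
#'   clusters).
#' @param transcripts Output of [build_transcript_models()].
#' @param gene_type `"protein_coding"` (includes histone-like genes) or
#'   `"lncRNA"`.
#' @param parts_coding Bins per region for coding transcripts.
#' @param parts_lnc Bins for lncRNA transcripts.
#' @param normalize Normalise each transcript's bin counts to sum 1.
#' @return List with `bins` (numeric vector, length 150), `region` (bin
#'   labels), and `n_transcripts` (transcripts contributing reads).
#' @export
metagene_profile <- function(reads, transcripts,
                             gene_type = c("protein_coding", "lncRNA"),
                             parts_coding = c(50L, 50L, 50L),
                             parts_lnc = 150L, normalize = TRUE) {
  gene_type <- match.arg(gene_type)
  wanted <- if (gene_type == "protein_coding") c("protein_coding", "histone_like")
            else "lncRNA"
  txs <- Filter(function(m) m$gene_type %in% wanted, transcripts)
  if (!length(txs)) stop("no transcripts of gene_type ", gene_type)
  coding <- gene_type == "protein_coding"
  n_bins <- if (coding) sum(parts_coding) else parts_lnc
  region <- if (coding) rep(c("five_prime_utr", "cds", "three_prime_utr"),
                            parts_coding)
            else rep("transcript", parts_lnc)
  p5 <- five_prime_start(reads)
  chrom <- as.character(seqnames(reads))
  str <- as.character(strand(reads))
  total <- numeric(n_bins)
  n_contrib <- 0L
  for (m in txs) {
    sel <- which(chrom == m$chrom & str == m$strand)
    if (!length(sel)) next
    t <- project_to_transcript(p5[sel], m)
    t <- t[!is.na(t)]
    if (!length(t)) next
    if (coding) {
      rl <- m$region_lens
      if (any(rl == 0))
        warning("transcript ", m$transcript_id,
                " has a zero-length region; it contributes empty bins there")
      bnd <- cumsum(rl)
      bins <- rep(NA_integer_, length(t))
      in1 <- t < bnd[1]
      in2 <- t >= bnd[1] & t < bnd[2]
      in3 <- t >= bnd[2] & t < bnd[3]
      if (rl[1] > 0)
        bins[in1] <- pmin(floor(t[in1] * parts_coding[1] / rl[1]),
                          parts_coding[1] - 1L)
      if (rl[2] > 0)
        bins[in2] <- parts_coding[1] +
          pmin(floor((t[in2] - bnd[1]) * parts_coding[2] / rl[2]),
               parts_coding[2] - 1L)
      if (rl[3] > 0)
        bins[in3] <- parts_coding[1] + parts_coding[2] +
          pmin(floor((t[in3] - bnd[2]) * parts_coding[3] / rl[3]),
               parts_coding[3] - 1L)
      bins <- bins[!is.na(bins)]
    } else {
      bins <- pmin(floor(t * parts_lnc / m$tx_len), parts_lnc - 1L)
    }
    if (!length(bins)) next
    cnt <- tabulate(bins + 1L, nbins = n_bins)
    if (normalize) cnt <- cnt / sum(cnt)
    total <- total + cnt
    n_contrib <- n_contrib + 1L
  }
  list(bins = total, region = region, n_transcripts = n_contrib)
}
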