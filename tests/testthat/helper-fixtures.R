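suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# Shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Full default-condition experiment (the study conditions).
default_sim <- function() {
  fixture("default_sim", function() {
    simulate_spyclip_experiment(sim_config(seed = 101L))
  })
}

# Small, fast experiment for structural tests.
small_config <- function(seed = 11L, ...) {
  args <- list(genome_length = 40000L, n_chroms = 1L, n_genes = 8L,
               n_histone_like = 1L, n_lncrna = 1L,
               n_crosslink_sites = 40L, site_strength_mean = 12,
               n_input_reads = 4000L, n_mirnas = 8L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

small_sim <- function() {
  fixture("small_sim", function() simulate_spyclip_experiment(small_config()))
}

# Random mapped reads for dedup/cluster fixtures.
random_reads <- function(n, n_pos = 50L, n_umi = 20L, seed = 1L,
                         chroms = c("chrA", "chrB")) {
  set.seed(seed)
  pos <- sample.int(10000L, n_pos)
  p5 <- sample(pos, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  len <- sample(30:60, n, replace = TRUE)
  start <- ifelse(strand == "-", p5 - len + 1L, p5)
  gr <- GRanges(sample(chroms, n, replace = TRUE),
                IRanges(start, width = len), strand = strand)
  gr$umi <- paste0("U", sample.int(n_umi, n, replace = TRUE))
  gr$name <- paste0("r", seq_len(n), ":", gr$umi)
  gr$library_id <- "test"
  gr
}

# Independent brute-force duplicate-collapse oracle: hash-group on the
# strand-aware 5' start + UMI, keep the first read in coordinate-sorted order.
oracle_collapse <- function(reads) {
  ord <- order(as.character(seqnames(reads)), start(reads), end(reads))
  reads <- reads[ord]
  p5 <- ifelse(as.character(strand(reads)) == "-", end(reads), start(reads))
  key <- paste(as.character(seqnames(reads)), as.character(strand(reads)),
               p5, reads$umi)
  keep <- !duplicated(key)
  list(usable = reads[keep], n_duplicates = sum(!keep))
}

# Independent O(n^2) single-linkage clustering oracle: full pairwise
# adjacency (|pos_i - pos_j| <= window, same chrom/strand), connected
# components via igraph.
oracle_cluster <- function(sites, window = 3L) {
  df <- data.frame(chrom = as.character(seqnames(sites)),
                   strand = as.character(strand(sites)),
                   pos = start(sites), count = sites$read_count,
                   stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$chrom, df$strand))) {
    sub <- df[paste(df$chrom, df$strand) == key, ]
    n <- nrow(sub)
    adj <- abs(outer(sub$pos, sub$pos, "-")) <= window
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    lab <- igraph::components(g)$membership
    for (l in unique(lab)) {
      m <- sub[lab == l, ]
      m <- m[order(m$pos), ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = m$chrom[1], strand = m$strand[1],
        start = min(m$pos), end = max(m$pos),
        summit = m$pos[which.max(m$count)],
        read_count = sum(m$count))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

clusters_to_df <- function(cl) {
  df <- data.frame(chrom = as.character(seqnames(cl)),
                   strand = as.character(strand(cl)),
                   start = start(cl), end = end(cl),
                   summit = cl$summit, read_count = cl$read_count,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}

# Run dedup + clustering + input deduction on a simulated experiment.
cluster_pipeline <- function(sim, window = 3L, threshold = 15) {
  dd <- collapse_duplicates(sim$clip$aligned_bed)
  ddi <- collapse_duplicates(sim$input$aligned_bed)
  cl <- cluster_sites(call_crosslink_sites(dd$usable), window)
  cl <- quantify_rpm(cl, length(dd$usable))
  cl <- deduct_input(cl, ddi$usable, threshold = threshold)
  list(clusters = cl, usable = dd$usable, input_usable = ddi$usable)
}

truth_granges <- function(sim) {
  tr <- sim$clip$truth$crosslink_sites
  GRanges(tr$chrom, IRanges(tr$position, tr$position), strand = tr$strand)
}
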