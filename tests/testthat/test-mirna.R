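let7 <- c(`let-7` = "UGAGGUAGUAGGUUGUAUAGUU")  # 22 nt
let7_dna <- "TGAGGTAGTAGGTTGTATAGTT"

test_that("miRNA counting accepts -2..+2 nt variants only", {
  ctx <- c(`let-7` = "GC")
  reads <- c(let7_dna,                                  # exact
             substr(let7_dna, 1, 21),                   # -1
             substr(let7_dna, 1, 20),                   # -2
             substr(let7_dna, 1, 19),                   # -3: rejected
             paste0(let7_dna, "G"),                     # +1 templated
             paste0(let7_dna, "A"),                     # +1 mismatch: rejected
             paste0(let7_dna, "GC"),                    # +2 templated
             paste0(let7_dna, "GA"))                    # +2 mismatch: rejected
  got <- count_mirnas(reads, let7, genome_3p_context = ctx)
  expect_equal(got$count, 5)
  # without genomic context the extensions are disallowed, with a warning
  expect_warning(got2 <- count_mirnas(reads, let7), "context")
  expect_equal(got2$count, 3)
})

test_that("ambiguous reads are split fractionally or assigned to the first", {
  # mir-b truncated by 1 nt equals mir-a exactly
  mirs <- c(`mir-a` = "UGAGGUAGUAGGUUGUAUAGUU",
            `mir-b` = "UGAGGUAGUAGGUUGUAUAGUUC")
  ctx <- c(`mir-a` = "AA", `mir-b` = "AA")
  got <- count_mirnas(let7_dna, mirs, genome_3p_context = ctx)
  expect_equal(setNames(got$count, got$name),
               c(`mir-a` = 0.5, `mir-b` = 0.5))
  gotf <- count_mirnas(let7_dna, mirs, genome_3p_context = ctx,
                       count_mode = "first")
  expect_equal(setNames(gotf$count, gotf$name),
               c(`mir-a` = 1, `mir-b` = 0))
  # ranks: descending count, ties broken lexicographically by name
  reads <- c(rep(paste0(rna_to_dna(unname(mirs[2])), ""), 3), let7_dna)
  g3 <- count_mirnas(reads, mirs, genome_3p_context = ctx)
  expect_equal(g3$rank, 1:2)
  expect_equal(g3$name[1], "mir-b")
})

test_that("miRNA counting matches a brute-force variant oracle", {
  set.seed(31)
  n_mir <- 10L
  lens <- sample(20:23, n_mir, replace = TRUE)
  mirs <- setNames(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1)), sprintf("m%02d", seq_len(n_mir)))
  ctx <- setNames(vapply(seq_len(n_mir), function(i)
    paste(sample(c("A", "C", "G", "T"), 2), collapse = ""), character(1)),
    names(mirs))
  # reads drawn from the variant space plus random decoys
  variants_of <- function(i) {
    s <- rna_to_dna(unname(mirs[i])); L <- nchar(s)
    c(s, substr(s, 1, L - 1), substr(s, 1, L - 2),
      paste0(s, substr(ctx[i], 1, 1)), paste0(s, ctx[i]))
  }
  all_var <- lapply(seq_len(n_mir), variants_of)
  reads <- c(unlist(lapply(1:200, function(j) {
    i <- sample.int(n_mir, 1)
    sample(all_var[[i]], 1)
  })), vapply(1:50, function(j)
    paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""),
    character(1)))
  oracle <- setNames(numeric(n_mir), names(mirs))
  for (r in reads) {
    hit <- which(vapply(all_var, function(v) r %in% v, logical(1)))
    if (length(hit)) oracle[hit] <- oracle[hit] + 1 / length(hit)
  }
  got <- count_mirnas(reads, mirs, genome_3p_context = ctx)
  expect_equal(setNames(got$count, got$name), oracle[got$name])
  expect_equal(sum(got$count) + sum(oracle == 0) * 0, sum(oracle))
})

test_that("cluster sequences read 5'->3' on the cluster strand", {
  g <- DNAStringSet(c(c1 = paste0(strrep("A", 10), "TCTCT", strrep("G", 10))))
  cl <- GRanges("c1", IRanges(11, 15), strand = "+", cluster_id = "x")
  expect_equal(unname(cluster_sequences(cl, g, flank = 2L)),
               "AATCTCTGG")
  clm <- GRanges("c1", IRanges(11, 15), strand = "-", cluster_id = "x")
  expect_equal(unname(cluster_sequences(clm, g, flank = 2L)),
               revcomp_dna("AATCTCTGG"))
  # off-chromosome extraction yields NA
  edge <- GRanges("c1", IRanges(1, 5), strand = "+", cluster_id = "e")
  expect_true(is.na(cluster_sequences(edge, g, flank = 2L)))
})

test_that("7-mer scan reports per-start hit percentages over all clusters", {
  mir <- c(m1 = "UGAGGCAC")  # 8 nt: starts 1 and 2
  rc1 <- revcomp_dna(rna_to_dna("UGAGGCA"))  # start 1: TGCCTCA
  rc2 <- revcomp_dna(rna_to_dna("GAGGCAC"))  # start 2: GTGCCTC
  # flanks chosen so neither planted complement extends into the other
  seqs <- c(a = paste0("AAAA", rc1, "AAAA", rc2, "GGGG"),
            b = paste0("CCCC", rc1, "CCCC"),
            c = strrep("G", 20))
  res <- scan_seven_mers(seqs, mir)
  expect_equal(res$per_start$mirna_start, 1:2)
  expect_equal(res$per_start$n_clusters_hit, c(2L, 1L))
  expect_equal(res$per_start$pct, 100 * c(2, 1) / 3)
  expect_equal(res$per_start$n_mirnas_scanned, c(1L, 1L))
  h <- res$hits[res$hits$cluster == "a", ]
  expect_setequal(h$mirna_start, 1:2)
  expect_equal(h$target_offset[h$mirna_start == 1], 5L)
  expect_equal(h$target_offset[h$mirna_start == 2], 16L)
  # NA sequences are skipped but stay in the denominator
  res2 <- scan_seven_mers(c(seqs, d = NA), mir)
  expect_equal(res2$per_start$pct, 100 * c(2, 1) / 4)
})

test_that("every planted 7-mer target is recovered at its planted register", {
  sim <- small_sim()
  tg <- sim$planted_targets
  expect_gt(nrow(tg), 0)
  loci <- GRanges(tg$chrom, IRanges(tg$position, tg$position),
                  strand = tg$strand,
                  cluster_id = sprintf("t%03d", seq_len(nrow(tg))))
  seqs <- cluster_sequences(loci, sim$genome, flank = 30L)
  res <- scan_seven_mers(seqs, sim$mirnas)
  found <- vapply(seq_len(nrow(tg)), function(i) {
    any(res$hits$cluster == loci$cluster_id[i] &
          res$hits$mirna == tg$mirna[i] &
          res$hits$mirna_start == tg$mirna_start[i])
  }, logical(1))
  expect_true(all(found))
})

test_that("seed-complement density peaks where the seed complement starts", {
  g <- DNAStringSet(c(c1 = strrep("A", 100)))
  seed_rc <- revcomp_dna(rna_to_dna(substr(let7, 2, 8)))  # CTACCTCA -> 7 nt
  subseq(g[["c1"]], 50, 56) <- DNAString(seed_rc)
  cl <- GRanges("c1", IRanges(50, 50), strand = "+", summit = 50L)
  d <- seed_density(cl, g, let7, window = 20L)
  expect_equal(d$offset, -10:9)
  expect_equal(d$density[d$offset == 0], 1)
  expect_equal(sum(d$density), 1)
  # no match anywhere: flat zero
  d0 <- seed_density(cl, DNAStringSet(c(c1 = strrep("A", 100))), let7, 20L)
  expect_equal(d0$density, rep(0, 20))
  expect_error(seed_density(GRanges("c1", IRanges(2, 2), strand = "+",
                                    summit = 2L),
                            g, let7, 20L),
               "in-bounds")
})

test_that("HAR enrichment applies the two-fold cutoff on combined loci", {
  wt <- GRanges("c1", IRanges(c(100, 300), width = 10), strand = "+",
                read_count = c(50L, 100L))
  har <- GRanges("c1", IRanges(c(100, 300), width = 10), strand = "+",
                 read_count = c(100L, 198L))
  out <- har_enrichment(wt, har, total_wt = 1e6, total_har = 1e6)
  expect_equal(out$fold_change, c(2, 1.98))
  expect_identical(out$har_enriched, c(TRUE, FALSE))
  # nearby clusters merge into one locus under the gap window
  wt2 <- GRanges("c1", IRanges(100, 110), strand = "+", read_count = 10L)
  har2 <- GRanges("c1", IRanges(112, 120), strand = "+", read_count = 40L)
  out2 <- har_enrichment(wt2, har2, total_wt = 1e6, total_har = 1e6)
  expect_length(out2, 1)
  expect_equal(out2$fold_change, 4)
  # a locus absent from WT gets the pseudocount there
  har3 <- GRanges("c1", IRanges(c(100, 500), width = 10), strand = "+",
                  read_count = c(10L, 30L))
  out3 <- har_enrichment(wt2, har3, total_wt = 1e6, total_har = 1e6)
  expect_equal(out3$rpm_wt[2], 1)
  # totals come from quantify_rpm metadata when not supplied
  wtq <- quantify_rpm(wt, 1e6); harq <- quantify_rpm(har, 1e6)
  outq <- har_enrichment(wtq, harq)
  expect_equal(outq$fold_change, out$fold_change)
  expect_error(har_enrichment(wt, har), "totals")
})

test_that("MFE pair files round-trip and the hook degrades gracefully", {
  pairs <- data.frame(mirna = c("m1", "m1", "m2"),
                      mirna_seq = c("UGAGGUAG", "UGAGGUAG", "ACGUACGU"),
                      target_id = c("t1", "t2", "t3"),
                      target_seq = c("CTACCTCA", "GGGGCCCC", "ACGTACGT"),
                      stringsAsFactors = FALSE)
  dir <- tempfile("mfe")
  paths <- mfe_write_pairs(pairs, dir)
  expect_true(all(file.exists(paths)))
  back <- mfe_read_pairs(dir)
  expect_equal(back, pairs)
  fa <- readLines(paths[["mirnas"]])
  expect_equal(fa[1], ">m1")
  expect_equal(fa[2], "UGAGGUAG")  # RNA alphabet in the miRNA fasta
  expect_warning(mfe_hook(pairs, dir, program = "no_such_program_xyz"),
                 "skipped")
  unlink(dir, recursive = TRUE)
})
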