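test_that("crosslink sites count distinct strand-aware 5' starts", {
  gr <- GRanges("chr1", IRanges(c(rep(1000, 5), rep(1003, 2)), width = 40),
                strand = "+")
  gr$umi <- paste0("U", 1:7)
  sites <- call_crosslink_sites(gr)
  expect_equal(start(sites), c(1000, 1003))
  expect_equal(sites$read_count, c(5L, 2L))
  # minus-strand site is the read end
  m <- GRanges("chr1", IRanges(2001, 2040), strand = "-")
  m$umi <- "U"
  sm <- call_crosslink_sites(m)
  expect_equal(start(sm), 2040)
  # empty input
  expect_length(call_crosslink_sites(gr[0]), 0)
})

test_that("single-linkage chaining joins sites within the window", {
  sites <- GRanges("chr1", IRanges(c(100, 102, 103), width = 1), strand = "+",
                   read_count = c(5L, 2L, 1L))
  cl <- cluster_sites(sites, window = 3L)
  expect_length(cl, 1)
  expect_equal(start(cl), 100)
  expect_equal(end(cl), 103)
  expect_equal(cl$summit, 100L)
  expect_equal(cl$read_count, 8L)
  # gap of 4 exceeds a 3-nt window
  s2 <- GRanges("chr1", IRanges(c(100, 104), width = 1), strand = "+",
                read_count = c(1L, 1L))
  expect_length(cluster_sites(s2, 3L), 2)
  # single site forms its own cluster with itself as summit
  s3 <- GRanges("chr2", IRanges(500, 500), strand = "-", read_count = 3L)
  c3 <- cluster_sites(s3)
  expect_equal(c3$summit, 500L)
  # summit tie-break: leftmost maximal site
  s4 <- GRanges("chr1", IRanges(c(10, 12), width = 1), strand = "+",
                read_count = c(4L, 4L))
  expect_equal(cluster_sites(s4)$summit, 10L)
})

test_that("clustering equals the O(n^2) single-linkage oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    set.seed(seed)
    n <- 300L
    sites <- GRanges(sample(c("c1", "c2"), n, replace = TRUE),
                     IRanges(sample.int(3000L, n), width = 1),
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     read_count = sample.int(50L, n, replace = TRUE))
    sites <- sites[!duplicated(paste(seqnames(sites), strand(sites),
                                     start(sites)))]
    expect_identical(clusters_to_df(cluster_sites(sites, 3L)),
                     oracle_cluster(sites, 3L))
  }
  # one large fixture at full scale
  set.seed(99)
  n <- 2000L
  sites <- GRanges("c1", IRanges(sample.int(15000L, n), width = 1),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   read_count = sample.int(50L, n, replace = TRUE))
  sites <- sites[!duplicated(paste(strand(sites), start(sites)))]
  expect_identical(clusters_to_df(cluster_sites(sites, 3L)),
                   oracle_cluster(sites, 3L))
})

test_that("clustering is order-invariant and leaves no mergeable pair", {
  set.seed(4)
  n <- 400L
  sites <- GRanges("c1", IRanges(sample.int(4000L, n), width = 1),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   read_count = sample.int(20L, n, replace = TRUE))
  sites <- sites[!duplicated(paste(strand(sites), start(sites)))]
  shuffled <- sites[sample(length(sites))]
  expect_identical(clusters_to_df(cluster_sites(sites)),
                   clusters_to_df(cluster_sites(shuffled)))
  cl <- cluster_sites(sites, 3L)
  for (st in c("+", "-")) {
    s <- cl[strand(cl) == st]
    s <- s[order(start(s))]
    if (length(s) > 1)
      expect_true(all(start(s)[-1] - end(s)[-length(s)] > 3L))
  }
})

test_that("RPM is reads per million mapped and requires a positive total", {
  cl <- GRanges("c1", IRanges(1, 10), strand = "+", read_count = 10L)
  expect_equal(quantify_rpm(cl, 1e6)$rpm, 10)
  expect_error(quantify_rpm(cl, 0), "positive")
  # linearity: cluster RPMs sum to 1e6 * in-cluster fraction
  cl2 <- GRanges("c1", IRanges(c(1, 100), width = 5), strand = "+",
                 read_count = c(30L, 20L))
  q <- quantify_rpm(cl2, 1000L)
  expect_equal(sum(q$rpm), 1e6 * 50 / 1000)
})

test_that("input deduction applies the 15-fold threshold exactly", {
  # one input read inside each cluster span; input total 1e6 -> input rpm 2
  # when the input library is half a million reads... construct directly:
  cl <- GRanges("c1", IRanges(c(100, 300), width = 10), strand = "+",
                read_count = c(30L, 29L))
  cl <- quantify_rpm(cl, 1e6)  # rpm 30 and 29.9... use counts as rpm
  cl$rpm <- c(30, 29.9)
  input <- GRanges("c1", IRanges(c(105, 305), width = 30), strand = "+")
  input$umi <- c("A", "B")
  out <- deduct_input(cl, input, input_total = 500000L, threshold = 15)
  expect_equal(out$input_rpm, c(2, 2))
  expect_equal(out$fold_enrichment, c(15, 14.95))
  expect_identical(out$specific, c(TRUE, FALSE))
})

test_that("clusters with no input reads get the pseudocount", {
  cl <- GRanges("c1", IRanges(100, 110), strand = "+", read_count = 50L)
  cl <- quantify_rpm(cl, 1000L)
  out <- deduct_input(cl, GRanges("c1", IRanges(5000, 5030), strand = "+",
                                  umi = "X"),
                      input_total = 1000L, pseudocount_reads = 1)
  expect_equal(out$input_rpm, 1e6 / 1000)
  expect_true(is.finite(out$fold_enrichment))
})

test_that("contaminant loci are rejected and planted sites recovered", {
  for (seed in c(3L, 17L)) {
    sim <- simulate_spyclip_experiment(small_config(seed = seed))
    res <- cluster_pipeline(sim)
    sp <- res$clusters[res$clusters$specific]
    cont <- sim$annotation$contaminant_loci
    expect_equal(sum(countOverlaps(cont, sp, ignore.strand = FALSE)), 0L,
                 label = paste("contaminant overlap, seed", seed))
    tr <- truth_granges(sim)
    expect_gte(mean(countOverlaps(tr, sp) > 0), 0.9)
  }
})

test_that("replicate reproducibility is 1 for self, high for true replicates", {
  sim <- small_sim()
  res <- cluster_pipeline(sim)
  cl <- res$clusters
  expect_equal(replicate_reproducibility(cl, cl), 1.0)
  expect_error(replicate_reproducibility(cl[1:2], cl[1:2]), "3 union loci")
})

test_that("independent resimulations of one truth correlate; disjoint truths do not", {
  # two libraries from the same planted sites (different library noise):
  # reuse the same config but regenerate reads with another seed while
  # holding genome/annotation/sites fixed
  cfg <- small_config(seed = 61L, site_strength_mean = 25)
  ga <- generate_genome_and_annotation(cfg)
  sites <- spyclip:::choose_crosslink_sites(cfg, ga$annotation)
  cfg_b <- cfg; cfg_b$seed <- 62L
  lib_a <- simulate_clip_library(cfg, ga$genome, ga$annotation, sites = sites)
  lib_b <- simulate_clip_library(cfg_b, ga$genome, ga$annotation, sites = sites)
  mk <- function(lib) {
    dd <- collapse_duplicates(lib$aligned_bed)
    quantify_rpm(cluster_sites(call_crosslink_sites(dd$usable)),
                 length(dd$usable))
  }
  ca <- mk(lib_a); cb <- mk(lib_b)
  expect_gte(replicate_reproducibility(ca, cb), 0.9)
  # disjoint truth: different site seed
  cfg_c <- small_config(seed = 63L, site_strength_mean = 25)
  sites_c <- spyclip:::choose_crosslink_sites(cfg_c, ga$annotation)
  lib_c <- simulate_clip_library(cfg_c, ga$genome, ga$annotation,
                                 sites = sites_c)
  cc <- mk(lib_c)
  expect_lt(abs(replicate_reproducibility(ca, cc)), 0.2)
})
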