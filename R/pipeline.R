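#' Pipeline run configuration
#'
#' Collects input paths and per-stage parameters. Every stage parameter
#' defaults to the protocol's stated value: 10-nt UMI, 30-65 nt usable
#' inserts, 3-nt clustering window, 15-fold input enrichment, pentamer
#' z-score threshold 200 in [-10,+10] summit windows, 2-fold HAR enrichment,
#' top-100 miRNAs.
#'
#' @param genome_fa Genome FASTA path (required).
#' @param gtf Annotation GTF path (required).
#' @param clip_bed Aligned CLIP reads, BED6 (required).
#' @param input_bed Aligned input reads, BED6 (required).
#' @param fastq Optional raw CLIP FASTQ; when given, reads failing UMI
#'   extraction, adapter trimming or the length filter are removed from the
#'   BED before deduplication.
#' @param mirnas_fa Optional mature miRNA FASTA.
#' @param outdir Output directory.
#' @param adapter 3' adapter sequence.
#' @param umi_length,min_len,max_len Read-processing parameters.
#' @param window Clustering window (nt).
#' @param enrichment_threshold Input fold-enrichment threshold.
#' @param z_threshold,n_random_draws,motif_window Pentamer-enrichment
#'   parameters.
#' @param category_order `"splicing"`, `"ago2"`, or an explicit permutation of
#'   the four region labels.
#' @param cl_set Crosslink-motif tetramer set (see [expand_cl_set()]).
#' @param top_n_mirnas miRNAs used in the target scan.
#' @param har_fold HAR enrichment threshold.
#' @param dedup_key Duplicate key, see [collapse_duplicates()].
#' @param seed RNG seed for the stochastic stages (background draws,
#'   saturation subsampling).
#' @return A `run_config` list.
#' @export
run_config <- function(genome_fa, gtf, clip_bed, input_bed,
                       fastq = NULL, mirnas_fa = NULL,
                       outdir = "spyclip_out",
                       adapter = "AGATCGGAAGAGC",
                       umi_length = 10L, min_len = 30L, max_len = 65L,
                       window = 3L, enrichment_threshold = 15,
                       z_threshold = 200, n_random_draws = 100L,
                       motif_window = c(-10L, 10L),
                       category_order = "splicing",
                       cl_set = "all_pyrimidine",
                       top_n_mirnas = 100L, har_fold = 2,
                       dedup_key = "five_prime", seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

resolve_order <- function(x) {
  if (identical(x, "splicing")) return(category_order_splicing)
  if (identical(x, "ago2")) return(category_order_ago2)
  stopifnot(setequal(x, region_labels))
  x
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order: read processing (optional,
#' FASTQ-driven), PCR-duplicate collapsing, crosslink-site cluster calling,
#' RPM quantification, input deduction, category annotation, pentamer
#' enrichment, crosslink-motif profile, miRNA target scanning, and metagene
#' profiles. All outputs are written under `config$outdir` and listed in a
#' manifest with md5 checksums; the effective parameter set is written as
#' JSON. Rerunning with the same config and seed reproduces identical
#' checksums.
#'
#' @param config A [run_config()].
#' @return List with `manifest` (data.frame of file, md5), `params`, and the
#'   main in-memory results (`clusters`, `composition`, `categories`,
#'   `pentamers`, `metagene_coding`, `metagene_lnc`).
#' @export
run_pipeline <- function(config) {
  required <- c("genome_fa", "gtf", "clip_bed", "input_bed")
  for (f in required) {
    if (is.null(config[[f]])) stop("validation error: missing ", f)
    if (!file.exists(config[[f]]))
      stop("validation error: ", f, " not found: ", config[[f]])
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  order <- resolve_order(config$category_order)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }

  stage_log("load", "reading genome, annotation, reads")
  genome <- readDNAStringSet(config$genome_fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  annotation <- read_annotation(config$gtf,
                                chrom_lengths = setNames(width(genome),
                                                         names(genome)))
  clip <- read_mapped_bed(config$clip_bed, "clip")
  input <- read_mapped_bed(config$input_bed, "input")
  stage_log("load", length(clip), " CLIP and ", length(input), " input records")

  n_total_raw <- length(clip)
  if (!is.null(config$fastq)) {
    stage_log("process", "UMI extraction, adapter trimming, length filter")
    fq <- read_fastq(config$fastq)
    pr <- process_reads(fq, config$adapter, config$umi_length,
                        config$min_len, config$max_len)
    n_total_raw <- pr$counts[["total"]]
    keep <- clip$name %in% pr$processed$read_id
    stage_log("process", sum(keep), "/", length(clip), " records kept")
    clip <- clip[keep]
    emit("processed_reads.tsv", function(p)
      write.table(pr$processed, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  stage_log("dedup", "collapsing PCR duplicates")
  dd_clip <- collapse_duplicates(clip, config$dedup_key)
  dd_input <- collapse_duplicates(input, config$dedup_key)
  usable <- dd_clip$usable
  comp <- read_composition(total = n_total_raw,
                           uniquely_mapped = length(clip),
                           pcr_duplicates = dd_clip$n_duplicates)
  emit("composition.tsv", function(p)
    write.table(comp, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("usable.bed", function(p) write_bed6(usable, p))
  depths <- unique(pmax(1L, round(length(clip) * c(0.1, 0.25, 0.5, 0.75, 1))))
  sat <- saturation_curve(clip, depths, seed = config$seed, key = config$dedup_key)
  emit("saturation.tsv", function(p)
    write.table(sat, p, sep = "\t", quote = FALSE, row.names = FALSE))
  stage_log("dedup", length(usable), " usable CLIP reads, ",
            length(dd_input$usable), " usable input reads")

  stage_log("clusters", "calling crosslink-site clusters")
  sites <- call_crosslink_sites(usable)
  clusters <- cluster_sites(sites, config$window)
  clusters <- quantify_rpm(clusters, length(usable))
  clusters <- deduct_input(clusters, dd_input$usable,
                           input_total = length(dd_input$usable),
                           threshold = config$enrichment_threshold)
  stage_log("clusters", length(clusters), " clusters, ",
            sum(clusters$specific), " specific")

  stage_log("annotate", "assigning element categories")
  clusters$category <- assign_category(clusters, annotation, order)
  histones <- histone_overlap(clusters, annotation,
                              top_n = min(200L, length(clusters)))
  emit("clusters.tsv", function(p) write_clusters(clusters, p))
  emit("clusters.bed", function(p)
    write_clusters(clusters, tempfile(), bed_path = p))
  dist <- category_distribution(clusters, annotation, order)
  emit("category_distribution.tsv", function(p)
    write.table(data.frame(category = names(dist), fraction = dist),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("histone_overlap.tsv", function(p)
    write.table(histones$flags, p, sep = "\t", quote = FALSE, row.names = FALSE))

  specific <- clusters[clusters$specific]
  if (length(specific) >= 3 && any(specific$category != "intergenic")) {
    stage_log("motifs", "pentamer z-scores over ", length(specific),
              " specific clusters")
    pent <- pentamer_zscores(specific, genome, annotation,
                             categories = specific$category,
                             window = config$motif_window,
                             n_random_draws = config$n_random_draws,
                             z_threshold = config$z_threshold,
                             seed = config$seed)
    emit("pentamer_zscores.tsv", function(p)
      write.table(pent, p, sep = "\t", quote = FALSE, row.names = FALSE))
  } else {
    stage_log("motifs", "too few specific clusters; pentamer stage skipped")
    pent <- NULL
  }
  clp <- cl_profile(usable, genome, config$cl_set)
  emit("cl_profile.tsv", function(p)
    write.table(clp, p, sep = "\t", quote = FALSE, row.names = FALSE))

  scan <- NULL
  if (!is.null(config$mirnas_fa) && length(specific) > 0) {
    stage_log("mirna", "7-mer target scan")
    mirnas <- readRNAStringSet(config$mirnas_fa)
    names(mirnas) <- sub("\\s.*$", "", names(mirnas))
    top <- utils::head(mirnas, config$top_n_mirnas)
    seqs <- cluster_sequences(specific, genome)
    scan <- scan_seven_mers(seqs, top)
    emit("seven_mer_hits.tsv", function(p)
      write.table(scan$hits, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("seven_mer_per_start.tsv", function(p)
      write.table(scan$per_start, p, sep = "\t", quote = FALSE, row.names = FALSE))
    sdens <- seed_density(specific, genome, top)
    emit("seed_density.tsv", function(p)
      write.table(sdens, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }

  stage_log("metagene", "length-normalised transcript profiles")
  txs <- build_transcript_models(annotation)
  in_specific <- overlapsAny(GRanges(seqnames(usable),
                                     IRanges(five_prime_start(usable),
                                             five_prime_start(usable)),
                                     strand = strand(usable)),
                             specific, ignore.strand = FALSE)
  mg_reads <- usable[in_specific]
  mg_coding <- metagene_profile(mg_reads, txs, "protein_coding")
  emit("metagene_coding.tsv", function(p)
    write.table(data.frame(bin = seq_along(mg_coding$bins),
                           region = mg_coding$region,
                           density = mg_coding$bins),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  mg_lnc <- tryCatch(metagene_profile(mg_reads, txs, "lncRNA"),
                     error = function(e) NULL)
  if (!is.null(mg_lnc))
    emit("metagene_lncrna.tsv", function(p)
      write.table(data.frame(bin = seq_along(mg_lnc$bins),
                             region = mg_lnc$region,
                             density = mg_lnc$bins),
                  p, sep = "\t", quote = FALSE, row.names = FALSE))

  params <- config[!vapply(config, is.null, logical(1))]
  class(params) <- NULL
  params_path <- file.path(outdir, "params.json")
  jsonlite::write_json(params, params_path, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, params_path)
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write.table(manifest, file.path(outdir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("done", nrow(manifest), " outputs written to ", outdir)
  list(manifest = manifest, params = params, clusters = clusters,
       composition = comp, pentamers = pent, scan = scan,
       metagene_coding = mg_coding, metagene_lnc = mg_lnc)
}
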