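#' Scaled purity-sweep simulation study
#'
#' Reruns the simulation protocol at desk scale: a random two-chromosome
#' reference, SNPs at 0.1%, a fixed number of events of each of the six
#' rearrangement types, 90-bp paired reads with Gaussian N(760, 45)
#' inserts at 40x coverage, and tumor samples mixed to a series of
#' purities against a separately drawn normal-genome read pool (the
#' matched normal sample is a third, independent draw). The cancer genome,
#' truth set and all read pools are generated once and shared across
#' purities; the pool alignments are likewise mapped once and subset per
#' purity, which leaves the per-purity pipelines identical to
#' [run_pipeline()] stage by stage.
#'
#' @param seed integer seed driving every random choice
#' @param purities tumor purities to evaluate (default 1, 0.2, 0.1)
#' @param genome_lengths chromosome lengths (default two of 500 kb)
#' @param events_per_type rearrangement events per type (default 4)
#' @param len_range affected-length range (default 300 bp to 5 kb)
#' @param coverage per-sample read coverage (default 40)
#' @param snp_rate SNP rate of the normal genome (default 0.001)
#' @param config an [sv_config()] object
#' @param verbose print stage progress
#' @return list with `truth`, `runs` (one element per purity: `purity`,
#'   `calls`, `evaluation`, `counts`), and pooled `fdr` across runs
#' @export
run_purity_study <- function(seed = 1L, purities = c(1, 0.2, 0.1),
                             genome_lengths = c(chr1 = 500000L,
                                                chr2 = 500000L),
                             events_per_type = 4L,
                             len_range = c(300L, 5000L), coverage = 40,
                             snp_rate = 0.001, config = sv_config(),
                             verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  set.seed(seed)

  ref <- sim_genome(genome_lengths)
  normal <- add_snps(ref, snp_rate)$genome
  rr <- apply_rearrangements(normal, n_per_type = events_per_type,
                             len_range = len_range)
  truth <- rr$truth
  say("[study] genomes ready: %d truth junctions (%.0fs)", nrow(truth),
      proc.time()[3] - t0)

  gidx <- build_genome_index(ref)
  cancer_reads <- sim_reads(rr$genome, coverage, prefix = "c")
  pool_reads <- sim_reads(normal, coverage, prefix = "p")
  matched_reads <- sim_reads(normal, coverage, prefix = "n")
  say("[study] reads simulated: %d/%d/%d pairs (%.0fs)",
      nrow(cancer_reads), nrow(pool_reads), nrow(matched_reads),
      proc.time()[3] - t0)

  im <- if (is.null(config$insert_mean)) 760 else config$insert_mean
  is_ <- if (is.null(config$insert_sd)) 45 else config$insert_sd
  cancer_pairs <- map_read_pairs(gidx, cancer_reads, sample = "tumor",
                                 insert_mean = im, insert_sd = is_)
  pool_pairs <- map_read_pairs(gidx, pool_reads, sample = "tumor",
                               insert_mean = im, insert_sd = is_)
  matched_pairs <- map_read_pairs(gidx, matched_reads, sample = "normal",
                                  insert_mean = im, insert_sd = is_)
  say("[study] pools mapped (%.0fs)", proc.time()[3] - t0)

  model <- if (is.null(config$insert_mean) || is.null(config$insert_sd))
    estimate_insert_model(cancer_pairs) else insert_model(im, is_)

  ridx_n <- build_read_index(c(matched_reads$read1, matched_reads$read2),
                             sample_label = "normal")
  disc_n <- extract_discordant(matched_pairs, config$mapq_min)
  say("[study] matched-normal dictionary ready (%.0fs)",
      proc.time()[3] - t0)

  runs <- vector("list", length(purities))
  for (ri in seq_along(purities)) {
    phi <- purities[ri]
    n <- nrow(cancer_reads)
    k <- round(phi * n)
    i_c <- sample(n, k)
    i_p <- sample(nrow(pool_reads), n - k)
    tumor_reads <- rbind(cancer_reads[i_c], pool_reads[i_p])
    tumor_pairs <- rbind(cancer_pairs[i_c], pool_pairs[i_p])

    disc_t <- extract_discordant(tumor_pairs, config$mapq_min)
    points <- pairs_to_points(rbind(disc_t, disc_n), gidx$gg)
    points <- cluster_points(points, model$mean)
    clusters <- summarize_clusters(points, tumor_rate = config$somatic_rate,
                                   min_support = config$min_cluster_support)
    regions <- predict_cluster_regions(points, clusters, model,
                                       tau = config$tau, bin = config$bin)
    ridx_t <- build_read_index(c(tumor_reads$read1, tumor_reads$read2),
                               sample_label = "tumor")
    calls <- detect_breakpoints(regions, ridx_t, ridx_n, gidx, model,
                                config$scan)
    ev <- evaluate_calls(calls, truth, tol = config$tol, regions = regions)
    runs[[ri]] <- list(purity = phi, calls = calls, evaluation = ev,
                       counts = list(discordant_tumor = nrow(disc_t),
                                     clusters = nrow(clusters),
                                     regions = nrow(regions),
                                     calls = nrow(calls)))
    say("[study] purity %.0f%%: sensitivity %.1f%%, %d false calls (%.0fs)",
        100 * phi, 100 * ev$sensitivity, ev$n_false, proc.time()[3] - t0)
    rm(ridx_t)
    gc(verbose = FALSE)
  }

  n_false <- sum(vapply(runs, function(r) r$evaluation$n_false, numeric(1)))
  n_calls <- sum(vapply(runs, function(r) r$evaluation$n_calls, numeric(1)))
  list(truth = truth, runs = runs,
       fdr = if (n_calls == 0) NA_real_ else n_false / n_calls,
       n_false = n_false, n_calls = n_calls)
}
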