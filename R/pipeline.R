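#' Pipeline configuration
#'
#' All tunables of the end-to-end pipeline with their defaults. When
#' `insert_mean`/`insert_sd` are `NULL` they are estimated robustly from
#' the accordant pairs of the tumor sample.
#'
#' @param mapq_min minimum mapping quality per end (default 30)
#' @param insert_mean,insert_sd insert model; `NULL` = estimate
#' @param min_cluster_support minimum discordant pairs per cluster
#'   (default 3)
#' @param somatic_rate tumor fraction above which a cluster is somatic
#'   (default 0.9)
#' @param tau relative threshold on the conjugate-transformed grid
#'   (default 0.5)
#' @param bin grid bin size in bp (default 2)
#' @param tol truth-matching tolerance in bp for evaluation (default 10)
#' @param seed RNG seed recorded with the run
#' @param scan a [scan_params()] object
#' @return list of class `sv_config`
#' @export
sv_config <- function(mapq_min = 30L, insert_mean = NULL, insert_sd = NULL,
                      min_cluster_support = 3L, somatic_rate = 0.9,
                      tau = 0.5, bin = 2L, tol = 10L, seed = 1L,
                      scan = scan_params()) {
  structure(list(mapq_min = mapq_min, insert_mean = insert_mean,
                 insert_sd = insert_sd,
                 min_cluster_support = min_cluster_support,
                 somatic_rate = somatic_rate, tau = tau, bin = bin,
                 tol = tol, seed = seed, scan = scan),
            class = "sv_config")
}

#' Run the full breakpoint-detection pipeline
#'
#' Stages: map tumor and normal reads (internal exact-seed mapper),
#' estimate the insert model if unset, extract MAPQ-filtered discordant
#' pairs, cluster them in the plane of global coordinates, predict
#' breakpoint regions with the conjugate operator, build the read
#' dictionaries, scan the regions and call precise junctions with somatic
#' status. If a truth set is supplied, sensitivity and false-detection
#' rate are evaluated.
#'
#' @param reference named character vector of reference chromosome
#'   sequences (or a prebuilt `genome_index`)
#' @param tumor_reads,normal_reads read tables (`qname`, `read1`,
#'   `read2`)
#' @param config an [sv_config()] object
#' @param truth optional truth `data.table` (see
#'   [apply_rearrangements()])
#' @param verbose print stage progress (default TRUE)
#' @return list: `calls`, `regions`, `clusters`, `points`, `model`,
#'   `gidx`, `config`, `counts` (stage tallies) and, with truth,
#'   `evaluation`
#' @export
run_pipeline <- function(reference, tumor_reads, normal_reads,
                         config = sv_config(), truth = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  counts <- list()

  gidx <- if (inherits(reference, "genome_index")) reference
          else build_genome_index(reference)
  say("[svbwt] genome indexed (%.0f bp, %.1fs)", sum(gidx$gg$lengths),
      proc.time()[3] - t0)

  im <- if (is.null(config$insert_mean)) 760 else config$insert_mean
  is_ <- if (is.null(config$insert_sd)) 45 else config$insert_sd
  pt <- map_read_pairs(gidx, tumor_reads, sample = "tumor",
                       insert_mean = im, insert_sd = is_)
  pn <- map_read_pairs(gidx, normal_reads, sample = "normal",
                       insert_mean = im, insert_sd = is_)
  counts$pairs_tumor <- nrow(pt)
  counts$pairs_normal <- nrow(pn)
  say("[svbwt] mapped %d + %d pairs (%.1fs)", nrow(pt), nrow(pn),
      proc.time()[3] - t0)

  model <- if (is.null(config$insert_mean) || is.null(config$insert_sd)) {
    estimate_insert_model(pt)
  } else {
    insert_model(config$insert_mean, config$insert_sd)
  }

  dt_t <- extract_discordant(pt, config$mapq_min)
  dt_n <- extract_discordant(pn, config$mapq_min)
  counts$discordant_tumor <- nrow(dt_t)
  counts$discordant_normal <- nrow(dt_n)
  points <- pairs_to_points(rbind(dt_t, dt_n), gidx$gg)
  points <- cluster_points(points, model$mean)
  clusters <- summarize_clusters(points, tumor_rate = config$somatic_rate,
                                 min_support = config$min_cluster_support)
  counts$clusters <- nrow(clusters)
  say("[svbwt] %d + %d discordant pairs -> %d clusters (%.1fs)",
      nrow(dt_t), nrow(dt_n), nrow(clusters), proc.time()[3] - t0)

  regions <- predict_cluster_regions(points, clusters, model,
                                     tau = config$tau, bin = config$bin)
  counts$regions <- nrow(regions)
  say("[svbwt] %d breakpoint regions predicted (%.1fs)", nrow(regions),
      proc.time()[3] - t0)

  ridx_t <- build_read_index(c(tumor_reads$read1, tumor_reads$read2),
                             sample_label = "tumor")
  ridx_n <- build_read_index(c(normal_reads$read1, normal_reads$read2),
                             sample_label = "normal")
  say("[svbwt] read dictionaries built (%.1fs)", proc.time()[3] - t0)

  calls <- detect_breakpoints(regions, ridx_t, ridx_n, gidx, model,
                              config$scan)
  counts$calls <- nrow(calls)
  say("[svbwt] %d breakpoint calls (%.1fs)", nrow(calls),
      proc.time()[3] - t0)

  out <- list(calls = calls, regions = regions, clusters = clusters,
              points = points, model = model, gidx = gidx, config = config,
              counts = counts)
  if (!is.null(truth)) {
    out$evaluation <- evaluate_calls(calls, truth, tol = config$tol,
                                     regions = regions)
    say("[svbwt] sensitivity %.1f%%, false-detection rate %s",
        100 * out$evaluation$sensitivity,
        if (is.na(out$evaluation$fdr)) "n/a"
        else sprintf("%.2f%%", 100 * out$evaluation$fdr))
  }
  out
}

#' Evaluate calls against a truth set
#'
#' A truth junction is detected when some call matches both of its
#' coordinates within `tol` bp; a call is false when it matches no truth
#' junction. Region-level accounting (a truth junction is predicted when
#' some region's projections contain it, with `tol` slack) is reported
#' alongside.
#'
#' @param calls call table (see [detect_breakpoints()])
#' @param truth truth table with `x0`, `y0` columns
#' @param tol matching tolerance in bp (default 10)
#' @param regions optional region table for region-level accounting
#' @return list: `sensitivity`, `n_truth`, `n_detected`, `n_calls`,
#'   `n_false`, `fdr` (`NA` when there are no calls), `truth` (with
#'   `detected` flag), and optionally `region_sensitivity`
#' @export
evaluate_calls <- function(calls, truth, tol = 10L, regions = NULL) {
  truth <- copy(as.data.table(truth))
  detected <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(calls$x0 - truth$x0[i]) <= tol &
          abs(calls$y0 - truth$y0[i]) <= tol)
  }, logical(1))
  truth[, detected := detected]
  false_call <- if (nrow(calls) == 0) logical(0) else
    vapply(seq_len(nrow(calls)), function(i) {
      !any(abs(truth$x0 - calls$x0[i]) <= tol &
             abs(truth$y0 - calls$y0[i]) <= tol)
    }, logical(1))
  out <- list(sensitivity = mean(detected), n_truth = nrow(truth),
              n_detected = sum(detected), n_calls = nrow(calls),
              n_false = sum(false_call),
              fdr = if (nrow(calls) == 0) NA_real_ else mean(false_call),
              truth = truth)
  if (!is.null(regions) && nrow(regions) > 0) {
    pred <- vapply(seq_len(nrow(truth)), function(i) {
      any(truth$x0[i] >= regions$a_lo - tol &
            truth$x0[i] <= regions$a_hi + tol &
            truth$y0[i] >= regions$b_lo - tol &
            truth$y0[i] <= regions$b_hi + tol)
    }, logical(1))
    out$region_sensitivity <- mean(pred)
    out$n_region_predicted <- sum(pred)
  }
  out
}
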