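test_that("genome generation is reproducible with uniform composition", {
  g1 <- sim_genome(c(chr1 = 50000, chr2 = 30000), seed = 601)
  g2 <- sim_genome(c(chr1 = 50000, chr2 = 30000), seed = 601)
  expect_identical(g1, g2)
  expect_equal(sum(nchar(g1)), 80000)
  comp <- table(strsplit(paste(g1, collapse = ""), "")[[1]])
  # binomial bound: each base ~ Bin(n, 1/4)
  expect_true(all(abs(comp / 80000 - 0.25) < 4 * sqrt(0.25 * 0.75 / 80000)))
})

test_that("SNP injection follows the rate and logs exactly the changes", {
  g <- sim_genome(c(chr = 300000), seed = 602)
  expect_identical(add_snps(g, 0)$genome, g)
  res <- add_snps(g, 0.001, seed = 603)
  k <- nrow(res$log)
  expect_lt(abs(k - 300), 3 * sqrt(300) + 1)
  # the log equals the diff of the two sequences
  a <- strsplit(g[["chr"]], "")[[1]]
  b <- strsplit(res$genome[["chr"]], "")[[1]]
  diff_pos <- which(a != b) - 1L
  expect_equal(res$log$pos, diff_pos)
  expect_equal(res$log$ref, a[diff_pos + 1])
  expect_equal(res$log$alt, b[diff_pos + 1])
})

test_that("rearrangements follow the junction-counting convention", {
  g <- sim_genome(c(chr1 = 100000, chr2 = 100000), seed = 604)
  # one deletion of [s, t): a single junction joining s-1 to t
  rr <- apply_rearrangements(g, n_per_type = 1, len_range = c(500, 1000),
                             types = "deletion", seed = 605)
  expect_equal(nrow(rr$truth), 1)
  expect_equal(rr$truth$class, "del_like")
  del_len <- rr$truth$y0 - rr$truth$x0 - 1
  expect_equal(sum(nchar(rr$genome)), 200000 - del_len)

  # one inversion: two junctions, both inversion classes
  rr <- apply_rearrangements(g, n_per_type = 1, len_range = c(500, 1000),
                             types = "inversion", seed = 606)
  expect_equal(nrow(rr$truth), 2)
  expect_setequal(rr$truth$class, c("inv_pp", "inv_mm"))
  expect_equal(sum(nchar(rr$genome)), 200000)

  # per-type junction counts for the full six-type protocol
  g4 <- sim_genome(c(chr1 = 400000, chr2 = 400000), seed = 607)
  rr <- apply_rearrangements(g4, n_per_type = 3, len_range = c(300, 3000),
                             seed = 608)
  cnt <- rr$truth[, .N, by = type]
  expected <- c(insertion = 2L, deletion = 1L, inversion = 2L,
                tandem_dup = 1L, intra_trans = 3L, inter_trans = 3L) * 3L
  expect_equal(cnt$N[match(names(expected), cnt$type)],
               unname(expected))
  expect_true(all(rr$truth$x0 < rr$truth$y0))
})

test_that("read simulation respects coverage, inserts and error model", {
  g <- sim_genome(c(chr = 200000), seed = 609)
  reads <- sim_reads(g, coverage = 10, seed = 610)
  # coverage identity: 2 * 90 * n_pairs / len ~ 10
  expect_lt(abs(2 * 90 * nrow(reads) / 200000 - 10), 0.1)
  expect_true(all(nchar(reads$read1) == 90))

  # error rate 0: every read is an exact substring of genome or revcomp
  clean <- sim_reads(g, coverage = 0.5, error_rate = 0, seed = 611)
  idx <- build_genome_index(g)
  hits <- vapply(head(clean$read1, 200), function(r)
    count_occurrences(idx, r) >= 1, logical(1))
  hits2 <- vapply(head(clean$read2, 200), function(r)
    count_occurrences(idx, r) >= 1, logical(1))
  expect_true(all(hits) && all(hits2))

  # insert lengths encoded in read names: CLT bound on the sample mean
  il <- as.numeric(sub(".*_", "", reads$qname))
  expect_lt(abs(mean(il) - 760), 4 * 45 / sqrt(length(il)) + 0.5)
  expect_lt(abs(sd(il) - 45) / 45, 0.05)

  # reproducibility
  expect_identical(sim_reads(g, coverage = 1, seed = 612),
                   sim_reads(g, coverage = 1, seed = 612))
})

test_that("purity mixing gives the exact split", {
  g <- sim_genome(c(chr = 50000), seed = 613)
  t_reads <- sim_reads(g, coverage = 4, seed = 614, prefix = "t")
  p_reads <- sim_reads(g, coverage = 4, seed = 615, prefix = "p")
  expect_identical(mix_purity(t_reads, p_reads, 1, seed = 1)$qname %in%
                     t_reads$qname, rep(TRUE, nrow(t_reads)))
  expect_identical(mix_purity(t_reads, p_reads, 0, seed = 1)$qname %in%
                     p_reads$qname, rep(TRUE, nrow(t_reads)))
  mixed <- mix_purity(t_reads, p_reads, 0.2, seed = 616)
  expect_equal(nrow(mixed), nrow(t_reads))
  expect_equal(sum(startsWith(mixed$qname, "t_")),
               round(0.2 * nrow(t_reads)))
  expect_equal(anyDuplicated(mixed$qname), 0)
})

test_that("the internal mapper sets flags like a standard paired mapper", {
  set.seed(617)
  ref <- sim_genome(c(chr1 = 80000, chr2 = 80000), seed = 618)
  gidx <- build_genome_index(ref)

  # accordant error-free pair from the unrearranged genome: proper
  reads <- sim_reads(ref, coverage = 1, error_rate = 0, seed = 619)
  pairs <- map_read_pairs(gidx, reads)
  expect_gt(mean(pairs$proper), 0.98)
  expect_gt(mean(pairs$mapq1 == 60), 0.98)
  # template length recovers the simulated insert length
  il <- as.numeric(sub(".*_", "", reads$qname))
  ok <- pairs$proper
  expect_true(all(pairs$tlen[ok] == il[ok]))

  # a pair straddling a deletion: span too large, both ends MAPQ 60
  rr <- apply_rearrangements(ref, n_per_type = 1, len_range = c(3000, 4000),
                             types = "deletion", seed = 620)
  donor <- rr$genome
  cp <- global_to_chrom(gidx$gg, rr$truth$x0)
  # fragment crossing the junction in donor coordinates
  dpos <- cp$pos - 400  # 0-based donor == reference left of the junction
  frag <- substr(donor[[cp$chrom]], dpos + 1, dpos + 760)
  cross <- data.table::data.table(
    qname = "cross", read1 = substr(frag, 1, 90),
    read2 = revcomp(substr(frag, 671, 760)))
  pc <- map_read_pairs(gidx, cross)
  expect_false(pc$proper)
  expect_equal(pc$mapq1, 60L)
  expect_equal(pc$mapq2, 60L)

  # read of novel (non-genomic) sequence: unmapped
  set.seed(621)
  novel <- data.table::data.table(qname = "x", read1 = rand_seq(90),
                                  read2 = rand_seq(90))
  pn <- map_read_pairs(gidx, novel)
  expect_false(pn$mapped1)

  # a single mismatch in the seed is rescued
  r <- substr(ref[["chr1"]], 10001, 10090)
  substr(r, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                               substr(r, 15, 15))[1]
  pm <- map_read_pairs(gidx, data.table::data.table(
    qname = "m", read1 = r, read2 = revcomp(substr(ref[["chr1"]], 10601,
                                                   10690))))
  expect_true(pm$mapped1)
  expect_equal(pm$pos1, 10001L)
  expect_equal(pm$nm1, 1L)
})

test_that("FASTQ and SAM round-trips preserve the pair table", {
  g <- sim_genome(c(chr = 30000), seed = 622)
  reads <- sim_reads(g, coverage = 2, seed = 623)
  f1 <- tempfile(fileext = ".fq")
  f2 <- tempfile(fileext = ".fq")
  write_fastq(reads, f1, f2)
  back <- read_fastq(f1, f2)
  expect_equal(back$read1, reads$read1)
  expect_equal(back$read2, reads$read2)
  unlink(c(f1, f2))

  gidx <- build_genome_index(g)
  pairs <- map_read_pairs(gidx, reads[1:200])
  sam <- tempfile(fileext = ".sam")
  write_sam(pairs, gidx$gg, sam)
  back <- read_sam(sam, sample = "tumor")
  expect_equal(nrow(back), 200)
  data.table::setkey(back, qname)
  orig <- data.table::copy(pairs)
  data.table::setkey(orig, qname)
  expect_equal(back$pos1, orig$pos1)
  expect_equal(back$strand2, orig$strand2)
  expect_equal(back$proper, orig$proper)
  expect_equal(back$mapq1, orig$mapq1)
  unlink(sam)
})
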