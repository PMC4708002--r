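mk_pair <- function(chrom1 = "a", pos1 = 100L, strand1 = "+", mapq1 = 60L,
                    chrom2 = "a", pos2 = 800L, strand2 = "-", mapq2 = 60L,
                    proper = FALSE, mapped1 = TRUE, mapped2 = TRUE,
                    sample = "tumor") {
  data.table::data.table(qname = "q", chrom1 = chrom1, pos1 = pos1,
                         strand1 = strand1, mapq1 = mapq1, len1 = 90L,
                         mapped1 = mapped1, chrom2 = chrom2, pos2 = pos2,
                         strand2 = strand2, mapq2 = mapq2, len2 = 90L,
                         mapped2 = mapped2, proper = proper,
                         sample = sample)
}

test_that("discordant extraction applies the proper-pair and MAPQ rules", {
  expect_equal(nrow(extract_discordant(mk_pair(proper = TRUE))), 0)
  expect_equal(nrow(extract_discordant(mk_pair(chrom2 = "b"))), 1)
  expect_equal(nrow(extract_discordant(mk_pair(mapq1 = 29L))), 0)
  expect_equal(nrow(extract_discordant(mk_pair(mapq1 = 30L))), 1)
  expect_equal(nrow(extract_discordant(mk_pair(mapped2 = FALSE))), 0)
  # monotone in the threshold
  set.seed(301)
  many <- data.table::rbindlist(lapply(1:50, function(i)
    mk_pair(mapq1 = sample(0:60, 1), mapq2 = sample(0:60, 1))))
  n_prev <- Inf
  for (q in c(0, 20, 30, 50, 61)) {
    n <- nrow(extract_discordant(many, q))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("pairs map to points with x < y and strand-determined classes", {
  gg <- concatenate_genome(c(a = 10000L, b = 10000L))
  # ends at global 500 and 100 swap to (100, 500)
  p <- pairs_to_points(mk_pair(pos1 = 501L, strand1 = "-", pos2 = 101L,
                               strand2 = "+"), gg)
  # reverse-strand first base is the rightmost base: 500 + 89
  expect_equal(p$x, 100)
  expect_equal(p$y, 500 + 89)
  expect_true(all(pairs_to_points(data.table::rbindlist(
    lapply(1:5, function(i) mk_pair())), gg)$x <
      pairs_to_points(data.table::rbindlist(
        lapply(1:5, function(i) mk_pair())), gg)$y))
  expect_equal(orientation_class("+", "-"), "del_like")
  expect_equal(orientation_class("-", "+"), "dup_like")
  expect_equal(orientation_class("+", "+"), "inv_pp")
  expect_equal(orientation_class("-", "-"), "inv_mm")
})

test_that("mapped junction-spanning pairs land in the class's quadrant", {
  # forward-simulation consistency: build a donor genome with one junction
  # per class, sequence error-free pairs across it, map and check that the
  # discordant points sit in the predicted quadrant with the right class
  set.seed(302)
  ref <- sim_genome(c(chr1 = 120000, chr2 = 120000))
  gidx <- build_genome_index(ref)
  gg <- gidx$gg

  cases <- list(
    deletion = list(type = "deletion", class = "del_like"),
    tandem_dup = list(type = "tandem_dup", class = "dup_like"),
    inversion = list(type = "inversion", class = c("inv_pp", "inv_mm")))
  for (cs in cases) {
    rr <- apply_rearrangements(ref, n_per_type = 1,
                               len_range = c(2000, 4000),
                               types = cs$type, seed = 303)
    reads <- sim_reads(rr$genome, coverage = 8, error_rate = 0, seed = 304)
    pairs <- map_read_pairs(gidx, reads)
    disc <- extract_discordant(pairs)
    pts <- pairs_to_points(disc, gg)
    expect_gt(nrow(pts), 3)
    # every discordant point near a junction carries one of the truth
    # classes at that locus (an inversion's two junctions are 1 bp apart,
    # so both its classes co-occur in the window)
    for (k in seq_len(nrow(rr$truth))) {
      tr <- rr$truth[k]
      win <- pts[abs(x - tr$x0) < 1000 & abs(y - tr$y0) < 1000]
      expect_true(all(win$class %in% rr$truth$class))
      near <- win[class == tr$class]
      expect_gt(nrow(near), 1)
      d <- svbwt:::class_geometry(tr$class)$d
      expect_true(all(sign(near$x - tr$x0) == d[1]))
      expect_true(all(sign(near$y - tr$y0) == d[2]))
    }
  }
})

test_that("clustering refines to the fixed point and conserves points", {
  L <- 760
  p2 <- data.table::data.table(x = c(0, L - 1), y = c(0, L - 1),
                               class = "del_like", sample = "tumor")
  expect_equal(length(unique(cluster_points(p2, L)$cluster)), 1)
  p2b <- data.table::data.table(x = c(0, L + 1), y = c(0, 0),
                                class = "del_like", sample = "tumor")
  expect_equal(length(unique(cluster_points(p2b, L)$cluster)), 2)

  set.seed(305)
  # well-separated random clusters
  centers <- data.table::data.table(cx = runif(8, 0, 1e6),
                                    cy = runif(8, 2e6, 3e6))
  pts <- data.table::rbindlist(lapply(seq_len(nrow(centers)), function(i)
    data.table::data.table(
      x = centers$cx[i] + runif(25, 0, L / 2),
      y = centers$cy[i] + runif(25, 0, L / 2),
      class = "del_like",
      sample = sample(c("tumor", "normal"), 25, TRUE))))
  cl <- cluster_points(pts, L)
  expect_equal(nrow(cl), nrow(pts))  # conservation

  # equals single-linkage components under "both axis gaps < L"
  oracle <- sl_components(pts$x, pts$y, L)
  tab <- table(cl$cluster, oracle)
  expect_equal(sum(tab > 0), length(unique(cl$cluster)))
  expect_equal(length(unique(cl$cluster)), length(unique(oracle)))

  # permutation invariance: same partition up to label renaming,
  # checked via co-membership of random point pairs
  perm <- sample(nrow(pts))
  cl2 <- cluster_points(pts[perm], L)
  for (i in 1:50) {
    a <- sample(nrow(pts), 2)
    same1 <- cl$cluster[a[1]] == cl$cluster[a[2]]
    b1 <- which(perm == a[1])
    b2 <- which(perm == a[2])
    same2 <- cl2$cluster[b1] == cl2$cluster[b2]
    expect_equal(same1, same2)
  }
})

test_that("the 90% rule separates somatic from germline clusters", {
  expect_true(label_somatic(10 / 10))
  expect_true(label_somatic(9 / 10))
  expect_false(label_somatic(8 / 10))
  pts <- data.table::data.table(
    x = rep(c(0, 1e5), c(10, 10)), y = rep(c(5e5, 9e5), c(10, 10)),
    class = "del_like",
    sample = c(rep("tumor", 9), "normal", rep("tumor", 8), rep("normal", 2)))
  cl <- cluster_points(pts, 760)
  cs <- summarize_clusters(cl)
  expect_equal(sort(cs$somatic), c(FALSE, TRUE))
})
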