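#' Extract discordant pairs from an alignment pair table
#'
#' A pair is kept when both ends are mapped as primary alignments, the
#' proper-pair condition (inward orientation at about one insert length,
#' as flagged by the mapper) is violated, and the smaller of the two
#' mapping qualities is at least `mapq_min`: only unambiguous placements
#' are trusted.
#'
#' @param pairs a pair `data.table` as produced by [map_read_pairs()] or
#'   [read_sam()] (columns `chrom1/2`, `pos1/2`, `strand1/2`, `mapq1/2`,
#'   `len1/2`, `mapped1/2`, `proper`, `sample`)
#' @param mapq_min minimum Phred-scaled mapping quality per end
#'   (default 30)
#' @return the filtered pair table, with attribute `n_skipped`
#' @export
extract_discordant <- function(pairs, mapq_min = 30L) {
  keep <- pairs$mapped1 & pairs$mapped2 & !pairs$proper &
    pmin(pairs$mapq1, pairs$mapq2) >= mapq_min
  out <- pairs[keep]
  setattr(out, "n_skipped", sum(!keep))
  out
}

#' Map discordant pairs to points in the plane of global coordinates
#'
#' Each pair becomes a point `(x, y)` where `x` and `y` are the global
#' coordinates of the first sequenced bases of the two reads (for a
#' reverse-strand read, its rightmost reference base) and `x < y` by
#' swapping. The orientation class is determined by the two strands after
#' the swap and fixes the junction geometry the pair supports:
#'
#' * `del_like`  (`+`,`-`): pair flanks the junction from outside
#' * `dup_like`  (`-`,`+`): both ends between the two breakpoints
#' * `inv_pp`    (`+`,`+`): inversion-type, both reads forward
#' * `inv_mm`    (`-`,`-`): inversion-type, both reads reverse
#'
#' @param pairs discordant pair table (see [extract_discordant()])
#' @param gg a `global_genome`
#' @return `data.table` with columns `x`, `y`, `class`, `sample`
#' @export
pairs_to_points <- function(pairs, gg) {
  if (nrow(pairs) == 0)
    return(data.table(x = numeric(0), y = numeric(0),
                      class = character(0), sample = character(0)))
  fb1 <- ifelse(pairs$strand1 == "+", pairs$pos1 - 1,
                pairs$pos1 - 1 + pairs$len1 - 1)
  fb2 <- ifelse(pairs$strand2 == "+", pairs$pos2 - 1,
                pairs$pos2 - 1 + pairs$len2 - 1)
  g1 <- chrom_to_global(gg, pairs$chrom1, fb1)
  g2 <- chrom_to_global(gg, pairs$chrom2, fb2)
  swap <- g1 > g2
  x <- ifelse(swap, g2, g1)
  y <- ifelse(swap, g1, g2)
  sx <- ifelse(swap, pairs$strand2, pairs$strand1)
  sy <- ifelse(swap, pairs$strand1, pairs$strand2)
  cls <- orientation_class(sx, sy)
  data.table(x = x, y = y, class = cls, sample = pairs$sample)
}

# strand pair (after the x < y swap) -> orientation class
orientation_class <- function(strand_x, strand_y) {
  key <- paste0(strand_x, strand_y)
  map <- c("+-" = "del_like", "-+" = "dup_like",
           "++" = "inv_pp", "--" = "inv_mm")
  unname(map[key])
}

# displacement direction (unit vector) from a breakpoint towards its
# discordant pairs, and the diffusion direction of the insert spread
class_geometry <- function(class) {
  switch(class,
    del_like = list(d = c(-1L, 1L), antidiag = FALSE),
    dup_like = list(d = c(1L, -1L), antidiag = FALSE),
    inv_pp   = list(d = c(-1L, -1L), antidiag = TRUE),
    inv_mm   = list(d = c(1L, 1L), antidiag = TRUE),
    stop("unknown orientation class: ", class))
}

#' Cluster discordant points by alternating sort-partition refinement
#'
#' Points of one orientation class (tumor and normal pooled) are sorted by
#' the first coordinate and split wherever consecutive coordinates differ
#' by at least the insert length; each group is then re-sorted and split
#' on the second coordinate, and the two steps alternate until the
#' partition stops changing. Points associated with the same breakpoint
#' fall within an insert length of each other and end up in one cluster.
#'
#' @param points `data.table` from [pairs_to_points()]
#' @param insert_len clustering distance: the mean insert length (bp)
#' @return the input with an integer `cluster` column added (cluster ids
#'   are unique across classes)
#' @export
cluster_points <- function(points, insert_len) {
  points <- copy(points)
  if (nrow(points) == 0) {
    points[, cluster := integer(0)]
    return(points)
  }
  refine <- function(cl, v, L) {
    ord <- order(cl, v)
    cls <- cl[ord]
    vs <- v[ord]
    brk <- c(TRUE, diff(vs) >= L | cls[-1] != cls[-length(cls)])
    out <- integer(length(cl))
    out[ord] <- cumsum(brk)
    out
  }
  base <- match(points$class, sort(unique(points$class)))
  cl <- base
  repeat {
    cl2 <- refine(cl, points$x, insert_len)
    cl2 <- refine(cl2, points$y, insert_len)
    if (identical(cl2, cl)) break
    cl <- cl2
  }
  points[, cluster := cl]
  points[]
}

#' Summarize clusters and label them somatic or germline
#'
#' A cluster is somatic when the fraction of its discordant pairs coming
#' from the tumor sample is at least `tumor_rate` (default 90%); germline
#' breakpoints recruit pairs from both samples.
#'
#' @param points clustered points (see [cluster_points()])
#' @param tumor_rate somatic threshold on the tumor fraction
#' @param min_support minimum pairs per cluster retained (default 3)
#' @return `data.table`, one row per retained cluster: `cluster`, `class`,
#'   `n`, `n_tumor`, `n_normal`, `tumor_fraction`, `somatic`, bounding box
#'   `xmin/xmax/ymin/ymax`
#' @export
summarize_clusters <- function(points, tumor_rate = 0.9, min_support = 3L) {
  if (nrow(points) == 0)
    return(data.table(cluster = integer(0), class = character(0),
                      n = integer(0), n_tumor = integer(0),
                      n_normal = integer(0), tumor_fraction = numeric(0),
                      somatic = logical(0), xmin = numeric(0),
                      xmax = numeric(0), ymin = numeric(0),
                      ymax = numeric(0)))
  cs <- points[, .(class = class[1], n = .N,
                   n_tumor = sum(sample == "tumor"),
                   n_normal = sum(sample == "normal"),
                   xmin = min(x), xmax = max(x),
                   ymin = min(y), ymax = max(y)),
               by = cluster]
  cs[, tumor_fraction := n_tumor / n]
  cs[, somatic := label_somatic(tumor_fraction, tumor_rate)]
  cs[n >= min_support][order(cluster)]
}

#' Somatic/germline decision for a cluster
#' @param tumor_fraction fraction of the cluster's pairs from the tumor
#' @param tumor_rate threshold (default 0.9)
#' @return logical: `TRUE` = somatic, `FALSE` = germline
#' @export
label_somatic <- function(tumor_fraction, tumor_rate = 0.9) {
  tumor_fraction >= tumor_rate
}
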