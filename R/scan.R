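#' Scan parameters
#'
#' Tunables of the breakpoint scan. `low_thresh`/`high_thresh` are on
#' normalized edit distances (edit distance divided by extension length):
#' a branch "matches" a region below `low_thresh` and "does not match"
#' above `high_thresh`. `margin` extends the scan beyond the predicted
#' projection (defaults to one insert length, mirroring the prediction
#' uncertainty); `min_branch_len` is the shortest extension accepted as
#' junction evidence.
#'
#' @param alpha anchor-query slack over the MLU (default 3)
#' @param ext_len maximum leftward extension length e (default 20)
#' @param min_support minimum supporting extensions for a call (default 2)
#' @param low_thresh normalized distance below which an extension matches
#'   a region (default 0.1)
#' @param high_thresh normalized distance above which it does not
#'   (default 0.3)
#' @param margin scan extension beyond the projection, bp (default:
#'   insert mean)
#' @param min_branch_len minimum extension length for junction evidence
#'   (default 14: short enough that low-coverage junction reads still
#'   qualify, long enough that a one-edit chance match against a
#'   kilobase of partner sequence is rare)
#' @param min_positions minimum number of scan positions a candidate run
#'   must span (default 2): a real junction supports candidate branches
#'   at every position within `low_thresh * ext_len` bases of it, while
#'   chance partner matches of short branches are isolated
#' @param own_pad local reference-context padding for the own-region
#'   distance (default 8)
#' @return list of class `scan_params`
#' @export
scan_params <- function(alpha = 3L, ext_len = 20L, min_support = 2L,
                        low_thresh = 0.1, high_thresh = 0.3, margin = NULL,
                        min_branch_len = 14L, min_positions = 2L,
                        own_pad = 8L) {
  stopifnot(low_thresh >= 0, low_thresh < high_thresh, high_thresh <= 1,
            ext_len >= 10)
  structure(list(alpha = as.integer(alpha), ext_len = as.integer(ext_len),
                 min_support = as.integer(min_support),
                 low_thresh = low_thresh, high_thresh = high_thresh,
                 margin = margin, min_branch_len = as.integer(min_branch_len),
                 min_positions = as.integer(min_positions),
                 own_pad = as.integer(own_pad)),
            class = "scan_params")
}

#' Minimum semi-global edit distance
#'
#' The minimum, over all substrings `t` of `text`, of the edit distance
#' between `pattern` and `t` (pattern fully consumed, text ends free),
#' computed with a bit-parallel dynamic program.
#'
#' @param pattern,text non-empty strings
#' @return integer distance
#' @export
min_edit_distance <- function(pattern, text) {
  stopifnot(nchar(pattern) >= 1, nchar(text) >= 1)
  min_edit_distance_cpp(pattern, text)$distance
}

# scan passes per orientation class: each junction adjacency is crossed by
# leftward extensions in exactly two pass geometries (one per side), which
# realizes the "repeat with A and B swapped" confirmation.
# orient: "+" scans the forward genome sequence right to left; "-" scans
# the reverse-complement strand entry right to left. expected: partner
# strand on which the crossing extension should align.
region_passes <- function(class) {
  switch(class,
    del_like = list(list(side = "A", orient = "-", expected = "-"),
                    list(side = "B", orient = "+", expected = "+")),
    dup_like = list(list(side = "A", orient = "+", expected = "+"),
                    list(side = "B", orient = "-", expected = "-")),
    inv_pp   = list(list(side = "A", orient = "-", expected = "+"),
                    list(side = "B", orient = "-", expected = "+")),
    inv_mm   = list(list(side = "A", orient = "+", expected = "-"),
                    list(side = "B", orient = "+", expected = "-")),
    stop("unknown orientation class: ", class))
}

#' Scan a predicted breakpoint region against read dictionaries
#'
#' For each scan position (right to left over the scanned side extended by
#' `margin`), the unique anchor query of length MLU+(x) + alpha is looked
#' up in the read index by backward search; all leftward extensions up to
#' `ext_len` bases are enumerated with their support, and each extension
#' is scored by normalized minimum edit distance against its local
#' reference context and against both strands of the partner region
#' sequence. The result is the multivalued edit-distance profile of the
#' region, per pass and per sample.
#'
#' @param region one region row (see [predict_cluster_regions()])
#' @param ridx_tumor,ridx_normal `read_index` objects (normal may be
#'   `NULL`)
#' @param gidx a `genome_index`
#' @param model an `insert_model`
#' @param params a [scan_params()] object
#' @return list of passes; each pass is a list with `meta` (side, orient,
#'   expected partner strand, scan direction) and per-sample profile
#'   `data.table`s (`g`, `extension`, `support`, `d_own`, `d_partner`,
#'   `partner_strand`, `partner_g`) plus query-coverage vectors
#' @export
scan_region <- function(region, ridx_tumor, ridx_normal, gidx, model,
                        params = scan_params()) {
  margin <- if (is.null(params$margin)) round(model$mean) else params$margin
  partner_pad <- params$ext_len + params$alpha + ceiling(4 * model$sd)
  passes <- region_passes(region$class)

  side_interval <- function(side) {
    if (side == "A") c(region$a_lo, region$a_hi) else
      c(region$b_lo, region$b_hi)
  }

  out <- vector("list", length(passes))
  for (pi in seq_along(passes)) {
    p <- passes[[pi]]
    iv <- side_interval(p$side)
    piv <- side_interval(if (p$side == "A") "B" else "A")

    # clip the scan window to the chromosome of the projection midpoint
    mid <- global_to_chrom(gidx$gg, floor((iv[1] + iv[2]) / 2))
    off <- gidx$gg$offsets[[mid$chrom]]
    clen <- gidx$gg$lengths[[mid$chrom]]
    g_lo <- max(off, iv[1] - margin)
    g_hi <- min(off + clen - 1, iv[2] + margin)
    g <- seq(g_lo, g_hi)
    if (p$orient == "+") g <- rev(g)  # right-to-left in scan orientation
    tp <- global_to_text(gidx, g, strand = p$orient)

    qlen <- rep(NA_integer_, length(tp))
    ok <- !is.na(tp)
    if (any(ok)) {
      m <- gidx$mlu[tp[ok] + 1L]
      q <- m + params$alpha
      k <- findInterval(tp[ok], gidx$segments$text_start)
      within <- tp[ok] - gidx$segments$text_start[k]
      q[!is.na(q) & within + q > gidx$segments$len[k]] <- NA_integer_
      qlen[ok] <- as.integer(q)
    }
    tpi <- ifelse(is.na(tp), -1L, as.integer(tp))

    # partner sequences, padded so junction-proximal extensions align
    pm <- global_to_chrom(gidx$gg, floor((piv[1] + piv[2]) / 2))
    ps <- genome_slice(gidx, pm$chrom,
                       piv[1] - gidx$gg$offsets[[pm$chrom]] - partner_pad,
                       piv[2] - gidx$gg$offsets[[pm$chrom]] + partner_pad + 1)
    pf_start_g <- gidx$gg$offsets[[pm$chrom]] + ps$start0
    pf_end_g <- pf_start_g + nchar(ps$seq) - 1
    pfwd <- code_seq(ps$seq)
    prc <- code_seq(revcomp(ps$seq))

    run_sample <- function(ridx) {
      if (is.null(ridx)) return(NULL)
      res <- scan_pass_cpp(ridx$bwt, ridx$C, ridx$occ, gidx$text,
                           tpi, qlen, pfwd, prc,
                           params$ext_len, params$own_pad, emit_ends = TRUE)
      br <- as.data.table(res$branches)
      if (nrow(br) > 0) {
        br[, g := g[match(pos, tpi)]]
        br[, len := nchar(extension)]
        use_fwd <- br$d_partner_fwd <= br$d_partner_rc
        br[, d_partner := ifelse(use_fwd, d_partner_fwd, d_partner_rc)]
        br[, partner_strand := ifelse(use_fwd, "+", "-")]
        br[, partner_g := ifelse(use_fwd,
                                 pf_start_g + end_fwd - 1,
                                 pf_end_g - (end_rc - 1))]
      } else {
        br[, c("g", "len", "d_partner", "partner_strand", "partner_g") :=
             list(numeric(0), integer(0), numeric(0), character(0),
                  numeric(0))]
      }
      list(profile = br, query_count = res$query_count, g = g)
    }

    out[[pi]] <- list(
      meta = list(side = p$side, orient = p$orient, expected = p$expected,
                  dir = if (p$orient == "+") -1L else 1L,
                  class = region$class),
      tumor = run_sample(ridx_tumor),
      normal = run_sample(ridx_normal))
  }
  out
}

#' Detect drastic branch changes in one edit-distance profile
#'
#' A junction announces itself as a supported extension branch whose
#' distance to the partner region is near zero while its distance to the
#' scanned region's own sequence is large (the branch has departed from
#' the reference band, which grows linearly as the scan approaches the
#' junction). Maximal runs of such scan positions are reduced to one
#' breakpoint each: the position whose branch aligns the partner best,
#' ties broken towards the deepest scanned position. The partner
#' coordinate is the branch's best alignment end in the partner region.
#'
#' @param profile one pass/sample profile `data.table` (see
#'   [scan_region()])
#' @param params a [scan_params()] object
#' @param dir scan direction: -1 when deeper means smaller coordinate
#' @param min_support override of `params$min_support`
#' @param min_positions override of `params$min_positions`
#' @return `data.table`: `g0` (scan-side breakpoint, global 0-based),
#'   `partner_g`, `partner_strand`, `support`, `n_positions`
#' @export
detect_branch_change <- function(profile, params = scan_params(), dir = -1L,
                                 min_support = NULL, min_positions = NULL) {
  ms <- if (is.null(min_support)) params$min_support else min_support
  mp <- if (is.null(min_positions)) params$min_positions else min_positions
  empty <- data.table(g0 = numeric(0), partner_g = numeric(0),
                      partner_strand = character(0), support = integer(0),
                      n_positions = integer(0))
  if (is.null(profile) || nrow(profile) == 0) return(empty)
  cand <- profile[support >= ms & len >= params$min_branch_len &
                    d_partner < params$low_thresh &
                    d_own > params$high_thresh]
  if (nrow(cand) == 0) return(empty)
  setorder(cand, g)
  run_id <- cumsum(c(1, diff(cand$g) > 3))
  cand[, run := run_id]
  calls <- cand[, {
    best <- which(d_partner == min(d_partner))
    pick <- if (dir < 0) best[which.min(g[best])] else best[which.max(g[best])]
    .(g0 = g[pick], partner_g = partner_g[pick],
      partner_strand = partner_strand[pick],
      support = max(support), n_positions = length(unique(g)))
  }, by = run]
  calls[, run := NULL]
  calls[n_positions >= mp][]
}

#' Confirm calls across swapped scans and assign somatic status
#'
#' Combines the calls of a region's two scan passes (the scanned-side
#' coordinate of each pass is the precise breakpoint on that side);
#' calls agreeing within 2 x alpha on both coordinates are merged and
#' flagged as confirmed by the swapped scan. A call is somatic when the
#' normal sample's profiles show no junction branch (at any support) at
#' the same locus.
#'
#' @param region the region row the passes belong to
#' @param passes output of [scan_region()]
#' @param params a [scan_params()] object
#' @return `data.table` of breakpoint calls: `x0`, `y0` (global 0-based,
#'   `x0 < y0`), `class`, `somatic`, `support`, `confirmed`,
#'   `strand_agrees`
#' @export
confirm_and_type <- function(region, passes, params = scan_params()) {
  per_pass <- lapply(passes, function(p) {
    calls <- detect_branch_change(p$tumor$profile, params, p$meta$dir)
    if (nrow(calls) == 0) return(calls[, .(x0 = numeric(0), y0 = numeric(0),
                                           support = integer(0),
                                           strand_agrees = logical(0),
                                           side = character(0))])
    x0 <- if (p$meta$side == "A") calls$g0 else calls$partner_g
    y0 <- if (p$meta$side == "A") calls$partner_g else calls$g0
    # a short rearrangement's scan window can cover both breakpoint ends,
    # so a pass may detect the junction from the other side; enforce the
    # x0 < y0 convention so such calls merge with their mirror image
    swap <- x0 > y0
    tmp <- x0[swap]
    x0[swap] <- y0[swap]
    y0[swap] <- tmp
    data.table(x0 = x0, y0 = y0, support = calls$support,
               strand_agrees = calls$partner_strand == p$meta$expected,
               side = p$meta$side)
  })
  normal_calls <- rbindlist(lapply(passes, function(p) {
    nc <- detect_branch_change(p$normal$profile, params, p$meta$dir,
                               min_support = 1L, min_positions = 1L)
    if (nrow(nc) == 0)
      return(data.table(x0 = numeric(0), y0 = numeric(0)))
    if (p$meta$side == "A") data.table(x0 = nc$g0, y0 = nc$partner_g)
    else data.table(x0 = nc$partner_g, y0 = nc$g0)
  }))

  tol <- 2 * params$alpha
  c1 <- per_pass[[1]]
  c2 <- per_pass[[2]]
  used2 <- rep(FALSE, nrow(c2))
  rows <- list()
  for (i in seq_len(nrow(c1))) {
    j <- which(!used2 & abs(c2$x0 - c1$x0[i]) <= tol &
                 abs(c2$y0 - c1$y0[i]) <= tol)
    if (length(j) > 0) {
      j <- j[1]
      used2[j] <- TRUE
      # take each coordinate from the pass that scanned that side
      x0 <- if (c1$side[i] == "A") c1$x0[i] else c2$x0[j]
      y0 <- if (c1$side[i] == "B") c1$y0[i] else c2$y0[j]
      rows[[length(rows) + 1]] <- data.table(
        x0 = x0, y0 = y0, support = max(c1$support[i], c2$support[j]),
        confirmed = TRUE,
        strand_agrees = c1$strand_agrees[i] && c2$strand_agrees[j])
    } else {
      rows[[length(rows) + 1]] <- data.table(
        x0 = c1$x0[i], y0 = c1$y0[i], support = c1$support[i],
        confirmed = FALSE, strand_agrees = c1$strand_agrees[i])
    }
  }
  for (j in which(!used2)) {
    rows[[length(rows) + 1]] <- data.table(
      x0 = c2$x0[j], y0 = c2$y0[j], support = c2$support[j],
      confirmed = FALSE, strand_agrees = c2$strand_agrees[j])
  }
  if (length(rows) == 0)
    return(data.table(x0 = numeric(0), y0 = numeric(0), class = character(0),
                      somatic = logical(0), support = integer(0),
                      confirmed = logical(0), strand_agrees = logical(0)))
  calls <- rbindlist(rows)
  calls[, class := region$class]
  calls[, somatic := TRUE]
  if (nrow(normal_calls) > 0) {
    for (i in seq_len(nrow(calls))) {
      hit <- abs(normal_calls$x0 - calls$x0[i]) <= 5 &
        abs(normal_calls$y0 - calls$y0[i]) <= 5
      if (any(hit)) calls[i, somatic := FALSE]
    }
  }
  setcolorder(calls, c("x0", "y0", "class", "somatic", "support",
                       "confirmed", "strand_agrees"))
  calls[]
}

#' Detect breakpoints across all predicted regions
#'
#' Runs [scan_region()] and [confirm_and_type()] over every region and
#' deduplicates calls supported by overlapping regions.
#'
#' @param regions region table (see [predict_cluster_regions()])
#' @param ridx_tumor,ridx_normal read indexes
#' @param gidx a `genome_index`
#' @param model an `insert_model`
#' @param params a [scan_params()] object
#' @return call `data.table` (see [confirm_and_type()]), one row per
#'   distinct junction
#' @export
detect_breakpoints <- function(regions, ridx_tumor, ridx_normal, gidx,
                               model, params = scan_params()) {
  empty <- data.table(x0 = numeric(0), y0 = numeric(0), class = character(0),
                      somatic = logical(0), support = integer(0),
                      confirmed = logical(0), strand_agrees = logical(0))
  if (nrow(regions) == 0) return(empty)
  all_calls <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    passes <- scan_region(regions[i], ridx_tumor, ridx_normal, gidx, model,
                          params)
    all_calls[[i]] <- confirm_and_type(regions[i], passes, params)
  }
  calls <- rbindlist(all_calls)
  if (nrow(calls) == 0) return(empty)
  setorder(calls, class, x0, y0, -support)
  # deduplicate: same class and both coordinates within 5 bp
  keep <- rep(TRUE, nrow(calls))
  merged <- calls
  grp <- integer(nrow(merged))
  gid <- 0
  for (i in seq_len(nrow(merged))) {
    if (grp[i] != 0) next
    gid <- gid + 1
    grp[i] <- gid
    same <- merged$class == merged$class[i] &
      abs(merged$x0 - merged$x0[i]) <= 5 &
      abs(merged$y0 - merged$y0[i]) <= 5 & grp == 0
    grp[same] <- gid
  }
  merged[, grp := grp]
  out <- merged[, .(x0 = x0[which.max(support)][1],
                    y0 = y0[which.max(support)][1],
                    class = class[1],
                    somatic = all(somatic),
                    support = max(support),
                    confirmed = any(confirmed),
                    strand_agrees = any(strand_agrees)), by = grp]
  out[, grp := NULL]
  setorder(out, x0, y0)
  out[]
}
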