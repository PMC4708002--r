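#' Concatenate chromosomes into a single global coordinate system
#'
#' All chromosome sequences are conceptually concatenated, separated by a
#' single '$' symbol, so that every base of every chromosome has one
#' global coordinate and all positions are mutually comparable. Global
#' coordinates are 0-based; separators occupy one coordinate each and
#' never fall inside a chromosome's range.
#'
#' @param seqs named character vector (or `DNAStringSet`) of chromosome
#'   sequences, or a named integer vector of chromosome lengths
#' @return an object of class `global_genome` with `names`, `lengths`,
#'   `offsets` (global start of each chromosome) and `total_length`
#' @export
concatenate_genome <- function(seqs) {
  if (is.numeric(seqs)) {
    lens <- as.integer(seqs)
    nms <- names(seqs)
  } else {
    nms <- names(seqs)
    seqs <- as.character(seqs)
    lens <- nchar(seqs)
  }
  if (is.null(nms) || anyNA(nms) || any(nms == ""))
    stop("chromosomes must be named")
  if (anyDuplicated(nms)) stop("duplicate chromosome names")
  offsets <- cumsum(c(0, head(lens + 1, -1)))  # +1 for each separator
  structure(
    list(names = nms, lengths = setNames(lens, nms),
         offsets = setNames(as.numeric(offsets), nms),
         total_length = sum(lens) + length(lens) - 1L),
    class = "global_genome")
}

#' Convert chromosome coordinates to global coordinates
#' @param gg a `global_genome`
#' @param chrom chromosome names (recycled with `pos`)
#' @param pos 0-based positions within the chromosome
#' @return numeric global 0-based coordinates
#' @export
chrom_to_global <- function(gg, chrom, pos) {
  off <- gg$offsets[chrom]
  if (anyNA(off)) stop("unknown chromosome")
  len <- gg$lengths[chrom]
  if (any(pos < 0 | pos >= len)) stop("position outside chromosome")
  unname(off + pos)
}

#' Convert global coordinates back to chromosome coordinates
#' @param gg a `global_genome`
#' @param g global 0-based coordinates
#' @return `data.frame` with columns `chrom`, `pos` (0-based)
#' @export
global_to_chrom <- function(gg, g) {
  idx <- findInterval(g, gg$offsets)
  bad <- idx < 1 | g > gg$total_length
  chrom <- gg$names[idx]
  pos <- g - gg$offsets[idx]
  sep <- pos >= gg$lengths[idx]  # separator coordinate
  chrom[bad | sep] <- NA
  pos[bad | sep] <- NA
  data.frame(chrom = unname(chrom), pos = unname(pos),
             stringsAsFactors = FALSE)
}

#' Build a genome index: FM-index, suffix array and uniqueness lengths
#'
#' Indexes both strands of the reference: every chromosome (split at runs
#' of N, which cannot be matched exactly against reads) contributes a
#' forward entry and a reverse-complement entry to one suffix array, so
#' substring counts over the index are counts over both strands. From the
#' suffix array's LCP structure the index stores, for every position, the
#' minimum length for uniqueness (MLU): the length of the shortest
#' subsequence starting there, extending rightward, that occurs exactly
#' once in both strands of the genome. Positions whose unique subsequence
#' would run past the containing segment are marked undefined.
#'
#' @param seqs named character vector (or `DNAStringSet`) of chromosome
#'   sequences over A,C,G,T,N
#' @return an object of class `genome_index`
#' @export
build_genome_index <- function(seqs) {
  seqs <- setNames(toupper(as.character(seqs)), names(seqs))
  gg <- concatenate_genome(seqs)
  if (!all(grepl("^[ACGTN]*$", seqs))) stop("sequences must be over ACGTN")

  # segment = maximal N-free run of one chromosome
  seg <- list()
  for (ch in gg$names) {
    m <- gregexpr("[ACGT]+", seqs[[ch]])[[1]]
    if (m[1] == -1) next
    seg[[ch]] <- data.table(chrom = ch,
                            seg_start = as.integer(m) - 1L,
                            len = attr(m, "match.length"))
  }
  segs_f <- rbindlist(seg)
  if (nrow(segs_f) == 0) stop("genome contains no ACGT sequence")
  segs_f[, strand := "+"]
  segs_r <- copy(segs_f)[, strand := "-"]
  segs <- rbind(segs_f, segs_r)

  entries <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- substr(seqs[[segs$chrom[i]]], segs$seg_start[i] + 1L,
                segs$seg_start[i] + segs$len[i])
    entries[i] <- if (segs$strand[i] == "+") s else revcomp(s)
  }
  segs[, text_start := cumsum(c(0, head(len + 1L, -1)))]

  fm <- fm_build_cpp(entries, keep_sa = TRUE, compute_mlu = TRUE)

  # mask undefined MLUs: separator coordinates, and positions whose
  # unique subsequence would cross the segment end
  mlu <- fm$mlu
  pos_in_entry <- sequence(segs$len + 1L) - 1L
  entry_len <- rep(segs$len, segs$len + 1L)
  undef <- pos_in_entry >= entry_len |
    pos_in_entry + mlu > entry_len
  mlu[undef] <- NA_integer_

  structure(
    list(bwt = fm$bwt, C = fm$C, occ = fm$occ, n = fm$n,
         n_entries = fm$n_entries, sa = fm$sa, text = fm$text,
         mlu = mlu, segments = segs, gg = gg, seqs = seqs),
    class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf(
    "<genome_index> %d chromosome(s), %.0f bp (+ reverse strand), %d segment entries\n",
    length(x$gg$names), sum(x$gg$lengths), x$n_entries))
  invisible(x)
}

# --- coordinate plumbing ------------------------------------------------

# text position (0-based) of a forward-strand global coordinate, or of the
# reverse-strand entry covering it; NA inside N runs
global_to_text <- function(gidx, g, strand = "+") {
  cp <- global_to_chrom(gidx$gg, g)
  want <- strand
  segs <- gidx$segments[gidx$segments$strand %in% want]
  out <- rep(NA_real_, length(g))
  for (ch in unique(cp$chrom[!is.na(cp$chrom)])) {
    ii <- which(!is.na(cp$chrom) & cp$chrom == ch)
    sc <- segs[segs$chrom == ch]
    k <- findInterval(cp$pos[ii], sc$seg_start)
    ok <- k >= 1
    kk <- pmax(k, 1L)
    within <- cp$pos[ii] - sc$seg_start[kk]
    ok <- ok & within < sc$len[kk]
    tp <- ifelse(sc$strand[kk] == "+",
                 sc$text_start[kk] + within,
                 sc$text_start[kk] + sc$len[kk] - 1 - within)
    out[ii] <- ifelse(ok, tp, NA_real_)
  }
  out
}

# inverse: 0-based text position -> (chrom, pos0, strand); separators NA
text_to_global <- function(gidx, tp) {
  segs <- gidx$segments
  k <- findInterval(tp, segs$text_start)
  within <- tp - segs$text_start[k]
  sep <- within >= segs$len[k]
  pos <- ifelse(segs$strand[k] == "+",
                segs$seg_start[k] + within,
                segs$seg_start[k] + segs$len[k] - 1 - within)
  g <- gidx$gg$offsets[segs$chrom[k]] + pos
  g[sep] <- NA
  data.frame(g = unname(g), strand = segs$strand[k],
             chrom = segs$chrom[k], stringsAsFactors = FALSE)
}

#' Minimum length for uniqueness at forward-strand positions
#'
#' @param gidx a `genome_index`
#' @param x global 0-based coordinates (forward strand)
#' @return integer MLU values; `NA` where undefined (inside N runs, at
#'   separators, or where no rightward extension within the segment is
#'   unique)
#' @export
mlu_plus <- function(gidx, x) {
  tp <- global_to_text(gidx, x, strand = "+")
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(tp)
  out[ok] <- gidx$mlu[tp[ok] + 1L]
  out
}

#' Full MLU table over the global coordinate range
#'
#' @param gidx a `genome_index`
#' @return integer vector of length `total_length`; `NA` at separator
#'   coordinates and undefined positions
#' @export
compute_mlu_plus <- function(gidx) {
  mlu_plus(gidx, seq_len(gidx$gg$total_length) - 1)
}

#' Extract a unique anchor query at a genome position
#'
#' The query is the genomic subsequence of length `MLU+(x) + alpha` with
#' its left end at `x`; by construction it occurs exactly once in both
#' strands of the genome, and the `alpha` slack keeps spurious dictionary
#' hits out. Returns `NA` (a skip signal for the scanner) where the MLU is
#' undefined or the window would cross a segment boundary.
#'
#' @param gidx a `genome_index`
#' @param x global 0-based coordinate (forward strand), scalar
#' @param alpha query slack in bases (default 3)
#' @return the query string, or `NA_character_`
#' @export
make_window_query <- function(gidx, x, alpha = 3L) {
  m <- mlu_plus(gidx, x)
  if (is.na(m)) return(NA_character_)
  qlen <- m + alpha
  cp <- global_to_chrom(gidx$gg, x)
  s <- substr(gidx$seqs[[cp$chrom]], cp$pos + 1L, cp$pos + qlen)
  if (nchar(s) < qlen || !is_acgt(s)) return(NA_character_)
  # the slack may not cross the segment end
  if (fm_count_cpp(gidx$bwt, gidx$C, gidx$occ, s) < 1) return(NA_character_)
  s
}

# genome slice helper, clipped to the chromosome (0-based half-open)
genome_slice <- function(gidx, chrom, start0, end0) {
  len <- gidx$gg$lengths[[chrom]]
  a <- max(0, start0)
  b <- min(len, end0)
  if (b <= a) return(list(seq = "", start0 = a))
  list(seq = substr(gidx$seqs[[chrom]], a + 1, b), start0 = a)
}
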