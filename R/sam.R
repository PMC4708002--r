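#' Write a pair table as SAM
#'
#' Emits two primary records per pair with standard flags (paired,
#' proper-pair, strand, mate fields, TLEN); mapped records get a
#' full-length match CIGAR. Sequences are written when the table carries
#' `read1`/`read2` columns, `*` otherwise.
#'
#' @param pairs pair `data.table` (see [map_read_pairs()])
#' @param gg `global_genome` providing the `@SQ` header lines
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sam <- function(pairs, gg, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", gg$names, gg$lengths))
  rec <- function(first) {
    s <- if (first) "1" else "2"
    o <- if (first) "2" else "1"
    mapped <- pairs[[paste0("mapped", s)]]
    omapped <- pairs[[paste0("mapped", o)]]
    rev <- pairs[[paste0("strand", s)]] == "-"
    orev <- pairs[[paste0("strand", o)]] == "-"
    flag <- 1L +
      ifelse(pairs$proper, 2L, 0L) +
      ifelse(mapped, 0L, 4L) +
      ifelse(omapped, 0L, 8L) +
      ifelse(mapped & rev, 16L, 0L) +
      ifelse(omapped & orev, 32L, 0L) +
      if (first) 64L else 128L
    chrom <- ifelse(mapped, pairs[[paste0("chrom", s)]], "*")
    pos <- ifelse(mapped, pairs[[paste0("pos", s)]], 0L)
    mapq <- ifelse(mapped, pairs[[paste0("mapq", s)]], 0L)
    cigar <- ifelse(mapped, paste0(pairs[[paste0("len", s)]], "M"), "*")
    mchrom <- ifelse(omapped,
                     ifelse(omapped & mapped &
                              pairs[[paste0("chrom", o)]] ==
                                pairs[[paste0("chrom", s)]],
                            "=", pairs[[paste0("chrom", o)]]),
                     "*")
    mpos <- ifelse(omapped, pairs[[paste0("pos", o)]], 0L)
    tlen <- if ("tlen" %in% names(pairs)) {
      sign <- ifelse(mapped & omapped &
                       pairs[[paste0("pos", s)]] <=
                         pairs[[paste0("pos", o)]], 1L, -1L)
      ifelse(mapped & omapped & pairs$chrom1 == pairs$chrom2,
             sign * pairs$tlen, 0L)
    } else 0L
    seqcol <- paste0("read", s)
    seqs <- if (seqcol %in% names(pairs)) pairs[[seqcol]] else "*"
    paste(pairs$qname, flag, chrom, pos, mapq, cigar, mchrom, mpos, tlen,
          seqs, "*", sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(pairs) > 0) {
    writeLines(rec(TRUE), con)
    writeLines(rec(FALSE), con)
  }
  invisible(path)
}

#' Read a SAM file into a pair table
#'
#' Primary, non-supplementary paired records are joined by query name into
#' one row per pair. Secondary/supplementary alignments are skipped with a
#' counter.
#'
#' @param path SAM (text) file
#' @param sample sample label to attach (`"tumor"` or `"normal"`)
#' @return pair `data.table` with attribute `n_skipped`
#' @export
read_sam <- function(path, sample = "tumor") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) stop("no alignment records in ", path)
  f <- tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  rec <- data.table(qname = f[[1]], flag = as.integer(f[[2]]),
                    chrom = f[[3]], pos = as.integer(f[[4]]),
                    mapq = as.integer(f[[5]]), cigar = f[[6]],
                    seq = f[[10]])
  sec <- bitwAnd(rec$flag, 256L) > 0 | bitwAnd(rec$flag, 2048L) > 0 |
    bitwAnd(rec$flag, 1L) == 0
  n_skipped <- sum(sec)
  rec <- rec[!sec]
  rec[, first := bitwAnd(flag, 64L) > 0]
  rec[, mapped := bitwAnd(flag, 4L) == 0]
  rec[, strand := ifelse(bitwAnd(flag, 16L) > 0, "-", "+")]
  rec[, proper := bitwAnd(flag, 2L) > 0]
  rec[, len := ifelse(seq == "*", cigar_ref_len(cigar), nchar(seq))]
  r1 <- rec[first == TRUE]
  r2 <- rec[first == FALSE]
  setkey(r1, qname)
  setkey(r2, qname)
  common <- intersect(r1$qname, r2$qname)
  r1 <- r1[common]
  r2 <- r2[common]
  out <- data.table(
    qname = r1$qname,
    chrom1 = r1$chrom, pos1 = r1$pos, strand1 = r1$strand,
    mapq1 = r1$mapq, len1 = r1$len, mapped1 = r1$mapped,
    chrom2 = r2$chrom, pos2 = r2$pos, strand2 = r2$strand,
    mapq2 = r2$mapq, len2 = r2$len, mapped2 = r2$mapped,
    proper = r1$proper & r2$proper,
    sample = sample)
  setattr(out, "n_skipped", n_skipped)
  out
}

# reference-consuming length of a CIGAR string
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]", "", toks))
    op <- sub("[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write breakpoint calls as BEDPE
#'
#' Standard 10-column BEDPE (0-based half-open intervals, one base each):
#' chromA, startA, endA, chromB, startB, endB, name, score (= supporting
#' extension count), strandA, strandB, plus `somatic`, `class` and
#' `confirmed` extra columns.
#'
#' @param calls call table from [detect_breakpoints()]
#' @param gg a `global_genome`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bedpe <- function(calls, gg, path) {
  if (nrow(calls) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  a <- global_to_chrom(gg, calls$x0)
  b <- global_to_chrom(gg, calls$y0)
  strands <- class_strands(calls$class)
  out <- data.table(
    chromA = a$chrom, startA = a$pos, endA = a$pos + 1,
    chromB = b$chrom, startB = b$pos, endB = b$pos + 1,
    name = sprintf("bp%03d", seq_len(nrow(calls))),
    score = calls$support,
    strandA = strands$x, strandB = strands$y,
    somatic = ifelse(calls$somatic, "somatic", "germline"),
    class = calls$class,
    confirmed = calls$confirmed)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

class_strands <- function(class) {
  map_x <- c(del_like = "+", dup_like = "-", inv_pp = "+", inv_mm = "-")
  map_y <- c(del_like = "-", dup_like = "+", inv_pp = "+", inv_mm = "-")
  list(x = unname(map_x[class]), y = unname(map_y[class]))
}
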