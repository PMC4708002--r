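#' Generate a random reference genome
#'
#' I.i.d. uniform A/C/G/T sequence; a stand-in for a real reference at
#' desk scale.
#'
#' @param lengths integer vector of chromosome lengths (named, or names
#'   `chr1`, `chr2`, ... are generated)
#' @param seed optional RNG seed
#' @return named character vector of chromosome sequences
#' @export
sim_genome <- function(lengths, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nms <- names(lengths)
  if (is.null(nms)) nms <- paste0("chr", seq_along(lengths))
  out <- vapply(lengths, function(n) {
    paste(sample(BASES, n, replace = TRUE), collapse = "")
  }, character(1))
  setNames(out, nms)
}

#' Introduce random SNPs
#'
#' Each base is substituted independently with probability `rate` by a
#' uniformly chosen different base.
#'
#' @param genome named character vector of chromosome sequences
#' @param rate per-base substitution probability (default 0.001)
#' @param seed optional RNG seed
#' @return list with `genome` (mutated sequences) and `log`
#'   (`data.table`: `chrom`, `pos` 0-based, `ref`, `alt`)
#' @export
add_snps <- function(genome, rate = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(rate >= 0, rate <= 0.05)
  logs <- list()
  for (ch in names(genome)) {
    len <- nchar(genome[[ch]])
    k <- rbinom(1, len, rate)
    if (k == 0) next
    pos <- sort(sample.int(len, k))
    s <- charToRaw(genome[[ch]])
    ref <- rawToChar(s[pos], multiple = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1),
                  USE.NAMES = FALSE)
    s[pos] <- charToRaw(paste(alt, collapse = ""))
    genome[[ch]] <- rawToChar(s)
    logs[[ch]] <- data.table(chrom = ch, pos = pos - 1L, ref = ref, alt = alt)
  }
  list(genome = genome,
       log = if (length(logs)) rbindlist(logs) else
         data.table(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0)))
}

# end-base u joined (reading forward) to start-base v, both on the forward
# strand, in global coordinates: junction point and orientation class
fwd_adjacency <- function(u, v) {
  if (u < v) list(x0 = u, y0 = v, class = "del_like")
  else list(x0 = v, y0 = u, class = "dup_like")
}

#' Introduce random rearrangements and record the truth set
#'
#' Applies `n_per_type` events of each of six types — insertion, deletion,
#' inversion, tandem duplication, and intra- and inter-chromosomal
#' translocation — at non-overlapping positions, with affected lengths
#' uniform in `len_range`. Every novel adjacency created in the derived
#' (cancer) genome is recorded as a truth junction with its coordinates on
#' the source (normal/reference) coordinate system and its orientation
#' class. Junction counts per event: insertion 2, deletion 1, inversion 2,
#' tandem duplication 1, translocations 3 (cut-and-paste: one at the
#' excision site, two at the integration site).
#'
#' Insertions copy a distant genomic segment to the integration point
#' (dispersed duplication), so the inserted material is mappable and both
#' junction partners have reference coordinates.
#'
#' @param genome named character vector (the normal genome)
#' @param n_per_type events of each type (default 40)
#' @param len_range affected-length range in bp (default 300 to 30000)
#' @param margin minimum separation between events (default 3000 bp)
#' @param end_margin keep events away from chromosome ends (default
#'   2000 bp)
#' @param types subset of event types to introduce (default all six)
#' @param seed optional RNG seed
#' @return list with `genome` (the rearranged cancer genome) and `truth`
#'   (`data.table`: `event_id`, `type`, `x0`, `y0` global 0-based
#'   coordinates with `x0 < y0`, `class`)
#' @export
apply_rearrangements <- function(genome, n_per_type = 40L,
                                 len_range = c(300L, 30000L),
                                 margin = 3000L, end_margin = 2000L,
                                 types = c("insertion", "deletion",
                                           "inversion", "tandem_dup",
                                           "intra_trans", "inter_trans"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  types <- match.arg(types, several.ok = TRUE)
  gg <- concatenate_genome(genome)
  chroms <- names(genome)
  lens <- nchar(genome)
  reserved <- lapply(chroms, function(ch) data.table(s = numeric(0),
                                                     t = numeric(0)))
  names(reserved) <- chroms

  place <- function(len, chrom = NULL, not_chrom = NULL) {
    for (try in 1:2000) {
      ch <- if (!is.null(chrom)) chrom else {
        cand <- setdiff(chroms, not_chrom)
        sample(cand, 1, prob = lens[cand])
      }
      lo <- end_margin
      hi <- lens[[ch]] - end_margin - len
      if (hi <= lo) next
      s <- floor(runif(1, lo, hi))
      r <- reserved[[ch]]
      if (nrow(r) == 0 || all(s + len + margin <= r$s | s >= r$t + margin)) {
        reserved[[ch]] <<- rbind(r, data.table(s = s, t = s + len))
        return(list(chrom = ch, s = s, t = s + len))
      }
    }
    stop("could not place a rearrangement without overlap; ",
         "reduce the event count or lengths")
  }

  plan <- data.table(type = rep(types, each = n_per_type))
  plan <- plan[sample(.N)]
  plan[, event_id := .I]

  edits <- lapply(chroms, function(ch) list())
  names(edits) <- chroms
  add_edit <- function(ch, s, t, repl) {
    edits[[ch]][[length(edits[[ch]]) + 1]] <<- list(s = s, t = t, repl = repl)
  }
  gpos <- function(ch, p) chrom_to_global(gg, ch, p)
  truth <- list()
  add_junction <- function(eid, type, j) {
    truth[[length(truth) + 1]] <<-
      data.table(event_id = eid, type = type, x0 = j$x0, y0 = j$y0,
                 class = j$class)
  }

  for (i in seq_len(nrow(plan))) {
    ty <- plan$type[i]
    eid <- plan$event_id[i]
    len <- floor(runif(1, len_range[1], len_range[2] + 1))
    if (ty == "deletion") {
      e <- place(len)
      add_edit(e$chrom, e$s, e$t, "")
      add_junction(eid, ty, fwd_adjacency(gpos(e$chrom, e$s - 1),
                                          gpos(e$chrom, e$t)))
    } else if (ty == "inversion") {
      e <- place(len)
      seg <- substr(genome[[e$chrom]], e$s + 1, e$t)
      add_edit(e$chrom, e$s, e$t, revcomp(seg))
      add_junction(eid, ty, list(x0 = gpos(e$chrom, e$s - 1),
                                 y0 = gpos(e$chrom, e$t - 1),
                                 class = "inv_pp"))
      add_junction(eid, ty, list(x0 = gpos(e$chrom, e$s),
                                 y0 = gpos(e$chrom, e$t),
                                 class = "inv_mm"))
    } else if (ty == "tandem_dup") {
      e <- place(len)
      seg <- substr(genome[[e$chrom]], e$s + 1, e$t)
      add_edit(e$chrom, e$s, e$t, paste0(seg, seg))
      add_junction(eid, ty, fwd_adjacency(gpos(e$chrom, e$t - 1),
                                          gpos(e$chrom, e$s)))
    } else if (ty == "insertion") {
      src <- place(len)
      tgt <- place(0)
      seg <- substr(genome[[src$chrom]], src$s + 1, src$t)
      add_edit(tgt$chrom, tgt$s, tgt$s, seg)
      add_junction(eid, ty, fwd_adjacency(gpos(tgt$chrom, tgt$s - 1),
                                          gpos(src$chrom, src$s)))
      add_junction(eid, ty, fwd_adjacency(gpos(src$chrom, src$t - 1),
                                          gpos(tgt$chrom, tgt$s)))
    } else if (ty %in% c("intra_trans", "inter_trans")) {
      cut <- place(len)
      tgt <- if (ty == "intra_trans") place(0, chrom = cut$chrom)
             else place(0, not_chrom = cut$chrom)
      seg <- substr(genome[[cut$chrom]], cut$s + 1, cut$t)
      add_edit(cut$chrom, cut$s, cut$t, "")
      add_edit(tgt$chrom, tgt$s, tgt$s, seg)
      add_junction(eid, ty, fwd_adjacency(gpos(cut$chrom, cut$s - 1),
                                          gpos(cut$chrom, cut$t)))
      add_junction(eid, ty, fwd_adjacency(gpos(tgt$chrom, tgt$s - 1),
                                          gpos(cut$chrom, cut$s)))
      add_junction(eid, ty, fwd_adjacency(gpos(cut$chrom, cut$t - 1),
                                          gpos(tgt$chrom, tgt$s)))
    }
  }

  cancer <- genome
  for (ch in chroms) {
    ops <- edits[[ch]]
    if (length(ops) == 0) next
    ord <- order(vapply(ops, `[[`, numeric(1), "s"))
    ops <- ops[ord]
    pieces <- character(0)
    prev <- 0
    for (op in ops) {
      pieces <- c(pieces, substr(genome[[ch]], prev + 1, op$s), op$repl)
      prev <- op$t
    }
    pieces <- c(pieces, substr(genome[[ch]], prev + 1, nchar(genome[[ch]])))
    cancer[[ch]] <- paste(pieces, collapse = "")
  }

  tr <- rbindlist(truth)
  stopifnot(all(tr$x0 < tr$y0))
  list(genome = cancer, truth = tr[order(x0)])
}

#' Simulate paired-end reads
#'
#' Fragments start uniformly on the genome; the insert length is Gaussian
#' N(insert_mean, insert_sd) truncated at twice the read length; the two
#' ends are read inward, `read_len` bases each, with i.i.d. substitution
#' errors. There is no position bias (no sonication bias): given the
#' fragment, the junction offset within it is uniform.
#'
#' @param genome named character vector
#' @param coverage mean per-base read coverage
#' @param read_len read length (default 90)
#' @param insert_mean mean insert length (default 760)
#' @param insert_sd insert-length sd (default 45)
#' @param error_rate per-base substitution error rate (default 0.001)
#' @param prefix read-name prefix
#' @param seed optional RNG seed
#' @return `data.table` with `qname`, `read1`, `read2`
#' @export
sim_reads <- function(genome, coverage, read_len = 90L, insert_mean = 760,
                      insert_sd = 45, error_rate = 0.001, prefix = "sim",
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(insert_mean > 2 * read_len, coverage > 0)
  lens <- nchar(genome)
  n_pairs <- round(coverage * sum(lens) / (2 * read_len))
  chrom_of <- sample(names(genome), n_pairs, replace = TRUE, prob = lens)
  out <- vector("list", length(genome))
  names(out) <- names(genome)
  for (ch in names(genome)) {
    n <- sum(chrom_of == ch)
    if (n == 0) next
    len <- lens[[ch]]
    l <- pmax(2L * read_len, pmin(round(rnorm(n, insert_mean, insert_sd)),
                                  len))
    start <- floor(runif(n, 1, len - l + 2))  # 1-based fragment start
    r1 <- substring(genome[[ch]], start, start + read_len - 1)
    r2 <- revcomp(substring(genome[[ch]], start + l - read_len,
                            start + l - 1))
    out[[ch]] <- data.table(
      qname = sprintf("%s_%s_%d_%d_%d", prefix, ch, seq_len(n), start, l),
      read1 = r1, read2 = r2)
  }
  dt <- rbindlist(out)
  if (error_rate > 0) {
    dt[, read1 := add_read_errors(read1, error_rate)]
    dt[, read2 := add_read_errors(read2, error_rate)]
  }
  dt
}

# i.i.d. substitution errors over a vector of equal-length reads
add_read_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  cells <- length(reads) * rl
  k <- rbinom(1, cells, rate)
  if (k == 0) return(reads)
  cell <- sample.int(cells, k)
  ridx <- (cell - 1L) %/% rl + 1L
  p <- (cell - 1L) %% rl + 1L
  byread <- split(p, ridx)
  idx <- as.integer(names(byread))
  for (j in seq_along(idx)) {
    i <- idx[j]
    s <- charToRaw(reads[i])
    for (pp in byread[[j]]) {
      cur <- rawToChar(s[pp])
      s[pp] <- charToRaw(sample(setdiff(BASES, cur), 1))
    }
    reads[i] <- rawToChar(s)
  }
  reads
}

#' Mix tumor and normal-genome reads to a target purity
#'
#' The output has exactly as many pairs as the tumor input: a fraction
#' `purity` drawn from the tumor set and `1 - purity` from the
#' normal-genome pool, both without replacement.
#'
#' @param tumor_reads,pool_reads read tables from [sim_reads()]
#' @param purity fraction of cancer-genome pairs in \[0, 1\]
#' @param seed optional RNG seed
#' @return read `data.table`
#' @export
mix_purity <- function(tumor_reads, pool_reads, purity, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(purity >= 0, purity <= 1)
  n <- nrow(tumor_reads)
  k <- round(purity * n)
  if (n - k > nrow(pool_reads)) stop("normal-genome pool too small")
  rbind(tumor_reads[sample(.N, k)], pool_reads[sample(.N, n - k)])
}

#' Map read pairs with the internal exact-seed mapper
#'
#' Each read's leading `seed_len` bases are matched exactly against both
#' strands of the reference via backward search (with a pigeonhole rescue
#' allowing one seed mismatch); candidate placements are scored by
#' full-length mismatch count, a unique best placement gets MAPQ 60 and
#' ties get 0. The proper-pair flag is set when the two ends map to the
#' same chromosome in inward orientation with a template length within
#' 4 sd of the insert mean.
#'
#' @param gidx a `genome_index`
#' @param reads read table (`qname`, `read1`, `read2`)
#' @param sample sample label attached to the pair table
#' @param insert_mean,insert_sd expected insert-length model for the
#'   proper-pair test
#' @param seed_len seed length (default 30)
#' @return pair `data.table` (one row per pair)
#' @export
map_read_pairs <- function(gidx, reads, sample = "tumor", insert_mean = 760,
                           insert_sd = 45, seed_len = 30L) {
  map_end <- function(rv) {
    m <- map_reads_cpp(gidx$bwt, gidx$C, gidx$occ, gidx$sa, gidx$text,
                       rv, seed_len = seed_len)
    mapped <- !is.na(m$pos)
    rl <- nchar(rv)
    chrom <- rep(NA_character_, length(rv))
    pos <- rep(NA_integer_, length(rv))
    strand <- rep(NA_character_, length(rv))
    if (any(mapped)) {
      tg <- text_to_global(gidx, m$pos[mapped])
      cp <- global_to_chrom(gidx$gg, tg$g)
      p0 <- ifelse(tg$strand == "+", cp$pos, cp$pos - (rl[mapped] - 1))
      chrom[mapped] <- cp$chrom
      pos[mapped] <- as.integer(p0 + 1L)  # 1-based leftmost
      strand[mapped] <- ifelse(tg$strand == "+", "+", "-")
    }
    list(chrom = chrom, pos = pos, strand = strand,
         mapq = ifelse(mapped, m$mapq, 0L), nm = m$nm,
         len = rl, mapped = mapped)
  }
  e1 <- map_end(reads$read1)
  e2 <- map_end(reads$read2)
  dt <- data.table(
    qname = reads$qname,
    chrom1 = e1$chrom, pos1 = e1$pos, strand1 = e1$strand,
    mapq1 = e1$mapq, len1 = e1$len, nm1 = e1$nm, mapped1 = e1$mapped,
    chrom2 = e2$chrom, pos2 = e2$pos, strand2 = e2$strand,
    mapq2 = e2$mapq, len2 = e2$len, nm2 = e2$nm, mapped2 = e2$mapped,
    sample = sample)
  both <- dt$mapped1 & dt$mapped2 & dt$chrom1 == dt$chrom2
  left_plus <- both & dt$strand1 == "+" & dt$strand2 == "-" &
    dt$pos1 <= dt$pos2
  right_plus <- both & dt$strand1 == "-" & dt$strand2 == "+" &
    dt$pos2 <= dt$pos1
  span <- rep(NA_integer_, nrow(dt))
  span[left_plus] <- dt$pos2[left_plus] + dt$len2[left_plus] -
    dt$pos1[left_plus]
  span[right_plus] <- dt$pos1[right_plus] + dt$len1[right_plus] -
    dt$pos2[right_plus]
  dt[, tlen := span]
  dt[, proper := !is.na(span) & abs(span - insert_mean) <= 4 * insert_sd]
  dt
}

#' FASTQ output / input for simulated pairs
#'
#' Plain four-line FASTQ with constant qualities (`I`); qualities are
#' ignored on input.
#'
#' @param reads read table (`qname`, `read1`, `read2`)
#' @param path1,path2 output files for the two ends
#' @rdname fastq_io
#' @export
write_fastq <- function(reads, path1, path2) {
  w <- function(seqs, names, path) {
    q <- strrep("I", nchar(seqs))
    writeLines(paste0("@", names, "\n", seqs, "\n+\n", q), path)
  }
  w(reads$read1, reads$qname, path1)
  w(reads$read2, reads$qname, path2)
  invisible(c(path1, path2))
}

#' @rdname fastq_io
#' @export
read_fastq <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  stopifnot(length(r1) == length(r2))
  data.table(qname = sub(" .*", "", names(r1)),
             read1 = as.character(r1), read2 = as.character(r2))
}
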