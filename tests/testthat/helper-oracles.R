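# Independent brute-force oracles used across the suite. All are naive
# implementations kept deliberately separate from the package's own code
# paths.

rand_reads <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# naive multi-string BWT: suffixes of every '$'-terminated entry, sorted
# with '$' < A < C < G < T; ties between equal suffixes broken by entry
# separators that descend with entry position (the package's canonical
# convention). Separators encoded as sortable multi-character tokens.
naive_bwt <- function(entries) {
  m <- length(entries)
  syms <- list()
  for (i in seq_along(entries)) {
    syms[[i]] <- c(strsplit(entries[i], "")[[1]], sprintf("!%09d", m - i))
  }
  syms <- unlist(syms)
  n <- length(syms)
  suff <- vapply(seq_len(n), function(k) paste(syms[k:n], collapse = ""),
                 character(1))
  ord <- order(suff, method = "radix")
  prev <- syms[ifelse(ord == 1, n, ord - 1)]
  prev[startsWith(prev, "!")] <- "$"
  paste(prev, collapse = "")
}

bwt_as_string <- function(index) {
  paste(c("$", "A", "C", "G", "T")[as.integer(index$bwt) + 1],
        collapse = "")
}

# overlapping substring count of p in one haystack
count_overlapping <- function(hay, p) {
  n <- 0L
  start <- 1L
  repeat {
    i <- regexpr(p, substr(hay, start, nchar(hay)), fixed = TRUE)
    if (i < 0) break
    n <- n + 1L
    start <- start + i
  }
  n
}

# total overlapping occurrences of p over a set of strings
brute_count <- function(strings, p) {
  sum(vapply(strings, count_overlapping, integer(1), p = p))
}

# all left contexts (up to e bases) of seed occurrences over strings
brute_left_contexts <- function(strings, seed, e) {
  out <- character(0)
  for (s in strings) {
    start <- 1L
    repeat {
      i <- regexpr(seed, substr(s, start, nchar(s)), fixed = TRUE)
      if (i < 0) break
      pos <- start + i - 1L
      out <- c(out, substr(s, max(1, pos - e), pos - 1))
      start <- pos + 1L
    }
  }
  out
}

# brute-force MLU+: smallest l such that the l-mer at 0-based pos of seq
# occurs exactly once over both strands of the genome; NA if none fits
brute_mlu <- function(genome, chrom, pos, max_l = 60) {
  both <- c(unname(genome), unname(vapply(genome, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))))
  len <- nchar(genome[[chrom]])
  for (l in seq_len(min(max_l, len - pos))) {
    p <- substr(genome[[chrom]], pos + 1, pos + l)
    if (brute_count(both, p) == 1) return(l)
  }
  NA_integer_
}

# classic full-matrix semi-global edit distance (text ends free)
dp_min_edit <- function(p, t) {
  pm <- strsplit(p, "")[[1]]
  tm <- strsplit(t, "")[[1]]
  m <- length(pm)
  n <- length(tm)
  prev <- rep(0, n + 1)
  for (i in seq_len(m)) {
    cur <- numeric(n + 1)
    cur[1] <- i
    for (j in seq_len(n)) {
      cur[j + 1] <- min(prev[j] + (pm[i] != tm[j]), prev[j + 1] + 1,
                        cur[j] + 1)
    }
    prev <- cur
  }
  min(prev)
}

# single-linkage connected components under "both axis gaps < L"
sl_components <- function(x, y, L) {
  n <- length(x)
  adj <- abs(outer(x, x, "-")) < L & abs(outer(y, y, "-")) < L
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] != 0) next
    cid <- cid + 1
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# sample discordant pairs from the generative insert model for a junction
# at (x0, y0) of a given class
sample_pairs_for_junction <- function(n, x0, y0, class, L = 760, sigma = 45) {
  l <- rnorm(n, L, sigma)
  u <- runif(n) * l
  v <- l - u
  switch(class,
    del_like = data.table::data.table(x = round(x0 - u), y = round(y0 + v)),
    dup_like = data.table::data.table(x = round(x0 + v), y = round(y0 - u)),
    inv_pp   = data.table::data.table(x = round(x0 - u), y = round(y0 - v)),
    inv_mm   = data.table::data.table(x = round(x0 + u), y = round(y0 + v)))
}
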