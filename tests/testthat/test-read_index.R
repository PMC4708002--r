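test_that("BWT construction matches the naive suffix-sort oracle", {
  set.seed(101)
  reads <- rand_reads(50, 20)
  idx <- build_read_index(reads, "tumor", min_read_len = 5)
  entries <- c(reads, revcomp(reads))
  expect_identical(bwt_as_string(idx), naive_bwt(entries))

  # the BWT is a permutation: character histogram equals the input's
  tab <- table(strsplit(bwt_as_string(idx), "")[[1]])
  input_chars <- table(strsplit(paste(entries, collapse = ""), "")[[1]])
  expect_equal(as.integer(tab[c("A", "C", "G", "T")]),
               as.integer(input_chars[c("A", "C", "G", "T")]))
  expect_equal(as.integer(tab[["$"]]), idx$n_entries)
})

test_that("a single read is indexed with its reverse complement", {
  idx <- build_read_index("ACGT", "normal", min_read_len = 4)
  expect_equal(idx$n_entries, 2L)  # palindrome still gives two entries
  expect_equal(idx$sample_label, "normal")
})

test_that("reads with non-ACGT characters are dropped with a count", {
  idx <- build_read_index(c("ACGTACGTAC", "ACGTNCGTAC", "TTTTGGGGCC"),
                          "tumor", min_read_len = 10)
  expect_equal(idx$n_reads, 2L)
  expect_equal(idx$n_dropped, 1L)
  expect_error(build_read_index(c("NNNN"), "tumor", min_read_len = 4),
               "no reads left")
  expect_error(build_read_index(character(0), "tumor"), "empty")
})

test_that("occurrence counting equals brute force over both strands", {
  set.seed(102)
  reads <- rand_reads(40, 25)
  entries <- c(reads, revcomp(reads))
  idx <- build_read_index(reads, "tumor", min_read_len = 5)

  # a read present twice counts at least twice
  idx2 <- build_read_index(c(reads, reads[1]), "tumor", min_read_len = 5)
  expect_gte(count_occurrences(idx2, reads[1]), 2L)

  # longer than any read: 0, not an error
  expect_equal(count_occurrences(idx, strrep("ACGT", 20)), 0L)

  for (i in 1:100) {
    L <- sample(5:25, 1)
    p <- if (runif(1) < 0.5) {
      r <- sample(reads, 1)
      s <- sample.int(25 - min(L, 24) + 1, 1)
      substr(r, s, min(25, s + L - 1))
    } else rand_seq(L)
    expect_equal(count_occurrences(idx, p), brute_count(entries, p),
                 info = p)
  }
})

test_that("reverse-complement closure holds", {
  set.seed(103)
  reads <- rand_reads(30, 30)
  idx <- build_read_index(reads, "tumor")
  for (i in 1:20) {
    p <- rand_seq(sample(6:15, 1))
    expect_equal(count_occurrences(idx, p),
                 brute_count(reads, p) + brute_count(reads, revcomp(p)))
  }
})

test_that("backward search steps match brute-force pattern counts", {
  set.seed(104)
  reads <- rand_reads(30, 20)
  entries <- c(reads, revcomp(reads))
  idx <- build_read_index(reads, "tumor", min_read_len = 5)

  # first step from the full interval = suffixes starting with that base
  iv <- backward_step(idx, search_interval(idx), "A")
  expect_equal(iv[2] - iv[1], idx$C[3] - idx$C[2])  # count of 'A' symbols

  # empty interval stays empty (bounds may move, width stays zero)
  empty_iv <- backward_step(idx, c(5L, 5L), "C")
  expect_equal(empty_iv[2] - empty_iv[1], 0L)
  expect_error(backward_step(idx, search_interval(idx), "N"))

  for (i in 1:30) {
    p <- rand_seq(8)
    iv <- search_interval(idx)
    for (c_ in rev(strsplit(p, "")[[1]]))
      iv <- backward_step(idx, iv, c_)
    expect_equal(iv[2] - iv[1], brute_count(entries, p), info = p)
  }
})

test_that("BWT inversion recovers the indexed multiset exactly", {
  set.seed(105)
  reads <- c(rand_reads(25, 18), rand_reads(2, 18)[c(1, 1)])  # with a dup
  idx <- build_read_index(reads, "tumor", min_read_len = 5)
  expect_identical(sort(extract_reads(idx)),
                   sort(c(reads, revcomp(reads))))
})

test_that("left-extension enumeration equals brute force and is monotone", {
  set.seed(106)
  # constructed branching example
  idx <- build_read_index(c("GGACGTAAAA", "TTACGTAAAA"), "tumor",
                          min_read_len = 6)
  res <- enumerate_left_extensions(idx, "ACGTAAAA", ext_len = 2)
  expect_setequal(res$extension, c("GG", "TT"))
  expect_true(all(res$support >= 1))

  # absent seed: empty set
  expect_equal(nrow(enumerate_left_extensions(idx, "ACGTACGTACGT", 5)), 0)

  reads <- rand_reads(30, 22)
  entries <- c(reads, revcomp(reads))
  idx <- build_read_index(reads, "tumor", min_read_len = 5)
  for (i in 1:25) {
    r <- sample(reads, 1)
    s <- sample(8:15, 1)
    seed <- substr(r, s, s + 6)
    e <- 5
    res <- enumerate_left_extensions(idx, seed, e)
    ctxs <- brute_left_contexts(entries, seed, e)
    seed_count <- count_occurrences(idx, seed)

    # every full-length context appears as a maximal extension
    full <- unique(ctxs[nchar(ctxs) >= e])
    for (cx in full)
      expect_true(substr(cx, nchar(cx) - e + 1, nchar(cx)) %in%
                    res$extension)
    # support equals the number of contexts ending with the extension
    for (j in seq_len(nrow(res))) {
      ext <- res$extension[j]
      sup <- sum(vapply(ctxs, function(cx)
        nchar(cx) >= nchar(ext) &&
          substr(cx, nchar(cx) - nchar(ext) + 1, nchar(cx)) == ext,
        logical(1)))
      expect_equal(res$support[j], sup)
      # support monotonicity along the extension tree
      if (nchar(ext) > 1) {
        expect_lte(res$support[j],
                   count_occurrences(idx, paste0(substr(ext, 2, nchar(ext)),
                                                 seed)))
      }
      expect_lte(res$support[j], seed_count)
    }
    # full-length branch supports cannot exceed the seed count
    expect_lte(sum(res$support[nchar(res$extension) == e]), seed_count)
  }
})

test_that("index serialization round-trips", {
  idx <- build_read_index(rand_reads(5, 15), "tumor", min_read_len = 5)
  f <- tempfile(fileext = ".rds")
  index_save(idx, f)
  idx2 <- index_load(f)
  expect_identical(idx, idx2)
  unlink(f)
})
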