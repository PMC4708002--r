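#' Build a lossless FM-index dictionary over a read collection
#'
#' Every read and its reverse complement are indexed as separate
#' '$'-terminated entries of a Burrows-Wheeler transform, so that
#' junction-spanning fragments are found by exact matching regardless of
#' the sequenced strand. The index supports exact occurrence counting by
#' backward search and recursive enumeration of leftward extensions; it is
#' lossless in the sense that the indexed multiset of entries can be
#' reconstructed from it exactly (see [extract_reads()]).
#'
#' Reads containing characters outside A/C/G/T (e.g. N calls) are dropped
#' with a count kept in the returned object, as are reads shorter than
#' `min_read_len`.
#'
#' @param reads character vector (or `DNAStringSet`) of read sequences
#' @param sample_label `"tumor"` or `"normal"`
#' @param min_read_len minimum read length retained (default 30)
#' @return an object of class `read_index`
#' @export
build_read_index <- function(reads, sample_label = c("tumor", "normal"),
                             min_read_len = 30L) {
  sample_label <- match.arg(sample_label)
  reads <- as.character(reads)
  if (length(reads) == 0) stop("empty read collection")
  keep <- is_acgt(reads) & nchar(reads) >= min_read_len
  n_dropped <- sum(!keep)
  reads <- toupper(reads[keep])
  if (length(reads) == 0) stop("no reads left after filtering")

  entries <- c(reads, revcomp(reads))
  fm <- fm_build_cpp(entries, keep_sa = FALSE, compute_mlu = FALSE)
  structure(
    list(bwt = fm$bwt, C = fm$C, occ = fm$occ,
         n_entries = fm$n_entries, n = fm$n,
         n_reads = length(reads), n_dropped = n_dropped,
         max_read_len = max(nchar(reads)),
         sample_label = sample_label),
    class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat(sprintf(
    "<read_index> %s sample: %d reads (+ reverse complements = %d entries), %d dropped, BWT length %d\n",
    x$sample_label, x$n_reads, x$n_entries, x$n_dropped, as.integer(x$n)))
  invisible(x)
}

#' Full backward-search interval of an index
#'
#' The interval matching the empty pattern: all suffix ranks, half-open
#' `[lo, hi)` with 0-based bounds.
#' @param index a `read_index` (or `genome_index`)
#' @return integer vector `c(lo, hi)`
#' @export
search_interval <- function(index) c(0L, as.integer(index$n))

#' One backward-search step
#'
#' Extends the pattern matched by `interval` one character to the left:
#' the returned interval matches `c . P`. An empty interval (`lo == hi`)
#' signals that the extended pattern does not occur; stepping an empty
#' interval yields an empty interval.
#'
#' @param index a `read_index` or `genome_index`
#' @param interval integer `c(lo, hi)`, half-open suffix-rank bounds
#' @param base single character, one of A, C, G, T
#' @return integer vector `c(lo, hi)`
#' @export
backward_step <- function(index, interval, base) {
  stopifnot(length(interval) == 2, interval[1] >= 0,
            interval[1] <= interval[2], interval[2] <= index$n)
  fm_step_cpp(index$bwt, index$C, index$occ,
              as.integer(interval[1]), as.integer(interval[2]), base)
}

#' Count exact occurrences of a pattern in the indexed entries
#'
#' Returns the number of occurrences of `pattern` as a substring of any
#' indexed entry (for a [build_read_index()] index: reads and their
#' reverse complements). A pattern longer than every entry simply has
#' count 0.
#'
#' @param index a `read_index` or `genome_index`
#' @param pattern non-empty A/C/G/T string
#' @return integer occurrence count
#' @export
count_occurrences <- function(index, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) >= 1)
  if (!is_acgt(pattern)) stop("pattern must be over A, C, G, T")
  fm_count_cpp(index$bwt, index$C, index$occ, toupper(pattern))
}

#' Enumerate maximal leftward extensions of a seed pattern
#'
#' Recursively examines the four possible one-base left extensions at each
#' step and returns every extension string `s` of length at most `ext_len`
#' such that `s . seed` occurs in the index and `s` is maximal: either
#' `nchar(s) == ext_len`, or no further one-base extension occurs at all.
#' `support` is the exact occurrence count of `s . seed`.
#'
#' @param index a `read_index` or `genome_index`
#' @param seed non-empty A/C/G/T seed pattern
#' @param ext_len maximum extension length (default 20)
#' @return `data.frame` with columns `extension`, `support`; zero rows if
#'   the seed does not occur
#' @export
enumerate_left_extensions <- function(index, seed, ext_len = 20L) {
  stopifnot(nchar(seed) >= 1, ext_len >= 1)
  if (!is_acgt(seed)) stop("seed must be over A, C, G, T")
  fm_extensions_cpp(index$bwt, index$C, index$occ, toupper(seed),
                    as.integer(ext_len), emit_ends = FALSE)
}

#' Reconstruct all indexed entries
#'
#' Inverts the BWT entry by entry (LF walk from each terminator row),
#' recovering the exact multiset of indexed strings. Mainly a correctness
#' device: the dictionary is lossless.
#'
#' @param index a `read_index`
#' @return character vector of all entries, in indexing order
#' @export
extract_reads <- function(index) {
  fm_invert_cpp(index$bwt, index$C, index$occ, index$n_entries)
}

#' Save / load an index
#'
#' Indexes are plain lists of atomic vectors; serialization is a versioned
#' RDS file.
#' @param index a `read_index` or `genome_index`
#' @param path file path
#' @rdname index_io
#' @export
index_save <- function(index, path) {
  saveRDS(list(format = "svbwt-index", version = 1L, index = index), path)
  invisible(path)
}

#' @param path file path
#' @rdname index_io
#' @export
index_load <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "svbwt-index"))
    stop("not an svbwt index file")
  x$index
}
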