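# Canonical k-mer counting and sorted-multiset algebra.  A k-mer table is
# the currency of the first half of the pipeline: the affected sample is
# reduced to its canonical k-mer spectrum, error-filtered, screened, and
# the unaffected samples' spectra are subtracted from it.

#' Construct a k-mer count table
#'
#' @param kmer Character vector of canonical k-mers (sorted or not).
#' @param count Positive integer counts, parallel to `kmer`.
#' @param k K-mer length.
#' @return A `kmer_table`: list with sorted `kmer`, `count`, and `k`.
#' @export
kmer_table <- function(kmer, count, k) {
  stopifnot(length(kmer) == length(count))
  k <- as.integer(k)
  if (length(kmer)) {
    stopifnot(all(nchar(kmer) == k), all(count >= 1L))
    o <- order(kmer, method = "radix")
    kmer <- kmer[o]; count <- as.integer(count[o])
    if (anyDuplicated(kmer)) stop("duplicate k-mer keys in table")
  }
  structure(list(kmer = as.character(kmer), count = as.integer(count), k = k),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: %d distinct %d-mers, total count %s\n",
              length(x$kmer), x$k, format(sum(as.numeric(x$count)))))
  invisible(x)
}

#' @export
length.kmer_table <- function(x) length(x$kmer)

#' Canonical form of a k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement;
#' collapsing strands this way keeps both sequencing orientations of a
#' locus in one key.  K-mers containing N have no canonical form and are
#' rejected.
#'
#' @param seq Character vector of equal-length DNA strings.
#' @return Character vector of canonical k-mers.
#' @export
canonicalize <- function(seq) {
  if (!length(seq)) return(character())
  if (any(grepl("[^ACGT]", seq)))
    stop("canonicalize: k-mers must contain only A/C/G/T")
  rc <- revcomp(seq)
  ifelse(seq <= rc, seq, rc)
}

#' Reverse complement
#'
#' @param seq Character vector of DNA strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(seq) .revcomp_cpp(seq)

#' Count canonical k-mers in a read set
#'
#' Every N-free length-`k` window of every read contributes one count to
#' its canonical k-mer; a read of length L yields L-k+1 windows.  Reads
#' shorter than `k` contribute nothing.
#'
#' @param reads A [read_set()], or a character vector of sequences.
#' @param k K-mer length (<= 31).
#' @return A [kmer_table()] sorted by k-mer.
#' @export
count_kmers <- function(reads, k) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  stopifnot(k >= 1L, k <= 31L)
  res <- .count_kmers_cpp(seqs, as.integer(k))
  structure(list(kmer = res$kmer, count = res$count, k = as.integer(k)),
            class = "kmer_table")
}

#' Drop low-count k-mers (sequencing-error filter)
#'
#' Keeps entries with `count >= min_count`.  In the pipeline this filter
#' is applied to the affected sample only; unaffected samples keep all
#' their k-mers, including singletons, so that a single parental read can
#' veto a candidate.
#'
#' @param table A [kmer_table()].
#' @param min_count Minimum count to keep.
#' @return Filtered [kmer_table()].
#' @export
filter_min_count <- function(table, min_count) {
  stopifnot(inherits(table, "kmer_table"), min_count >= 1L)
  keep <- table$count >= min_count
  structure(list(kmer = table$kmer[keep], count = table$count[keep],
                 k = table$k),
            class = "kmer_table")
}

#' Set subtraction of k-mer tables
#'
#' Entries of `a` whose key is absent from `b`, with counts taken from
#' `a`; `b`'s counts are irrelevant (presence-only veto).  A single
#' linear merge pass over the two sorted tables.
#'
#' @param a,b [kmer_table()]s with the same `k`.
#' @return A [kmer_table()].
#' @export
kmer_subtract <- function(a, b) {
  stopifnot(inherits(a, "kmer_table"), inherits(b, "kmer_table"))
  if (a$k != b$k) stop("kmer_subtract: mismatched k (", a$k, " vs ", b$k, ")")
  keep <- !.sorted_member_cpp(a$kmer, b$kmer)
  structure(list(kmer = a$kmer[keep], count = a$count[keep], k = a$k),
            class = "kmer_table")
}

#' Set intersection of k-mer tables
#'
#' Keys present in both tables, counts taken from `a`.
#'
#' @param a,b [kmer_table()]s with the same `k`.
#' @return A [kmer_table()].
#' @export
kmer_intersect <- function(a, b) {
  stopifnot(inherits(a, "kmer_table"), inherits(b, "kmer_table"))
  if (a$k != b$k) stop("kmer_intersect: mismatched k (", a$k, " vs ", b$k, ")")
  keep <- .sorted_member_cpp(a$kmer, b$kmer)
  structure(list(kmer = a$kmer[keep], count = a$count[keep], k = a$k),
            class = "kmer_table")
}

#' Read/write k-mer tables as sorted TSV
#'
#' On-disk format: one `KMER<TAB>COUNT` line per entry, sorted by k-mer,
#' so tables can be diffed and merged as streams.
#'
#' @param table A [kmer_table()].
#' @param path File path.
#' @return `write_kmer_table` returns `path` invisibly; `read_kmer_table`
#'   returns a [kmer_table()].
#' @export
write_kmer_table <- function(table, path) {
  writeLines(sprintf("%s\t%d", table$kmer, table$count), path)
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty k-mer table file (k unknown): ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kmer_table(vapply(parts, `[[`, character(1), 1L),
             as.integer(vapply(parts, `[[`, character(1), 2L)),
             k = nchar(parts[[1L]][1L]))
}
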