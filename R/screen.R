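# Screens: removal of vector-derived and reference-derived k-mers from the
# proband spectrum, and removal of vector-containing reads from the
# harvested candidate set.

#' Build a presence screen from a FASTA
#'
#' Computes the canonical k-mer set of a screening sequence collection: a
#' vector database, or the targeted regions of the reference genome.  When
#' `intervals` are given, only windows fully inside each interval padded
#' by k-1 on each side are included, so windows spanning a target edge are
#' still represented.  A k-mer present in any screen is, by construction,
#' not unique to the affected sample and cannot be the mutation sought.
#'
#' @param fasta Named character vector of sequences (or path to a FASTA).
#' @param k K-mer length.
#' @param intervals Optional interval data frame (`chrom`, `start`, `end`,
#'   0-based half-open) restricting the screen to targeted regions.
#' @param label Provenance label carried in the result.
#' @return A `screen_set`: a [kmer_table()] with a `label` attribute
#'   (counts are irrelevant; the screen is presence-only).
#' @export
build_screen_set <- function(fasta, k, intervals = NULL, label = "screen") {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta(fasta) else fasta
  if (!is.null(intervals) && nrow(intervals)) {
    missing_chrom <- setdiff(intervals$chrom, names(seqs))
    if (length(missing_chrom))
      stop("screen intervals reference unknown sequences: ",
           paste(missing_chrom, collapse = ", "))
    too_far <- intervals$end > nchar(seqs[intervals$chrom])
    if (any(too_far))
      stop("screen interval beyond end of sequence ",
           intervals$chrom[which(too_far)[1L]])
    pad <- k - 1L
    sub <- character(nrow(intervals))
    for (i in seq_len(nrow(intervals))) {
      s <- max(0L, intervals$start[i] - pad)
      e <- min(nchar(seqs[[intervals$chrom[i]]]), intervals$end[i] + pad)
      sub[i] <- substring(seqs[[intervals$chrom[i]]], s + 1L, e)
    }
    seqs <- sub
  }
  tab <- count_kmers(unname(seqs), k)
  attr(tab, "label") <- label
  class(tab) <- c("screen_set", "kmer_table")
  tab
}

#' Subtract a list of screens from a k-mer table
#'
#' Sequential presence-based subtraction; the result is independent of
#' screen order.
#'
#' @param table Proband [kmer_table()].
#' @param screens List of screen sets (from [build_screen_set()]).
#' @return Filtered [kmer_table()].
#' @export
subtract_screens <- function(table, screens) {
  for (s in screens) table <- kmer_subtract(table, s)
  table
}

#' Remove vector-contaminated reads
#'
#' A read is flagged as vector-derived if it shares an exact match of at
#' least `seed_len` bases with any vector sequence on either strand, or
#' has a local alignment to a vector of at least `min_aln_len` columns at
#' `min_identity` or better.  Intended for the harvested candidate read
#' set, which is small.
#'
#' @param reads A [read_set()].
#' @param vector_db Named character vector of vector sequences (may be
#'   empty).
#' @param seed_len Exact shared-substring length that triggers removal.
#' @param min_aln_len,min_identity Local-alignment removal thresholds.
#' @param config Optional [pipeline_config()] supplying alignment scores
#'   and defaults for the above.
#' @return List with `clean` (kept [read_set()]), `removed` (removed
#'   [read_set()]), and `log` (data frame: read id, vector id, rule).
#' @export
screen_reads_for_vector <- function(reads, vector_db,
                                    seed_len = NULL, min_aln_len = NULL,
                                    min_identity = NULL,
                                    config = pipeline_config()) {
  seed_len <- seed_len %||% config$vector_seed_len
  min_aln_len <- min_aln_len %||% config$vector_min_aln_len
  min_identity <- min_identity %||% config$vector_min_identity
  n <- nrow(reads)
  if (n == 0L || length(vector_db) == 0L) {
    return(list(clean = reads, removed = reads[integer(0), , drop = FALSE],
                log = data.frame(read_id = character(), vector_id = character(),
                                 rule = character(), stringsAsFactors = FALSE)))
  }
  hit_id <- rep(NA_character_, n)
  hit_rule <- rep(NA_character_, n)
  # exact seed: a shared substring of length >= seed_len on either strand
  # is equivalent to a shared canonical seed_len-mer
  for (v in names(vector_db)) {
    vk <- count_kmers(vector_db[[v]], seed_len)
    hits <- .kmer_hits_cpp(reads$seq, as.integer(seed_len), vk$kmer)
    idx <- hits$index[is.na(hit_id[hits$index])]
    hit_id[idx] <- v
    hit_rule[idx] <- "exact_seed"
  }
  # local alignment branch for divergent vector fragments
  todo <- which(is.na(hit_id))
  for (i in todo) {
    for (v in names(vector_db)) {
      a <- .align_to_target_cpp(reads$seq[i], vector_db[[v]],
                                config$match, config$mismatch,
                                config$gap_open, config$gap_extend)
      if (a$columns[1L] >= min_aln_len &&
          a$matches[1L] / a$columns[1L] >= min_identity) {
        hit_id[i] <- v
        hit_rule[i] <- "local_alignment"
        break
      }
    }
  }
  removed <- !is.na(hit_id)
  list(clean = reads[!removed, , drop = FALSE],
       removed = reads[removed, , drop = FALSE],
       log = data.frame(read_id = reads$id[removed],
                        vector_id = hit_id[removed],
                        rule = hit_rule[removed],
                        stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
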