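# Tracing candidate k-mers back to the reads that contain them.  The
# k-mer counter does not remember read provenance, so after the spectrum
# algebra the surviving k-mers are matched back against the original
# proband reads in one streaming pass over an in-memory presence index.

#' Harvest reads containing candidate k-mers
#'
#' Returns exactly the reads with at least one N-free window whose
#' canonical form is a key of `candidates`, together with the matched
#' k-mers per read.
#'
#' @param reads A [read_set()] (the full proband read set).
#' @param candidates A [kmer_table()] of surviving proband-unique k-mers.
#' @return A `candidate_reads` object: the harvested [read_set()] with a
#'   list column `matches` of matched canonical k-mers.
#' @export
harvest_reads <- function(reads, candidates) {
  stopifnot(inherits(candidates, "kmer_table"))
  if (length(candidates) == 0L)
    stop("harvest_reads: empty candidate table")
  hits <- .kmer_hits_cpp(reads$seq, candidates$k, candidates$kmer)
  out <- reads[hits$index, , drop = FALSE]
  out$matches <- I(hits$matches)
  rownames(out) <- NULL
  class(out) <- c("candidate_reads", "read_set", "data.frame")
  out
}

#' Write the read-to-k-mer match table
#'
#' @param harvested A `candidate_reads` object from [harvest_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_harvest_log <- function(harvested, path) {
  df <- data.frame(
    read_id = rep(harvested$id, lengths(harvested$matches)),
    kmer = unlist(harvested$matches, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
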