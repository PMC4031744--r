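#' Pipeline configuration
#'
#' Bundles every tunable threshold of the direct-comparison pipeline.  The
#' defaults are the operating point for deep exome-style data (roughly
#' 80--100x coverage): a novel heterozygous mutation then carries 40--50x
#' coverage, so k-mers supported by fewer than `min_count` proband reads are
#' overwhelmingly sequencing errors, while true-variant k-mers survive with
#' a wide margin.
#'
#' @param k K-mer length; odd, between 11 and 31 so a k-mer fits two bits
#'   per base in a single machine word.
#' @param min_count Minimum proband k-mer count.  K-mers seen fewer than
#'   `min_count` times in the affected sample are discarded as sequencing
#'   errors.  Applied to the affected sample only: unaffected samples keep
#'   even singleton k-mers so one parental read can veto a candidate.
#' @param min_reads_per_contig Contigs supported by fewer reads (after
#'   merging co-located contigs) are dropped.
#' @param min_variant_fraction Variants whose supporting-read fraction is
#'   not strictly greater than this are dropped; lowering it admits mosaic
#'   variants carried by a minority of cells.
#' @param read_length_hint Read length used to extend placed contigs when
#'   collecting parental evidence.
#' @param min_parent_depth Minimum read depth each unaffected sample must
#'   provide at every putative mutation column for a contig to survive the
#'   capture-dropout filter.
#' @param min_overlap,max_mismatch_frac Greedy assembler: minimum
#'   suffix-prefix overlap and maximum mismatch fraction within an overlap.
#' @param vector_seed_len Exact-match length that flags a read as
#'   vector-contaminated.
#' @param vector_min_aln_len,vector_min_identity Local-alignment branch of
#'   the vector screen: minimum alignment length and identity.
#' @param match,mismatch,gap_open,gap_extend Alignment scores used by
#'   contig placement, parental re-alignment, and the pileup aligner.
#' @param min_place_identity,min_place_qcov Contig placement is accepted
#'   only at this identity over at least this fraction of the contig.
#' @param min_realign_identity Parental/proband reads aligned to an
#'   extended contig window are kept only at this identity.
#' @param rng_seed Seed recorded in run manifests (the pipeline itself is
#'   deterministic; only the simulator consumes randomness).
#'
#' @return A list of class `denovok_config`.
#' @export
pipeline_config <- function(k = 27L,
                            min_count = 10L,
                            min_reads_per_contig = 4L,
                            min_variant_fraction = 0.05,
                            read_length_hint = 100L,
                            min_parent_depth = 1L,
                            min_overlap = 31L,
                            max_mismatch_frac = 0.02,
                            vector_seed_len = 18L,
                            vector_min_aln_len = 25L,
                            vector_min_identity = 0.90,
                            match = 1L, mismatch = -2L,
                            gap_open = -4L, gap_extend = -1L,
                            min_place_identity = 0.80,
                            min_place_qcov = 0.50,
                            min_realign_identity = 0.90,
                            rng_seed = 1L) {
  k <- as.integer(k)
  stopifnot(k %% 2L == 1L, k >= 11L, k <= 31L)
  stopifnot(min_count >= 2L)
  stopifnot(min_variant_fraction > 0, min_variant_fraction < 1)
  stopifnot(min_reads_per_contig >= 1L, min_parent_depth >= 0L)
  cfg <- list(
    k = k, min_count = as.integer(min_count),
    min_reads_per_contig = as.integer(min_reads_per_contig),
    min_variant_fraction = min_variant_fraction,
    read_length_hint = as.integer(read_length_hint),
    min_parent_depth = as.integer(min_parent_depth),
    min_overlap = as.integer(min_overlap),
    max_mismatch_frac = max_mismatch_frac,
    vector_seed_len = as.integer(vector_seed_len),
    vector_min_aln_len = as.integer(vector_min_aln_len),
    vector_min_identity = vector_min_identity,
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    min_place_identity = min_place_identity,
    min_place_qcov = min_place_qcov,
    min_realign_identity = min_realign_identity,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "denovok_config"
  cfg
}

#' @export
print.denovok_config <- function(x, ...) {
  cat("denovok pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
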