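# Capture-dropout elimination.  A heterozygous site captured in the child
# but missed by the exome capture in one parent masquerades as a de novo
# mutation.  Each surviving contig is therefore widened into a reference
# window, reads from every unaffected sample are re-aligned to it, reads
# with a better placement elsewhere in the genome are discarded, and the
# contig is kept only if every putative mutation column is covered by all
# unaffected samples.

#' Extend a placed contig into a reference window
#'
#' A placed contig is widened by one read length on each side (clamped to
#' the chromosome) so reads that only partially overlap the contig can
#' still be captured; an unplaced contig is used as its own window,
#' unextended.
#'
#' @param contig A `contig` (placement attempted).
#' @param reference Named character vector of reference sequences.
#' @param read_length Extension length (one read).
#' @return An `extended_contig`: the contig plus window coordinates,
#'   window sequence and the putative mutation columns (reference
#'   positions, 0-based) derived from the contig-versus-reference edit
#'   script.
#' @export
extend_contig <- function(contig, reference, read_length = 100L) {
  if (is.null(contig$placement)) {
    ec <- list(contig = contig, placed = FALSE, chrom = NA_character_,
               wstart = 0L, wend = nchar(contig$seq),
               window = contig$seq, mutation_cols = integer(0))
  } else {
    pl <- contig$placement
    clen <- nchar(reference[[pl$chrom]])
    wstart <- max(0L, pl$start - read_length)
    wend <- min(clen, pl$end + read_length)
    ec <- list(contig = contig, placed = TRUE, chrom = pl$chrom,
               wstart = as.integer(wstart), wend = as.integer(wend),
               window = substring(reference[[pl$chrom]], wstart + 1L, wend),
               mutation_cols = mutation_columns(contig, reference))
  }
  class(ec) <- "extended_contig"
  ec
}

#' Putative mutation columns of a placed contig
#'
#' Walks the placement edit script and returns the reference positions
#' (0-based) where the contig differs from the reference: mismatch
#' columns, deleted reference bases, and the two positions flanking an
#' insertion.
#'
#' @param contig A placed `contig`.
#' @param reference Named character vector of reference sequences.
#' @return Sorted integer vector of reference positions.
#' @export
mutation_columns <- function(contig, reference) {
  pl <- contig$placement
  if (is.null(pl)) return(integer(0))
  refseq <- reference[[pl$chrom]]
  ops <- parse_cigar(pl$cigar)
  qpos <- pl$qstart  # 0-based on oriented contig
  rpos <- pl$start
  cols <- integer(0)
  qseq <- pl$oseq
  for (i in seq_len(nrow(ops))) {
    n <- ops$len[i]
    switch(ops$op[i],
      M = {
        qb <- substring(qseq, qpos + 1L, qpos + n)
        rb <- substring(refseq, rpos + 1L, rpos + n)
        if (qb != rb) {
          qv <- strsplit(qb, "", fixed = TRUE)[[1L]]
          rv <- strsplit(rb, "", fixed = TRUE)[[1L]]
          cols <- c(cols, rpos + which(qv != rv) - 1L)
        }
        qpos <- qpos + n; rpos <- rpos + n
      },
      I = {  # insertion in contig: flag the flanking reference bases
        cols <- c(cols, rpos - 1L, rpos)
        qpos <- qpos + n
      },
      D = {  # contig lacks these reference bases
        cols <- c(cols, rpos:(rpos + n - 1L))
        rpos <- rpos + n
      })
  }
  sort(unique(cols[cols >= 0L]))
}

parse_cigar <- function(cigar) {
  if (!nzchar(cigar)) return(data.frame(len = integer(), op = character()))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MID]", cigar))[[1L]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Align reads from an unaffected sample to extended contigs
#'
#' Seed-and-extend: reads sharing an exact canonical k-mer with a window
#' are locally aligned to it (both orientations); alignments below
#' `min_realign_identity` over the aligned span are discarded.
#'
#' @param reads A [read_set()] (all reads of one sample).
#' @param targets List of `extended_contig`s.
#' @param config A [pipeline_config()].
#' @return List (parallel to `targets`) of alignment data frames with
#'   columns `read_id`, `strand`, `score`, `qstart`, `qend`, `tstart`,
#'   `tend` (window coordinates), `matches`, `columns`, `cigar`, `oseq`
#'   (read as aligned).
#' @export
align_unaffected_reads <- function(reads, targets,
                                   config = pipeline_config()) {
  lapply(targets, function(tg) {
    wk <- count_kmers(tg$window, config$k)
    empty <- data.frame(read_id = character(), strand = character(),
                        score = integer(), qstart = integer(),
                        qend = integer(), tstart = integer(),
                        tend = integer(), matches = integer(),
                        columns = integer(), cigar = character(),
                        oseq = character(), stringsAsFactors = FALSE)
    if (length(wk) == 0L || nrow(reads) == 0L) return(empty)
    hits <- .kmer_hits_cpp(reads$seq, config$k, wk$kmer)
    if (!length(hits$index)) return(empty)
    sub <- reads[hits$index, , drop = FALSE]
    a <- .align_to_target_cpp(sub$seq, tg$window, config$match,
                              config$mismatch, config$gap_open,
                              config$gap_extend)
    a$read_id <- sub$id
    a$oseq <- ifelse(a$strand == "-", revcomp(sub$seq), sub$seq)
    keep <- a$columns > 0L & a$matches / pmax(a$columns, 1L) >=
      config$min_realign_identity
    a <- a[keep, c("read_id", "strand", "score", "qstart", "qend",
                   "tstart", "tend", "matches", "columns", "cigar",
                   "oseq"), drop = FALSE]
    rownames(a) <- NULL
    a
  })
}

#' Discard reads that align better elsewhere in the genome
#'
#' Each read retained against a target window is re-aligned to the whole
#' reference; if its best score at a locus not overlapping the window
#' strictly exceeds its window score, the read is discarded (a tie keeps
#' the read).
#'
#' @param alignments One alignment data frame from
#'   [align_unaffected_reads()].
#' @param reads The sample's [read_set()] (source of read sequences).
#' @param target The corresponding `extended_contig`.
#' @param index A [reference_index()].
#' @param config A [pipeline_config()].
#' @return The alignment data frame with better-placed reads removed; the
#'   number removed is recorded in attribute `n_discarded`.
#' @export
better_placement_check <- function(alignments, reads, target, index,
                                   config = pipeline_config()) {
  if (nrow(alignments) == 0L) {
    attr(alignments, "n_discarded") <- 0L
    return(alignments)
  }
  seqs <- reads$seq[match(alignments$read_id, reads$id)]
  keep <- rep(TRUE, nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    g <- seed_align(index, seqs[i], config)
    if (nrow(g) == 0L) next
    if (target$placed) {
      away <- !(g$ref == target$chrom &
                g$rstart < target$wend & g$rend > target$wstart)
    } else {
      away <- rep(TRUE, nrow(g))
    }
    if (any(away) && max(g$score[away]) > alignments$score[i])
      keep[i] <- FALSE
  }
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# M-op coverage over window columns for one alignment data frame.
window_coverage <- function(alignments, window_len) {
  cov <- integer(window_len)
  for (i in seq_len(nrow(alignments))) {
    ops <- parse_cigar(alignments$cigar[i])
    tpos <- alignments$tstart[i]
    for (j in seq_len(nrow(ops))) {
      n <- ops$len[j]
      if (ops$op[j] == "M") {
        cov[(tpos + 1L):(tpos + n)] <- cov[(tpos + 1L):(tpos + n)] + 1L
        tpos <- tpos + n
      } else if (ops$op[j] == "D") {
        tpos <- tpos + n
      }
    }
  }
  cov
}

#' Require parental coverage at every putative mutation column
#'
#' A placed contig survives only if every putative mutation column is
#' covered by at least `min_parent_depth` retained reads from each
#' unaffected sample; capture dropout in any one sample removes it.  A
#' placed contig with no mutation column (a perfect reference match) is a
#' vacuous candidate and is removed.  Unplaced contigs are never filtered
#' here; they are routed to the separate novel-sequence report.
#'
#' @param targets List of `extended_contig`s.
#' @param parent_alignments List (one element per unaffected sample) of
#'   alignment lists as returned by [align_unaffected_reads()] (after
#'   [better_placement_check()]).
#' @param min_parent_depth Minimum depth per sample per mutation column.
#' @return List with `surviving`, `removed`, `vacuous`, `unplaced` (lists
#'   of `extended_contig`s) and `audit` (one row per placed contig:
#'   mutation columns, minimum depth per unaffected sample over those
#'   columns, decision).
#' @export
parental_coverage_filter <- function(targets, parent_alignments,
                                     min_parent_depth = 1L) {
  surviving <- removed <- vacuous <- unplaced <- list()
  audit <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[[ti]]
    if (!tg$placed) { unplaced <- c(unplaced, list(tg)); next }
    if (length(tg$mutation_cols) == 0L) {
      vacuous <- c(vacuous, list(tg))
      audit[[length(audit) + 1L]] <- data.frame(
        contig = tg$contig$id, mutation_cols = "",
        min_depth = "", decision = "vacuous", stringsAsFactors = FALSE)
      next
    }
    wlen <- nchar(tg$window)
    wcols <- tg$mutation_cols - tg$wstart
    wcols <- wcols[wcols >= 0L & wcols < wlen]
    min_depths <- vapply(parent_alignments, function(pa) {
      d <- window_coverage(pa[[ti]], wlen)
      min(d[wcols + 1L])
    }, numeric(1))
    covered <- length(wcols) > 0L && all(min_depths >= min_parent_depth)
    audit[[length(audit) + 1L]] <- data.frame(
      contig = tg$contig$id,
      mutation_cols = paste(tg$mutation_cols, collapse = ","),
      min_depth = paste(min_depths, collapse = ","),
      decision = if (covered) "kept" else "removed",
      stringsAsFactors = FALSE)
    if (covered) surviving <- c(surviving, list(tg))
    else removed <- c(removed, list(tg))
  }
  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(contig = character(), mutation_cols = character(),
               min_depth = character(), decision = character(),
               stringsAsFactors = FALSE)
  list(surviving = surviving, removed = removed, vacuous = vacuous,
       unplaced = unplaced, audit = audit_df)
}
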