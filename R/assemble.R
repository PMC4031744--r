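# Micro-assembly of harvested reads into short contigs.  Every harvested
# read contains a candidate k-mer spanning the putative mutation, so reads
# belonging to one mutation all overlap it and a greedy overlap-layout-
# consensus assembler with a hard 2L-1 length cap is sufficient: with
# reads of length at most L, two reads sharing at least one column can
# span at most 2L-1 columns.

new_contig <- function(id, layout) {
  layout <- layout[order(layout$offset, layout$id), , drop = FALSE]
  rownames(layout) <- NULL
  cons <- layout_consensus(layout)
  structure(list(id = id, seq = cons$seq, depth = cons$depth,
                 layout = layout, support = unique(layout$id),
                 placement = NULL),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig %s: %d bp, %d reads%s\n", x$id, nchar(x$seq),
              length(x$support),
              if (is.null(x$placement)) ", unplaced" else
                sprintf(", placed %s:%d-%d(%s)", x$placement$chrom,
                        x$placement$start, x$placement$end,
                        x$placement$strand)))
  invisible(x)
}

# Majority consensus over a gapless layout.  Ties go to the base of the
# deepest-coverage (longest-laid) read, then to the lexicographically
# smallest base.
layout_consensus <- function(layout) {
  len <- max(layout$offset + nchar(layout$seq))
  counts <- matrix(0L, 4L, len, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(layout))) {
    b <- strsplit(layout$seq[i], "", fixed = TRUE)[[1L]]
    pos <- layout$offset[i] + seq_along(b)
    known <- b %in% rownames(counts)
    idx <- cbind(match(b[known], rownames(counts)), pos[known])
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
  }
  depth <- colSums(counts)
  best <- apply(counts, 2L, max)
  cons <- character(len)
  # deepest-coverage read, used to break per-column ties
  deep <- which.max(nchar(layout$seq))
  deep_b <- strsplit(layout$seq[deep], "", fixed = TRUE)[[1L]]
  deep_pos <- layout$offset[deep] + seq_along(deep_b)
  deep_at <- rep(NA_character_, len)
  deep_at[deep_pos] <- deep_b
  for (j in seq_len(len)) {
    tied <- rownames(counts)[counts[, j] == best[j]]
    cons[j] <- if (length(tied) == 1L) tied
               else if (!is.na(deep_at[j]) && deep_at[j] %in% tied) deep_at[j]
               else tied[1L]
  }
  list(seq = paste(cons, collapse = ""), depth = as.integer(depth))
}

# Merge two contigs under one of the four suffix-prefix configurations
# reported by the overlap scanner (1: a->b, 2: b->a, 3: a->rc(b),
# 4: rc(b)->a).
merge_layouts <- function(a, b, conf, olen) {
  flip <- function(lay, total) {
    lay$seq <- revcomp(lay$seq)
    lay$offset <- total - (lay$offset + nchar(lay$seq))
    lay
  }
  la <- nchar(a$seq); lb <- nchar(b$seq)
  bl <- b$layout
  if (conf %in% c(3L, 4L)) bl <- flip(bl, lb)
  if (conf == 1L || conf == 3L) {        # a-suffix onto b-prefix
    bl$offset <- bl$offset + (la - olen)
    lay <- rbind(a$layout, bl)
  } else {                               # b-suffix onto a-prefix
    al <- a$layout
    al$offset <- al$offset + (lb - olen)
    lay <- rbind(bl, al)
  }
  lay
}

# Greedy merging over a list of contigs: repeatedly merge the pair with
# the longest admissible suffix-prefix overlap; ties are broken by the
# lexicographically smaller merged consensus, then by smallest read id.
greedy_merge <- function(items, min_overlap, max_mismatch_frac, max_len) {
  n <- length(items)
  if (n <= 1L) return(items)
  best_pair <- function(i, j) {
    m <- .overlap_pair_cpp(items[[i]]$seq, items[[j]]$seq,
                           min_overlap, max_mismatch_frac)
    m
  }
  ov <- matrix(0L, n, n)
  ovconf <- matrix(0L, n, n)
  fill <- function(i, j) {
    m <- best_pair(i, j)
    o <- max(m[, 1L])
    ov[i, j] <<- o
    ovconf[i, j] <<- if (o > 0L) which.max(m[, 1L]) else 0L
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) fill(i, j)
  alive <- rep(TRUE, n)
  repeat {
    o <- max(ov)
    if (o < min_overlap || o == 0L) break
    cand <- which(ov == o, arr.ind = TRUE)
    # evaluate tied merges; pick the lexicographically smallest consensus
    merged <- vector("list", nrow(cand))
    keys <- character(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      lay <- merge_layouts(items[[i]], items[[j]], ovconf[i, j], o)
      ctg <- new_contig(items[[i]]$id, lay)
      merged[[r]] <- ctg
      keys[r] <- paste0(ctg$seq, "\r", min(ctg$support))
    }
    ok <- vapply(merged, function(m) nchar(m$seq) <= max_len, logical(1))
    if (!any(ok)) {
      for (r in seq_len(nrow(cand))) ov[cand[r, 1L], cand[r, 2L]] <- 0L
      next
    }
    r <- which(ok)[order(keys[ok], method = "radix")][1L]
    i <- cand[r, 1L]; j <- cand[r, 2L]
    items[[i]] <- merged[[r]]
    alive[j] <- FALSE
    ov[j, ] <- 0L; ov[, j] <- 0L
    ov[i, ] <- 0L; ov[, i] <- 0L
    for (x in which(alive)) {
      if (x == i) next
      a <- min(x, i); b <- max(x, i)
      fill(a, b)
    }
  }
  items[alive]
}

#' Assemble candidate reads into short contigs
#'
#' Greedy overlap-layout-consensus over the harvested, vector-screened
#' reads.  Reads are first clustered by shared candidate k-mers (when the
#' input carries a `matches` column) and assembled per cluster; a second
#' greedy pass then merges contigs across clusters under the same rules.
#' Both orientations of every pair are considered.  Reads that never
#' reach an admissible overlap pass through as single-read contigs.
#' Every emitted contig respects the 2L-1 length bound, L being the
#' longest input read: merges that would exceed it are refused.
#'
#' @param reads A [read_set()] (typically `candidate_reads`).
#' @param min_overlap Minimum suffix-prefix overlap.
#' @param max_mismatch_frac Maximum mismatch fraction within an overlap.
#' @return List of `contig` objects.
#' @export
assemble_reads <- function(reads, min_overlap = 31L,
                           max_mismatch_frac = 0.02) {
  if (nrow(reads) == 0L) return(list())
  max_len <- 2L * max(nchar(reads$seq)) - 1L
  # cluster reads sharing candidate k-mers (union-find)
  comp <- seq_len(nrow(reads))
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (!is.null(reads$matches)) {
    km <- data.frame(read = rep(seq_len(nrow(reads)), lengths(reads$matches)),
                     kmer = unlist(reads$matches, use.names = FALSE),
                     stringsAsFactors = FALSE)
    for (grp in split(km$read, km$kmer)) {
      r0 <- find(grp[1L])
      for (g in grp[-1L]) comp[find(g)] <- r0
    }
  }
  roots <- vapply(seq_len(nrow(reads)), find, integer(1))
  items <- list()
  for (members in split(seq_len(nrow(reads)), roots)) {
    sub <- lapply(members, function(i) {
      new_contig(reads$id[i],
                 data.frame(id = reads$id[i], seq = reads$seq[i],
                            offset = 0L, stringsAsFactors = FALSE))
    })
    items <- c(items, greedy_merge(sub, min_overlap, max_mismatch_frac,
                                   max_len))
  }
  if (length(items) > 1L)
    items <- greedy_merge(items, min_overlap, max_mismatch_frac, max_len)
  # deterministic ids, largest-support contigs first
  o <- order(-vapply(items, function(x) length(x$support), integer(1)),
             vapply(items, function(x) x$seq, character(1)),
             method = "radix")
  items <- items[o]
  for (i in seq_along(items)) items[[i]]$id <- sprintf("ctg%04d", i)
  items
}

#' Build an exact-seed index of the reference
#'
#' @param reference Named character vector of reference sequences.
#' @param k_seed Seed length for exact-match anchoring.
#' @return A `ref_index` handle used by [place_contig()] and the
#'   realignment steps.
#' @export
reference_index <- function(reference, k_seed = 27L) {
  structure(list(ptr = .ref_index_cpp(reference, as.integer(k_seed)),
                 k_seed = as.integer(k_seed),
                 seqnames = names(reference),
                 seqlengths = setNames(nchar(reference), names(reference))),
            class = "ref_index")
}

# All seeded alignments of one sequence against the indexed reference.
seed_align <- function(index, seq, config) {
  .seed_align_cpp(index$ptr, seq, config$match, config$mismatch,
                  config$gap_open, config$gap_extend)
}

#' Place a contig on the reference
#'
#' Seed-and-extend alignment (exact seed hits, diagonal chaining, local
#' gapped extension).  The highest-scoring placement is returned if its
#' identity is at least `min_place_identity` over at least
#' `min_place_qcov` of the contig length; ties go to the leftmost
#' coordinate.  Returns the contig with `placement` set (or left `NULL`).
#'
#' @param contig A `contig`.
#' @param index A [reference_index()].
#' @param config A [pipeline_config()].
#' @return The contig, with `placement` filled in when one qualifies.
#' @export
place_contig <- function(contig, index, config = pipeline_config()) {
  hits <- seed_align(index, contig$seq, config)
  contig$placement <- NULL
  if (nrow(hits) == 0L) return(contig)
  qlen <- nchar(contig$seq)
  hits$identity <- hits$matches / pmax(hits$columns, 1L)
  hits$qcov <- (hits$qend - hits$qstart) / qlen
  hits <- hits[hits$identity >= config$min_place_identity &
               hits$qcov >= config$min_place_qcov, , drop = FALSE]
  if (nrow(hits) == 0L) return(contig)
  hits <- hits[order(-hits$score, hits$ref, hits$rstart), , drop = FALSE]
  h <- hits[1L, ]
  oseq <- if (h$strand == "-") revcomp(contig$seq) else contig$seq
  contig$placement <- list(chrom = h$ref, start = h$rstart, end = h$rend,
                           strand = h$strand, score = h$score,
                           identity = h$identity, cigar = h$cigar,
                           qstart = h$qstart, qend = h$qend, oseq = oseq)
  contig
}

#' Collapse contigs that map to the same location
#'
#' Contigs whose reference placements overlap (same chromosome,
#' intersecting intervals, transitively) are merged: their supporting
#' reads are pooled, re-assembled, and the merged contig is re-placed.
#' If re-assembly of the pooled reads still yields several contigs the
#' deepest one provides the consensus while the supporting-read union is
#' retained.  Unplaced contigs pass through untouched.  The operation is
#' idempotent.
#'
#' @param contigs List of `contig`s (placement already attempted).
#' @param index A [reference_index()].
#' @param config A [pipeline_config()].
#' @return List of `contig`s.
#' @export
merge_colocated <- function(contigs, index, config = pipeline_config()) {
  placed <- vapply(contigs, function(x) !is.null(x$placement), logical(1))
  if (sum(placed) <= 1L) return(contigs)
  p <- contigs[placed]
  meta <- data.frame(
    i = seq_along(p),
    chrom = vapply(p, function(x) x$placement$chrom, character(1)),
    start = vapply(p, function(x) x$placement$start, numeric(1)),
    end = vapply(p, function(x) x$placement$end, numeric(1)))
  groups <- list()
  for (g in split(meta, meta$chrom)) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    cur <- g$i[1L]; cur_end <- g$end[1L]
    if (nrow(g) > 1L) for (r in 2L:nrow(g)) {
      if (g$start[r] < cur_end) {  # >=1 bp overlap
        cur <- c(cur, g$i[r]); cur_end <- max(cur_end, g$end[r])
      } else {
        groups <- c(groups, list(cur))
        cur <- g$i[r]; cur_end <- g$end[r]
      }
    }
    groups <- c(groups, list(cur))
  }
  out <- list()
  for (grp in groups) {
    if (length(grp) == 1L) { out <- c(out, p[grp]); next }
    lay <- do.call(rbind, lapply(p[grp], function(x) x$layout))
    lay <- lay[!duplicated(lay$id), , drop = FALSE]
    reads <- read_set(lay$id, lay$seq)
    max_len <- 2L * max(nchar(reads$seq)) - 1L
    items <- lapply(seq_len(nrow(reads)), function(i) {
      new_contig(reads$id[i],
                 data.frame(id = reads$id[i], seq = reads$seq[i],
                            offset = 0L, stringsAsFactors = FALSE))
    })
    merged <- greedy_merge(items, config$min_overlap,
                           config$max_mismatch_frac, max_len)
    best <- merged[[which.max(vapply(merged, function(x)
      length(x$support), integer(1)))]]
    best$id <- p[[grp[1L]]]$id
    best$support <- sort(unique(lay$id))
    best <- place_contig(best, index, config)
    out <- c(out, list(best))
  }
  c(out, contigs[!placed])
}

#' Retain contigs with sufficient read support
#'
#' Applied after merging co-located contigs: a contig survives only if
#' its supporting-read set has at least `min_reads_per_contig` members.
#'
#' @param contigs List of `contig`s.
#' @param min_reads_per_contig Minimum supporting reads.
#' @return Filtered list of `contig`s.
#' @export
filter_min_support <- function(contigs, min_reads_per_contig = 4L) {
  Filter(function(x) length(x$support) >= min_reads_per_contig, contigs)
}
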