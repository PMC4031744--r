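# Readers and writers for the plain-text formats the pipeline touches.
# All coordinates are 0-based half-open internally; only VCF output is
# 1-based.  Gzip-compressed inputs are accepted transparently (base R file
# connections auto-detect compression).

#' Read sets
#'
#' A read set is a data frame with columns `id`, `seq` and (optionally) a
#' list column `qual` of integer Phred scores.
#'
#' @param id,seq,qual Character vectors of identifiers and uppercase DNA
#'   sequences, and an optional list of integer quality vectors.
#' @return A `read_set` data frame.
#' @export
read_set <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    stopifnot(length(qual) == length(seq),
              all(lengths(qual) == nchar(seq)))
    df$qual <- I(qual)
  }
  class(df) <- c("read_set", "data.frame")
  df
}

#' Read a FASTQ file
#'
#' Strict 4-line-per-record FASTQ with Phred+33 qualities.  Qualities are
#' retained for diagnostics only; all downstream filters are count-based.
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return A [read_set()] with qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) return(read_set(character(), character(), list()))
  if (n %% 4L != 0L)
    stop("malformed FASTQ ", path, ": truncated record starting at line ",
         (n %/% 4L) * 4L + 1L)
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ ", path, ": expected '@' header at line ",
         (bad[1L] - 1L) * 4L + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ ", path, ": expected '+' separator at line ",
         (bad[1L] - 1L) * 4L + 3L)
  bad <- which(nchar(seq) != nchar(qual) | nchar(seq) == 0L)
  if (length(bad))
    stop("malformed FASTQ ", path,
         ": sequence/quality length mismatch or empty read at line ",
         (bad[1L] - 1L) * 4L + 2L)
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  quals <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  read_set(ids, seq, quals)
}

#' Write a FASTQ file
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$qual)) {
    vapply(reads$qual, function(q) intToUtf8(q + 33L), character(1))
  } else {
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(rbind(paste0("@", reads$id), reads$seq, "+", qual), con)
  invisible(path)
}

#' Read a (multi-)FASTA file
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(x)), ids)
}

#' Write a (multi-)FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, width = width)
  invisible(path)
}

#' Read a BED file of targeted regions
#'
#' Three or more columns; 0-based half-open.  Overlapping or book-ended
#' intervals on the same chromosome are merged and the result is sorted.
#'
#' @param path Path to a BED file (plain or gzip).
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(V1 = character(), V2 = integer(), V3 = integer()))
      stop(e)
    })
  if (ncol(bed) < 3L) stop("BED file ", path, " has fewer than 3 columns")
  iv <- data.frame(chrom = as.character(bed[[1L]]),
                   start = as.integer(bed[[2L]]),
                   end = as.integer(bed[[3L]]),
                   stringsAsFactors = FALSE)
  bad <- which(iv$start >= iv$end | iv$start < 0L)
  if (length(bad))
    stop("invalid BED interval at line ", bad[1L], " of ", path,
         ": start must satisfy 0 <= start < end")
  merge_intervals(iv)
}

#' Merge and sort genomic intervals
#'
#' @param iv Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return Merged, sorted data frame of the same shape.
#' @export
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(iv, iv$chrom), function(g) {
    r <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    data.frame(chrom = g$chrom[1L], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a BED file
#'
#' @param iv Interval data frame (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  write.table(iv[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tabular gene model
#'
#' A coding-exon table with columns `gene_id`, `transcript_id`, `chrom`,
#' `start`, `end`, `strand` (one row per coding exon, 0-based half-open).
#' Validates that per-transcript exons are non-overlapping and that the
#' total CDS length is divisible by three.
#'
#' @param path Path to the TSV file.
#' @return A `gene_models` data frame.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  gm <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(gm)))
    stop("gene model file must have columns: ", paste(need, collapse = ", "))
  gm$start <- as.integer(gm$start); gm$end <- as.integer(gm$end)
  validate_gene_models(gm)
}

#' @rdname read_gene_models
#' @param gm A gene-model data frame to validate.
#' @export
validate_gene_models <- function(gm) {
  if (any(gm$start >= gm$end)) stop("gene model: exon with start >= end")
  if (!all(gm$strand %in% c("+", "-"))) stop("gene model: strand must be +/-")
  for (tx in split(gm, gm$transcript_id)) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) > 1L && any(tx$start[-1L] < tx$end[-nrow(tx)]))
      stop("gene model: overlapping exons in transcript ",
           tx$transcript_id[1L])
    if (sum(tx$end - tx$start) %% 3L != 0L)
      stop("gene model: CDS length of transcript ", tx$transcript_id[1L],
           " not divisible by 3")
  }
  gm <- gm[order(gm$chrom, gm$start), , drop = FALSE]
  rownames(gm) <- NULL
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Write a tabular gene model
#'
#' @param gm A `gene_models` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  write.table(as.data.frame(gm), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write candidate variants as VCF 4.2
#'
#' Positions are converted from the internal 0-based half-open convention
#' to 1-based VCF coordinates; indel alleles are left-aligned and minimal.
#' Variants without a reference placement are excluded (they belong in the
#' unplaced-contig report) and reported via the `excluded` attribute.
#'
#' @param variants Data frame of candidate variants (as produced by
#'   [pileup_call()]); may be empty.
#' @param reference Named character vector of reference sequences.
#' @param path Output path.
#' @param sample_name Name recorded in the VCF header.
#' @return `path`, invisibly, with attribute `excluded` (number of
#'   placement-less variants dropped).
#' @export
write_vcf <- function(variants, reference, path, sample_name = "proband") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=denovok",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            nchar(reference)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Proband read depth at site\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt-supporting read count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt-supporting read fraction\">",
    "##INFO=<ID=UDP,Number=.,Type=Integer,Description=\"Depth in each unaffected sample at site\">",
    "##INFO=<ID=CODING,Number=1,Type=String,Description=\"coding or noncoding\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Predicted consequence\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  n_excluded <- 0L
  rows <- character(0)
  if (!is.null(variants) && nrow(variants)) {
    placed <- !is.na(variants$chrom) & !is.na(variants$pos)
    n_excluded <- sum(!placed)
    v <- variants[placed, , drop = FALSE]
    if (nrow(v)) {
      norm <- normalize_variants(v, reference)
      info <- sprintf("DP=%d;AC=%d;AF=%.4g", norm$depth, norm$alt_count,
                      norm$fraction)
      if (!is.null(norm$parent_depth))
        info <- paste0(info, ";UDP=", norm$parent_depth)
      if (!is.null(norm$coding))
        info <- paste0(info, ";CODING=", norm$coding,
                       ";CSQ=", norm$consequence)
      ord <- order(norm$chrom, norm$pos)
      rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                      norm$chrom[ord], norm$pos[ord] + 1L, norm$ref[ord],
                      norm$alt[ord], info[ord])
    }
  }
  writeLines(c(hdr, rows), path)
  out <- invisible(path)
  attr(out, "excluded") <- n_excluded
  out
}

#' Left-align and minimalize variant alleles
#'
#' Standard VCF normalization: repeatedly truncate a shared rightmost base
#' (re-extending leftward from the reference when an allele would become
#' empty), then trim shared leading bases.  Input alleles must be
#' non-empty (indels anchored on a reference base).
#'
#' @param variants Data frame with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param reference Named character vector of reference sequences.
#' @return The data frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(variants, reference) {
  last_ch <- function(s) substring(s, nchar(s))
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    stopifnot(nzchar(ref) || nzchar(alt))
    refseq <- reference[[variants$chrom[i]]]
    repeat {
      if (nzchar(ref) && nzchar(alt) && last_ch(ref) == last_ch(alt) &&
          !(nchar(ref) == 1L && nchar(alt) == 1L)) {
        ref <- substring(ref, 1L, nchar(ref) - 1L)
        alt <- substring(alt, 1L, nchar(alt) - 1L)
        if (!nzchar(ref) || !nzchar(alt)) {
          if (pos == 0L) {  # cannot extend left of the chromosome
            anchor_pos <- pos + max(nchar(ref), nchar(alt))
            anchor <- substring(refseq, anchor_pos + 1L, anchor_pos + 1L)
            ref <- paste0(ref, anchor); alt <- paste0(alt, anchor)
            break
          }
          prev <- substring(refseq, pos, pos)  # base at 0-based pos-1
          ref <- paste0(prev, ref)
          alt <- paste0(prev, alt)
          pos <- pos - 1L
        }
        next
      }
      break
    }
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
      ref <- substring(ref, 2L); alt <- substring(alt, 2L)
      pos <- pos + 1L
    }
    variants$pos[i] <- pos
    variants$ref[i] <- ref
    variants$alt[i] <- alt
  }
  variants
}
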