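# Pileup variant calling over surviving contig windows, the mosaic-aware
# supporting-fraction filter, and coding-consequence annotation.

#' Call variants by pileup over surviving contig windows
#'
#' Proband reads aligned to each extended window (same seed-and-extend
#' engine as the parental re-alignment) are stacked per reference column.
#' A variant is emitted where a non-reference allele is supported by at
#' least `min_alt_reads` reads at a column lying within the contig's
#' putative mutation columns.  Indel alleles are anchored on the
#' preceding reference base and left-normalized.  No genotype
#' likelihoods: the pipeline needs positions and alleles, not genotype
#' quality.
#'
#' @param targets List of surviving `extended_contig`s (placed).
#' @param proband_alignments List (parallel to `targets`) of proband
#'   alignment data frames from [align_unaffected_reads()].
#' @param reference Named character vector of reference sequences.
#' @param parent_alignments Optional list of per-sample alignment lists;
#'   used to record per-sample depth at each called site.
#' @param min_alt_reads Minimum alt-supporting reads per emitted variant.
#' @return Data frame of candidate variants: `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `depth`, `alt_count`, `fraction`, `type`,
#'   `parent_depth` (comma-joined per-sample depth), `contig`.
#' @export
pileup_call <- function(targets, proband_alignments, reference,
                        parent_alignments = NULL, min_alt_reads = 2L) {
  out <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[[ti]]
    if (!tg$placed) next
    aln <- proband_alignments[[ti]]
    if (nrow(aln) == 0L) next
    wlen <- nchar(tg$window)
    wref <- strsplit(tg$window, "", fixed = TRUE)[[1L]]
    counts <- matrix(0L, 4L, wlen,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    ins_events <- list()  # key: "anchor|seq"
    del_events <- list()  # key: "start|len"
    for (i in seq_len(nrow(aln))) {
      ops <- parse_cigar(aln$cigar[i])
      tpos <- aln$tstart[i]; qpos <- aln$qstart[i]
      q <- aln$oseq[i]
      for (j in seq_len(nrow(ops))) {
        n <- ops$len[j]
        op <- ops$op[j]
        if (op == "M") {
          b <- strsplit(substring(q, qpos + 1L, qpos + n), "",
                        fixed = TRUE)[[1L]]
          cols <- (tpos + 1L):(tpos + n)
          known <- b %in% rownames(counts)
          for (r in which(known)) {
            bi <- match(b[r], rownames(counts))
            counts[bi, cols[r]] <- counts[bi, cols[r]] + 1L
          }
          tpos <- tpos + n; qpos <- qpos + n
        } else if (op == "I") {
          key <- paste0(tpos - 1L, "|", substring(q, qpos + 1L, qpos + n))
          ins_events[[key]] <- (ins_events[[key]] %||% 0L) + 1L
          qpos <- qpos + n
        } else if (op == "D") {
          key <- paste0(tpos, "|", n)
          del_events[[key]] <- (del_events[[key]] %||% 0L) + 1L
          tpos <- tpos + n
        }
      }
    }
    depth <- colSums(counts)
    wcols <- tg$mutation_cols - tg$wstart
    wcols <- wcols[wcols >= 0L & wcols < wlen]
    mut_set <- wcols
    pdep <- function(wc) {
      if (is.null(parent_alignments)) return(NA_character_)
      paste(vapply(parent_alignments, function(pa) {
        cv <- window_coverage(pa[[ti]], wlen)
        cv[wc + 1L]
      }, numeric(1)), collapse = ",")
    }
    # SNVs
    for (wc in mut_set) {
      rb <- wref[wc + 1L]
      for (b in setdiff(rownames(counts), rb)) {
        ac <- counts[b, wc + 1L]
        if (ac >= min_alt_reads) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = tg$chrom, pos = tg$wstart + wc, ref = rb, alt = b,
            depth = depth[wc + 1L], alt_count = ac,
            fraction = ac / depth[wc + 1L], type = "snv",
            parent_depth = pdep(wc), contig = tg$contig$id,
            stringsAsFactors = FALSE)
        }
      }
    }
    # deletions: read lacks reference bases [d0, d0+len)
    for (key in names(del_events)) {
      if (del_events[[key]] < min_alt_reads) next
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      d0 <- as.integer(parts[1L]); dl <- as.integer(parts[2L])
      if (!any((d0:(d0 + dl - 1L)) %in% mut_set)) next
      anchor <- d0 - 1L
      if (anchor < 0L) next
      dp <- depth[anchor + 1L]
      ac <- del_events[[key]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = tg$chrom, pos = tg$wstart + anchor,
        ref = paste(wref[(anchor + 1L):(d0 + dl)], collapse = ""),
        alt = wref[anchor + 1L],
        depth = dp, alt_count = ac, fraction = ac / max(dp, 1L),
        type = "del", parent_depth = pdep(anchor),
        contig = tg$contig$id, stringsAsFactors = FALSE)
    }
    # insertions: extra read bases between reference columns a and a+1
    for (key in names(ins_events)) {
      if (ins_events[[key]] < min_alt_reads) next
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      a <- as.integer(parts[1L]); iseq <- parts[2L]
      if (!any(c(a, a + 1L) %in% mut_set)) next
      if (a < 0L) next
      dp <- depth[a + 1L]
      ac <- ins_events[[key]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = tg$chrom, pos = tg$wstart + a,
        ref = wref[a + 1L], alt = paste0(wref[a + 1L], iseq),
        depth = dp, alt_count = ac, fraction = ac / max(dp, 1L),
        type = "ins", parent_depth = pdep(a),
        contig = tg$contig$id, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_variants())
  v <- do.call(rbind, out)
  v <- normalize_variants(v, reference)
  # merging windows can duplicate a site; keep one record per allele
  key <- paste(v$chrom, v$pos, v$ref, v$alt)
  v <- v[!duplicated(key), , drop = FALSE]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), depth = integer(), alt_count = integer(),
             fraction = numeric(), type = character(),
             parent_depth = character(), contig = character(),
             stringsAsFactors = FALSE)
}

#' Supporting-fraction filter
#'
#' Keeps variants whose supporting-read fraction is strictly greater
#' than `min_variant_fraction`.  The default 0.05 keeps mosaic variants
#' carried by well under half the reads while rejecting residual noise.
#'
#' @param variants Variant data frame from [pileup_call()].
#' @param min_variant_fraction Strict lower bound on the fraction.
#' @return Filtered data frame.
#' @export
fraction_filter <- function(variants, min_variant_fraction = 0.05) {
  variants[variants$fraction > min_variant_fraction, , drop = FALSE]
}

#' Annotate coding status and consequence
#'
#' SNVs inside a coding exon are classified by translating the affected
#' codon on the coding strand before and after the change (synonymous,
#' missense, nonsense); CDS indels whose length is not a multiple of
#' three are frameshifts; variants within 2 bp of an exon boundary but
#' outside the CDS are splice-proximal; everything else is noncoding.
#'
#' @param variants Variant data frame (normalized).
#' @param gene_models A `gene_models` data frame ([read_gene_models()]).
#' @param reference Named character vector of reference sequences.
#' @param splice_window Distance in bp from an exon boundary that counts
#'   as splice-proximal.
#' @return The data frame with `coding` and `consequence` columns added.
#' @export
annotate_consequence <- function(variants, gene_models, reference,
                                 splice_window = 2L) {
  variants$coding <- rep("noncoding", nrow(variants))
  variants$consequence <- rep(NA_character_, nrow(variants))
  if (!nrow(variants)) return(variants)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(variants))) {
    chrom <- variants$chrom[i]
    pos <- variants$pos[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    is_indel <- nchar(ref) != nchar(alt)
    # affected reference span (for an anchored indel, the event follows
    # the anchor base)
    ev_start <- if (is_indel) pos + 1L else pos
    ev_end <- if (is_indel) pos + max(nchar(ref) - 1L, 1L) else pos + 1L
    hit <- gene_models[gene_models$chrom == chrom &
                       gene_models$start < ev_end &
                       gene_models$end > ev_start, , drop = FALSE]
    if (nrow(hit)) {
      variants$coding[i] <- "coding"
      if (is_indel) {
        indel_len <- abs(nchar(ref) - nchar(alt))
        variants$consequence[i] <-
          if (indel_len %% 3L != 0L) "frameshift" else NA_character_
        next
      }
      tx <- gene_models[gene_models$transcript_id ==
                          hit$transcript_id[1L], , drop = FALSE]
      variants$consequence[i] <-
        classify_snv(pos, ref, alt, tx, reference[[chrom]], code)
      next
    }
    near <- gene_models[gene_models$chrom == chrom &
                        (abs(gene_models$start - pos) <= splice_window |
                         abs(gene_models$end - 1L - pos) <= splice_window),
                        , drop = FALSE]
    if (nrow(near)) variants$consequence[i] <- "splice-proximal"
  }
  variants
}

# Consequence of one coding SNV against one transcript's exon set.
classify_snv <- function(pos, ref, alt, tx, refseq, code) {
  tx <- tx[order(tx$start), , drop = FALSE]
  # CDS coordinate of pos on the genome-forward concatenation
  exon_of <- which(tx$start <= pos & pos < tx$end)
  if (!length(exon_of)) return(NA_character_)
  before <- if (exon_of > 1L)
    sum(tx$end[seq_len(exon_of - 1L)] - tx$start[seq_len(exon_of - 1L)])
  else 0L
  cds_fwd <- before + (pos - tx$start[exon_of])
  cds_len <- sum(tx$end - tx$start)
  cds_seq <- paste(substring(refseq, tx$start + 1L, tx$end), collapse = "")
  if (tx$strand[1L] == "+") {
    cds_idx <- cds_fwd                      # 0-based along coding strand
    coding <- cds_seq
    coding_alt <- alt
    coding_ref <- ref
  } else {
    cds_idx <- cds_len - 1L - cds_fwd
    coding <- as.character(revcomp(cds_seq))
    coding_alt <- revcomp(alt)
    coding_ref <- revcomp(ref)
  }
  codon_i <- cds_idx %/% 3L
  off <- cds_idx %% 3L
  codon <- substring(coding, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (substring(codon, off + 1L, off + 1L) != coding_ref)
    return(NA_character_)  # allele inconsistent with reference; no call
  codon_mut <- codon
  substring(codon_mut, off + 1L, off + 1L) <- coding_alt
  aa0 <- code[[codon]]
  aa1 <- code[[codon_mut]]
  if (aa0 == aa1) "synonymous"
  else if (aa1 == "*") "nonsense"
  else "missense"
}

#' Write the final reports
#'
#' A VCF of surviving variants, a TSV funnel report of per-step counts,
#' and a FASTA of contigs that could not be placed on the reference
#' (candidate mutations in sequence absent from the reference; reported
#' separately for manual review).
#'
#' @param variants Final variant data frame.
#' @param unplaced List of unplaced `extended_contig`s (or `contig`s).
#' @param reference Named character vector of reference sequences.
#' @param funnel Data frame with columns `step` and `count`.
#' @param out_dir Output directory (created if needed).
#' @param sample_name Name recorded in the VCF.
#' @return Named list of written paths.
#' @export
final_report <- function(variants, unplaced, reference, funnel, out_dir,
                         sample_name = "proband") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(out_dir, "variants.vcf")
  write_vcf(variants, reference, vcf, sample_name)
  fun <- file.path(out_dir, "funnel.tsv")
  write.table(funnel, fun, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(out_dir, "unplaced_contigs.fasta")
  useqs <- vapply(unplaced, function(u) {
    if (!is.null(u$contig)) u$contig$seq else u$seq
  }, character(1))
  names(useqs) <- vapply(unplaced, function(u) {
    if (!is.null(u$contig)) u$contig$id else u$id
  }, character(1))
  if (length(useqs)) write_fasta(useqs, fa) else writeLines(character(), fa)
  list(vcf = vcf, funnel = fun, unplaced_fasta = fa)
}
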