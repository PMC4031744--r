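# End-to-end orchestration of the ten pipeline steps for trio and pair
# mode.  The pipeline itself consumes no randomness: rerunning any step
# on the same inputs reproduces its outputs exactly.

funnel_row <- function(step, count)
  data.frame(step = step, count = as.numeric(count),
             stringsAsFactors = FALSE)

#' Run the direct-comparison pipeline
#'
#' Executes the ten steps: k-mer counting of every sample; error-count
#' filtering of the affected sample's spectrum; vector and
#' reference-target k-mer screens; subtraction of every unaffected
#' sample; read harvest; read-level vector screen; micro-assembly;
#' placement, merging and the read-support filter; parental re-alignment
#' with the better-placement discard and the coverage (capture-dropout)
#' filter; pileup calling, the supporting-fraction filter and consequence
#' annotation.  `run_trio()` takes two unaffected samples (the parents),
#' `run_pair()` one (matched normal tissue).
#'
#' @param proband,mother,father,diseased,normal [read_set()]s, or paths
#'   to FASTQ files.
#' @param reference Named character vector of reference sequences, or a
#'   FASTA path.
#' @param targets Interval data frame of capture targets, or a BED path.
#' @param vectors Named character vector of vector sequences, a FASTA
#'   path, or `NULL` for no vector screen.
#' @param gene_models A `gene_models` data frame, a TSV path, or `NULL`
#'   to skip consequence annotation.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, the VCF, funnel
#'   TSV, unplaced-contig FASTA and audit logs are written there.
#' @param coding_only Drop variants outside coding regions from the
#'   final set (they remain visible in the pre-filter audit).
#' @param drop_synonymous Drop synonymous coding variants from the final
#'   set.
#' @return A `denovok_run` object: final `variants`, the full `funnel`,
#'   pre-filter variant tables, contigs at each stage, the parental
#'   audit, and paths of any files written.
#' @export
run_trio <- function(proband, mother, father, reference, targets,
                     vectors = NULL, gene_models = NULL,
                     config = pipeline_config(), out_dir = NULL,
                     coding_only = FALSE, drop_synonymous = FALSE) {
  run_pipeline(affected = proband,
               unaffected = list(mother = mother, father = father),
               reference = reference, targets = targets, vectors = vectors,
               gene_models = gene_models, config = config,
               out_dir = out_dir, coding_only = coding_only,
               drop_synonymous = drop_synonymous)
}

#' @rdname run_trio
#' @export
run_pair <- function(diseased, normal, reference, targets,
                     vectors = NULL, gene_models = NULL,
                     config = pipeline_config(), out_dir = NULL,
                     coding_only = FALSE, drop_synonymous = FALSE) {
  run_pipeline(affected = diseased, unaffected = list(normal = normal),
               reference = reference, targets = targets, vectors = vectors,
               gene_models = gene_models, config = config,
               out_dir = out_dir, coding_only = coding_only,
               drop_synonymous = drop_synonymous)
}

load_reads <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing ", what, " FASTQ: ", x)
    return(read_fastq(x))
  }
  stopifnot(is.data.frame(x))
  x
}

run_pipeline <- function(affected, unaffected, reference, targets,
                         vectors, gene_models, config, out_dir,
                         coding_only = FALSE, drop_synonymous = FALSE) {
  affected <- load_reads(affected, "affected-sample")
  unaffected <- lapply(names(unaffected), function(nm)
    load_reads(unaffected[[nm]], nm))
  names(unaffected) <- if (length(unaffected) == 2L)
    c("mother", "father") else "normal"
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) reference <- read_fasta(reference)
  if (is.character(targets) && length(targets) == 1L) targets <-
      read_bed(targets)
  if (!is.null(vectors) && is.character(vectors) && length(vectors) == 1L &&
      file.exists(vectors)) vectors <- read_fasta(vectors)
  if (!is.null(gene_models) && is.character(gene_models) &&
      length(gene_models) == 1L) gene_models <-
      read_gene_models(gene_models)

  k <- config$k
  funnel <- funnel_row("affected_reads", nrow(affected))

  # steps 1-2: k-mer spectra; error filter on the affected sample only
  aff_tab <- count_kmers(affected, k)
  funnel <- rbind(funnel, funnel_row("affected_kmers", length(aff_tab)))
  aff_tab <- filter_min_count(aff_tab, config$min_count)
  funnel <- rbind(funnel,
                  funnel_row("kmers_after_error_filter", length(aff_tab)))

  # step 3: vector and reference-target screens
  if (!is.null(vectors) && length(vectors)) {
    vec_screen <- build_screen_set(vectors, k, label = "vector")
    aff_tab <- kmer_subtract(aff_tab, vec_screen)
  }
  funnel <- rbind(funnel,
                  funnel_row("kmers_after_vector_screen", length(aff_tab)))
  ref_screen <- build_screen_set(reference, k, intervals = targets,
                                 label = "reference_targets")
  aff_tab <- kmer_subtract(aff_tab, ref_screen)
  funnel <- rbind(funnel,
                  funnel_row("kmers_after_reference_screen",
                             length(aff_tab)))

  # step 4: subtract every unaffected sample (presence veto, no error
  # filter on their spectra)
  for (u in unaffected)
    aff_tab <- kmer_subtract(aff_tab, count_kmers(u, k))
  candidates <- aff_tab
  funnel <- rbind(funnel,
                  funnel_row("candidate_kmers", length(candidates)))

  empty_run <- function() {
    structure(list(
      variants = empty_variants(), prefilter_variants = empty_variants(),
      funnel = funnel, candidates = candidates,
      harvested = NULL, contigs = list(), surviving = list(),
      removed = list(), vacuous = list(), unplaced = list(),
      audit = NULL, truthy = NULL, config = config, paths = NULL),
      class = "denovok_run")
  }

  if (length(candidates) == 0L) {
    run <- empty_run()
    run$funnel <- pad_funnel(run$funnel)
    return(finish_run(run, reference, out_dir))
  }

  # step 5: harvest the affected reads containing candidate k-mers
  harvested <- harvest_reads(affected, candidates)
  funnel <- rbind(funnel,
                  funnel_row("reads_with_candidate_kmers", nrow(harvested)))

  # step 6: read-level vector screen
  screened <- screen_reads_for_vector(harvested, vectors %||% character(0),
                                      config = config)
  harvested <- screened$clean
  funnel <- rbind(funnel,
                  funnel_row("reads_after_vector_screen", nrow(harvested)))

  # step 7: micro-assembly
  contigs <- assemble_reads(harvested, config$min_overlap,
                            config$max_mismatch_frac)
  funnel <- rbind(funnel, funnel_row("contigs_assembled", length(contigs)))

  # step 8: placement, merge co-located, read-support filter
  index <- reference_index(reference, k_seed = k)
  contigs <- lapply(contigs, place_contig, index = index, config = config)
  contigs <- merge_colocated(contigs, index, config)
  contigs <- filter_min_support(contigs, config$min_reads_per_contig)
  funnel <- rbind(funnel,
                  funnel_row("contigs_after_merge_support",
                             length(contigs)))

  if (length(contigs) == 0L) {
    run <- empty_run()
    run$funnel <- pad_funnel(funnel)
    run$harvested <- harvested
    return(finish_run(run, reference, out_dir))
  }

  # step 9: parental evidence
  ext <- lapply(contigs, extend_contig, reference = reference,
                read_length = config$read_length_hint)
  parent_aln <- lapply(unaffected, function(u) {
    al <- align_unaffected_reads(u, ext, config)
    lapply(seq_along(al), function(ti)
      better_placement_check(al[[ti]], u, ext[[ti]], index, config))
  })
  filt <- parental_coverage_filter(ext, parent_aln,
                                   config$min_parent_depth)
  funnel <- rbind(funnel,
                  funnel_row("contigs_with_unaffected_coverage",
                             length(filt$surviving)))

  # step 10: pileup over surviving windows using the affected reads
  surviving_idx <- match(
    vapply(filt$surviving, function(x) x$contig$id, character(1)),
    vapply(ext, function(x) x$contig$id, character(1)))
  aff_aln <- align_unaffected_reads(affected, filt$surviving, config)
  parent_aln_surv <- lapply(parent_aln, function(pa) pa[surviving_idx])
  prefilter <- pileup_call(filt$surviving, aff_aln, reference,
                           parent_alignments = parent_aln_surv)
  funnel <- rbind(funnel,
                  funnel_row("variants_called", nrow(prefilter)))
  variants <- fraction_filter(prefilter, config$min_variant_fraction)
  funnel <- rbind(funnel,
                  funnel_row("variants_above_fraction", nrow(variants)))
  if (!is.null(gene_models)) {
    variants <- annotate_consequence(variants, gene_models, reference)
    n_coding <- sum(variants$coding == "coding")
    n_nonsyn <- sum(variants$coding == "coding" &
                    (is.na(variants$consequence) |
                     variants$consequence != "synonymous"))
    if (coding_only)
      variants <- variants[variants$coding == "coding", , drop = FALSE]
    if (drop_synonymous)
      variants <- variants[is.na(variants$consequence) |
                           variants$consequence != "synonymous", ,
                           drop = FALSE]
  } else {
    n_coding <- NA_real_
    n_nonsyn <- NA_real_
  }
  funnel <- rbind(funnel, funnel_row("variants_in_coding_regions",
                                     n_coding))
  funnel <- rbind(funnel, funnel_row("variants_nonsynonymous", n_nonsyn))
  rownames(variants) <- NULL

  run <- structure(list(
    variants = variants, prefilter_variants = prefilter, funnel = funnel,
    candidates = candidates, harvested = harvested, contigs = contigs,
    surviving = filt$surviving, removed = filt$removed,
    vacuous = filt$vacuous, unplaced = filt$unplaced, audit = filt$audit,
    vector_log = screened$log, config = config, paths = NULL),
    class = "denovok_run")
  finish_run(run, reference, out_dir)
}

# funnel rows for runs that short-circuit before the later steps
pad_funnel <- function(funnel) {
  all_steps <- c("affected_reads", "affected_kmers",
                 "kmers_after_error_filter", "kmers_after_vector_screen",
                 "kmers_after_reference_screen", "candidate_kmers",
                 "reads_with_candidate_kmers", "reads_after_vector_screen",
                 "contigs_assembled", "contigs_after_merge_support",
                 "contigs_with_unaffected_coverage", "variants_called",
                 "variants_above_fraction", "variants_in_coding_regions",
                 "variants_nonsynonymous")
  missing <- setdiff(all_steps, funnel$step)
  if (length(missing))
    funnel <- rbind(funnel, funnel_row(missing, 0))
  funnel[match(all_steps, funnel$step), , drop = FALSE]
}

finish_run <- function(run, reference, out_dir) {
  run$funnel <- pad_funnel(run$funnel)
  rownames(run$funnel) <- NULL
  if (!is.null(out_dir)) {
    paths <- final_report(run$variants, run$unplaced, reference,
                          run$funnel, out_dir)
    if (!is.null(run$audit)) {
      paths$audit <- file.path(out_dir, "parental_audit.tsv")
      write.table(run$audit, paths$audit, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    if (!is.null(run$vector_log)) {
      paths$vector_log <- file.path(out_dir, "vector_screen.tsv")
      write.table(run$vector_log, paths$vector_log, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    run$paths <- paths
  }
  run
}

#' @export
print.denovok_run <- function(x, ...) {
  cat("denovok pipeline run\n")
  f <- x$funnel
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-34s %s\n", f$step[i],
                ifelse(is.na(f$count[i]), "-", format(f$count[i]))))
  if (nrow(x$variants)) {
    cat("final variants:\n")
    print(x$variants[, intersect(c("chrom", "pos", "ref", "alt",
                                   "fraction", "coding", "consequence"),
                                 names(x$variants))])
  } else cat("final variants: none\n")
  invisible(x)
}

#' Check funnel monotonicity
#'
#' Verifies that the per-step counts decrease (weakly) within the k-mer
#' stages and from the read-harvest stage onward, the same shape the
#' data-reduction funnel takes on real exomes (the read-harvest count may
#' legitimately exceed the candidate k-mer count, as each k-mer occurs in
#' many reads).
#'
#' @param funnel Funnel data frame of a `denovok_run`.
#' @return `TRUE` if the funnel is monotone in that sense.
#' @export
funnel_is_monotone <- function(funnel) {
  cnt <- setNames(funnel$count, funnel$step)
  kstages <- cnt[c("affected_kmers", "kmers_after_error_filter",
                   "kmers_after_vector_screen",
                   "kmers_after_reference_screen", "candidate_kmers")]
  late <- cnt[c("reads_with_candidate_kmers", "reads_after_vector_screen",
                "contigs_assembled", "contigs_after_merge_support",
                "contigs_with_unaffected_coverage",
                "variants_above_fraction", "variants_in_coding_regions",
                "variants_nonsynonymous")]
  late <- late[!is.na(late)]
  all(diff(kstages) <= 0) && all(diff(late) <= 0)
}
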