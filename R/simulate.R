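# Synthetic trio / pair simulator.  Generates a small random reference
# with valid protein-coding genes and targeted regions, a diploid family
# (or a normal/diseased pair), planted de novo variants at chosen allele
# fractions, sequencing errors, optional vector contamination and
# capture dropout, plus a machine-readable truth set.  Everything is
# deterministic given the seed.

#' Simulation specification
#'
#' The generator's defaults describe deep targeted sequencing: ~80x
#' coverage with 100-bp reads and 0.5% per-base substitution error, an
#' inherited heterozygous variant rate of 1e-3 per bp, and five de novo
#' SNVs plus one small de novo indel planted in the affected sample at
#' 50% allele fraction.
#'
#' @param reference_length Reference length in bp.
#' @param n_genes Number of protein-coding genes planted.
#' @param target_fraction Approximate fraction of the reference under
#'   capture targets (coding exons plus extra noncoding targets).
#' @param inherited_rate Per-bp probability of an inherited variant site
#'   in each parent.
#' @param het_fraction Fraction of inherited sites that are heterozygous
#'   (the rest are homozygous alternate).
#' @param n_denovo_snv,n_denovo_indel Planted de novo SNVs / small
#'   indels.
#' @param denovo_vaf Allele fraction of each planted de novo variant
#'   (recycled; 0.5 = constitutional heterozygous, <0.5 = mosaic).
#' @param indel_len Length of planted de novo indels (alternating
#'   insertion/deletion).
#' @param coverage Mean read depth per sample over the targets.
#' @param read_length Read length.
#' @param error_rate Per-base substitution error probability.
#' @param vector_fraction Fraction of affected-sample reads turned into
#'   vector chimeras.
#' @param n_vectors,vector_length Synthetic vector database shape.
#' @param dropout_father,dropout_mother Optional interval data frames
#'   (`chrom`, `start`, `end`) from which that parent receives no reads,
#'   emulating capture dropout.
#' @param forced_het_pos Optional 0-based position forced to be an
#'   inherited heterozygous SNV transmitted to the child.  Combined with
#'   a dropout region in the transmitting parent this stages the
#'   capture-dropout artifact: the child's inherited k-mers look unique
#'   because the parent who carries them contributed no reads there.
#' @param forced_het_parent Which parent carries (and transmits) the
#'   forced heterozygous variant.
#' @param duplication_identity If non-NULL, a 2-kb segment is duplicated
#'   elsewhere in the reference at this sequence identity (a controlled
#'   paralog for better-placement tests).
#' @param mode `"trio"` (proband + mother + father) or `"pair"`
#'   (diseased + normal).
#' @param seed Integer random seed; the whole fixture is a deterministic
#'   function of the spec including this seed.
#' @return A `sim_spec` list.
#' @export
simulation_spec <- function(reference_length = 100000L,
                            n_genes = 8L,
                            target_fraction = 0.20,
                            inherited_rate = 1e-3,
                            het_fraction = 0.7,
                            n_denovo_snv = 5L,
                            n_denovo_indel = 1L,
                            denovo_vaf = 0.5,
                            indel_len = 3L,
                            coverage = 80L,
                            read_length = 100L,
                            error_rate = 0.005,
                            vector_fraction = 0,
                            n_vectors = 3L,
                            vector_length = 2000L,
                            dropout_father = NULL,
                            dropout_mother = NULL,
                            forced_het_pos = NULL,
                            forced_het_parent = c("father", "mother"),
                            duplication_identity = NULL,
                            mode = c("trio", "pair"),
                            seed = 1L) {
  mode <- match.arg(mode)
  forced_het_parent <- match.arg(forced_het_parent)
  stopifnot(inherited_rate >= 0, inherited_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            all(denovo_vaf > 0), all(denovo_vaf <= 1),
            vector_fraction >= 0, vector_fraction <= 1,
            coverage >= 20L)  # >= 2 x min_count so true k-mers survive
  spec <- as.list(environment())
  class(spec) <- "sim_spec"
  spec
}

#' Canonical k-mers introduced by a variant
#'
#' The canonical k-mers of the alternate-allele context: k-1 reference
#' bases on each side of the (normalized, anchored) allele.  These are
#' the k-mers whose presence in the affected sample and absence from the
#' unaffected samples make the variant discoverable.
#'
#' @param chrom,pos,ref,alt Variant in normalized form (`pos` 0-based).
#' @param reference Named character vector of reference sequences.
#' @param k K-mer length.
#' @return Character vector of canonical k-mers.
#' @export
variant_alt_kmers <- function(chrom, pos, ref, alt, reference, k = 27L) {
  refseq <- reference[[chrom]]
  left <- substring(refseq, pos - k + 2L, pos)       # k-1 bases before pos
  right <- substring(refseq, pos + nchar(ref) + 1L,
                     pos + nchar(ref) + k - 1L)
  ctx <- paste0(left, alt, right)
  n <- nchar(ctx)
  if (n < k) return(character(0))
  starts <- 1:(n - k + 1L)
  # anchored indels share their first base with the reference: the
  # window ending on the anchor is pure reference and not informative
  if (nchar(ref) != nchar(alt)) starts <- starts[starts + k - 1L > k]
  unique(canonicalize(substring(ctx, starts, starts + k - 1L)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A valid ORF of n_codons coding codons: ATG + codons without stops + stop.
rand_orf <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  body <- sample(codons, n_codons, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Simulate a reference genome with genes and capture targets
#'
#' Uniform random sequence with `n_genes` planted protein-coding genes
#' (valid ORFs, 1-3 coding exons, half on the minus strand), capture
#' targets consisting of the coding exons padded by 50 bp plus extra
#' noncoding targets up to `target_fraction`, and optionally a duplicated
#' segment at a controlled identity.
#'
#' @param spec A [simulation_spec()].
#' @return List with `reference` (named character), `targets` (interval
#'   data frame), `genes` (a `gene_models` data frame).
#' @export
simulate_reference <- function(spec) {
  set.seed(spec$seed)
  L <- spec$reference_length
  seq <- rand_dna(L)
  genes <- list()
  pad <- 50L
  # evenly spaced gene slots in the first half of every [slot] window
  slot <- L %/% (spec$n_genes + 1L)
  if (slot < 2500L) stop("reference too short for requested gene count")
  for (g in seq_len(spec$n_genes)) {
    n_codons <- sample(80:160, 1L)
    orf <- rand_orf(n_codons)
    n_exons <- sample(1:3, 1L)
    # split the ORF into exons at codon boundaries
    cl <- nchar(orf)
    cuts <- if (n_exons > 1L)
      sort(sample(seq(3L, cl - 3L, by = 3L), n_exons - 1L)) else integer(0)
    bounds <- c(0L, cuts, cl)
    strand <- if (g %% 2L == 0L) "-" else "+"
    gstart <- (g - 1L) * slot + slot %/% 4L
    # coding-order ORF pieces; on the minus strand the genome carries
    # the reverse complement with exon order reversed along the genome,
    # so genomic exon e holds revcomp(piece n+1-e)
    pieces <- substring(orf, bounds[-length(bounds)] + 1L, bounds[-1L])
    gpieces <- if (strand == "-") rev(revcomp(pieces)) else pieces
    exon_pos <- gstart
    for (e in seq_len(n_exons)) {
      elen <- nchar(gpieces[e])
      substring(seq, exon_pos + 1L, exon_pos + elen) <- gpieces[e]
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("gene%02d", g),
        transcript_id = sprintf("tx%02d", g),
        chrom = "chr1", start = exon_pos, end = exon_pos + elen,
        strand = strand, stringsAsFactors = FALSE)
      exon_pos <- exon_pos + elen + 200L  # 200-bp introns
    }
  }
  gm <- validate_gene_models(do.call(rbind, genes))
  # targets: padded exons + extra noncoding targets up to target_fraction
  tg <- data.frame(chrom = gm$chrom, start = pmax(0L, gm$start - pad),
                   end = pmin(L, gm$end + pad), stringsAsFactors = FALSE)
  want <- as.integer(spec$target_fraction * L)
  have <- sum(tg$end - tg$start)
  extra_len <- 500L
  tries <- 0L
  while (have < want && tries < 1000L) {
    s <- sample.int(L - extra_len, 1L) - 1L
    cand <- data.frame(chrom = "chr1", start = s, end = s + extra_len,
                       stringsAsFactors = FALSE)
    m <- merge_intervals(rbind(tg, cand))
    gain <- sum(m$end - m$start) - have
    if (gain >= extra_len %/% 2L) { tg <- m; have <- sum(tg$end - tg$start) }
    tries <- tries + 1L
  }
  tg <- merge_intervals(tg)
  if (!is.null(spec$duplication_identity)) {
    dlen <- 2000L
    src <- tg$start[1L]
    dup <- substring(seq, src + 1L, src + dlen)
    db <- strsplit(dup, "", fixed = TRUE)[[1L]]
    nmut <- round((1 - spec$duplication_identity) * dlen)
    at <- sample.int(dlen, nmut)
    for (p in at) db[p] <- sample(setdiff(c("A", "C", "G", "T"), db[p]), 1L)
    dest <- L - dlen  # paste the paralog at the far end, outside targets
    substring(seq, dest + 1L, dest + dlen) <- paste(db, collapse = "")
  }
  list(reference = c(chr1 = seq), targets = tg, genes = gm)
}

apply_edits <- function(seqchars, edits) {
  # edits: data.frame(pos (0-based), ref, alt), applied right-to-left
  if (!nrow(edits)) return(seqchars)
  edits <- edits[order(-edits$pos), , drop = FALSE]
  s <- seqchars
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    rl <- nchar(edits$ref[i])
    altv <- strsplit(edits$alt[i], "", fixed = TRUE)[[1L]]
    s <- append(s[-((p + 1L):(p + rl))], altv, after = p)
  }
  s
}

#' Simulate reads for a trio or pair
#'
#' Parents receive independent inherited SNVs (heterozygous or
#' homozygous); the child inherits one intact haplotype from each parent
#' (no recombination).  De novo variants exist only in the affected
#' sample: a read covering a de novo locus carries the alternate allele
#' with probability equal to the variant's VAF, so the alt read count at
#' depth d is Binomial(d, VAF).  Reads start uniformly over the targets
#' extended by one read length, carry per-base substitution errors, and
#' are emitted on a random strand.  In pair mode two samples are
#' generated from one individual's haplotypes, the diseased one carrying
#' the planted somatic variants.
#'
#' @param spec A [simulation_spec()].
#' @param ref Result of [simulate_reference()] (regenerated if omitted).
#' @return List with `reads` (named list of [read_set()]s: proband /
#'   mother / father, or diseased / normal), `truth` (de novo truth
#'   table), `inherited` (per-parent inherited variants), `vectors`
#'   (named character), `chimeras` (ids of vector-chimeric reads),
#'   `spec`, and the `reference`, `targets`, `genes` of `ref`.
#' @export
simulate_trio <- function(spec, ref = simulate_reference(spec)) {
  set.seed(spec$seed + 104729L)  # independent stream from the reference
  reference <- ref$reference
  targets <- ref$targets
  L <- nchar(reference[[1L]])
  k_guard <- 31L  # keep de novo loci clear of inherited sites by > k

  draw_inherited <- function() {
    n <- rbinom(1L, L, spec$inherited_rate)
    pos <- sort(sample.int(L, n) - 1L)
    refb <- substring(reference[[1L]], pos + 1L, pos + 1L)
    alt <- vapply(refb, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    het <- runif(n) < spec$het_fraction
    data.frame(pos = pos, ref = refb, alt = unname(alt), het = het,
               stringsAsFactors = FALSE)
  }
  mother <- draw_inherited()
  father <- draw_inherited()
  transmit_m <- sample(1:2, 1L)
  transmit_f <- sample(1:2, 1L)
  if (!is.null(spec$forced_het_pos)) {
    p <- as.integer(spec$forced_het_pos)
    rb <- substring(reference[[1L]], p + 1L, p + 1L)
    forced <- data.frame(
      pos = p, ref = rb, alt = setdiff(c("A", "C", "G", "T"), rb)[1L],
      het = TRUE, stringsAsFactors = FALSE)
    # the forced het sits on haplotype 1 of its carrier, which is forced
    # to be the transmitted haplotype so the child inherits it
    if (spec$forced_het_parent == "mother") {
      mother <- rbind(mother[mother$pos != p, , drop = FALSE], forced)
      mother <- mother[order(mother$pos), , drop = FALSE]
      transmit_m <- 1L
    } else {
      father <- rbind(father[father$pos != p, , drop = FALSE], forced)
      father <- father[order(father$pos), , drop = FALSE]
      transmit_f <- 1L
    }
  }
  # haplotypes as variant subsets; hap1 carries het+hom, hap2 carries hom
  hap_edits <- function(tab, hap)
    tab[tab$het == (hap == 1L) | !tab$het, c("pos", "ref", "alt"),
        drop = FALSE]
  child_h1 <- hap_edits(mother, transmit_m)
  child_h2 <- hap_edits(father, transmit_f)

  # plant de novo variants inside targets, away from inherited variants
  n_dn <- spec$n_denovo_snv + spec$n_denovo_indel
  vafs <- rep_len(spec$denovo_vaf, max(n_dn, 1L))
  occupied <- c(mother$pos, father$pos)
  tgt_pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                           targets$start, targets$end, SIMPLIFY = FALSE))
  truth <- list()
  taken <- integer(0)
  for (d in seq_len(n_dn)) {
    repeat {
      p <- sample(tgt_pos, 1L)
      clear <- all(abs(occupied - p) > k_guard) &&
        (length(taken) == 0L || all(abs(taken - p) > 400L)) &&
        p > k_guard && p < L - k_guard - 10L
      if (clear) break
    }
    taken <- c(taken, p)
    rb <- substring(reference[[1L]], p + 1L, p + 1L)
    if (d <= spec$n_denovo_snv) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
      type <- "snv"; refal <- rb
    } else if ((d - spec$n_denovo_snv) %% 2L == 1L) {
      refal <- substring(reference[[1L]], p + 1L, p + 1L + spec$indel_len)
      alt <- rb; type <- "del"
    } else {
      ins <- rand_dna(spec$indel_len)
      refal <- rb; alt <- paste0(rb, ins); type <- "ins"
    }
    truth[[d]] <- data.frame(
      chrom = "chr1", pos = p, ref = refal, alt = alt, type = type,
      vaf = vafs[d], stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), type = character(), vaf = numeric(),
    stringsAsFactors = FALSE)
  if (nrow(truth)) {
    truth <- normalize_variants(truth, reference)
    in_t <- vapply(truth$pos, function(p)
      any(targets$start <= p & p < targets$end), logical(1))
    truth$inside_target <- in_t
    # expected count of a single variant-spanning canonical k-mer:
    # depth x VAF x fraction of read windows containing the k-mer x
    # probability the k-mer window is sequenced error-free
    kspan <- 27L
    exp_kmer <- spec$coverage * truth$vaf *
      (spec$read_length - kspan + 1L) / spec$read_length *
      (1 - spec$error_rate)^kspan
    truth$expected_kmer_support <- exp_kmer
    truth$expected_detectable <- in_t & exp_kmer >= 10
  }

  # read sampling ------------------------------------------------------
  refseq <- reference[[1L]]
  rl <- spec$read_length
  ext <- data.frame(start = pmax(0L, targets$start - rl),
                    end = pmin(L - rl, targets$end))
  ext <- ext[ext$end > ext$start, , drop = FALSE]
  wts <- ext$end - ext$start
  # reads start uniformly over the extended targets; sizing by the
  # extended length makes the interior target depth equal `coverage`
  n_reads <- as.integer(round(spec$coverage * sum(wts) / rl))

  sample_reads <- function(sample_name, haps, denovo, dropout) {
    starts <- integer(n_reads)
    got <- 0L
    while (got < n_reads) {
      take <- n_reads - got
      iv <- sample.int(nrow(ext), take, replace = TRUE, prob = wts)
      s <- ext$start[iv] + floor(runif(take) * wts[iv])
      if (!is.null(dropout) && nrow(dropout)) {
        bad <- rep(FALSE, take)
        for (r in seq_len(nrow(dropout)))
          bad <- bad | (s < dropout$end[r] & s + rl > dropout$start[r])
        s <- s[!bad]
      }
      if (length(s)) {
        starts[(got + 1L):(got + length(s))] <- as.integer(s)
        got <- got + length(s)
      }
    }
    hap_i <- sample(1:2, n_reads, replace = TRUE)
    seqs <- character(n_reads)
    slack <- 16L
    for (i in seq_len(n_reads)) {
      s <- starts[i]
      tmpl_end <- min(L, s + rl + slack)
      tmpl <- strsplit(substring(refseq, s + 1L, tmpl_end), "",
                       fixed = TRUE)[[1L]]
      ed <- haps[[hap_i[i]]]
      ed <- ed[ed$pos >= s & ed$pos < tmpl_end - 4L, , drop = FALSE]
      if (!is.null(denovo) && nrow(denovo)) {
        dn <- denovo[denovo$pos >= s & denovo$pos < tmpl_end - 8L, ,
                     drop = FALSE]
        if (nrow(dn)) {
          carry <- runif(nrow(dn)) < dn$vaf
          dn <- dn[carry, c("pos", "ref", "alt"), drop = FALSE]
          if (nrow(dn)) ed <- rbind(ed, dn)
        }
      }
      if (nrow(ed)) {
        ed$pos <- ed$pos - s
        tmpl <- apply_edits(tmpl, ed)
      }
      read <- tmpl[seq_len(min(rl, length(tmpl)))]
      nerr <- rbinom(1L, length(read), spec$error_rate)
      if (nerr > 0L) {
        at <- sample.int(length(read), nerr)
        for (p in at)
          read[p] <- sample(setdiff(c("A", "C", "G", "T"), read[p]), 1L)
      }
      sq <- paste(read, collapse = "")
      if (runif(1L) < 0.5) sq <- revcomp(sq)
      seqs[i] <- sq
    }
    read_set(sprintf("%s_%06d", sample_name, seq_len(n_reads)), seqs,
             qual = rep(list(rep.int(40L, rl)), n_reads))
  }

  if (spec$mode == "trio") {
    child_haps <- list(child_h1, child_h2)
    mother_haps <- list(hap_edits(mother, 1L), hap_edits(mother, 2L))
    father_haps <- list(hap_edits(father, 1L), hap_edits(father, 2L))
    reads <- list(
      proband = sample_reads("proband", child_haps, truth, NULL),
      mother = sample_reads("mother", mother_haps, NULL,
                            spec$dropout_mother),
      father = sample_reads("father", father_haps, NULL,
                            spec$dropout_father))
  } else {
    germ <- list(child_h1, child_h2)
    reads <- list(
      diseased = sample_reads("diseased", germ, truth, NULL),
      normal = sample_reads("normal", germ, NULL, NULL))
  }

  # Refine detectability with the parental-veto check: a variant is only
  # discoverable by k-mer subtraction if at least one of its alternate
  # k-mers is absent from every unaffected sample's reads (a parental
  # read carrying the same substitution as a sequencing error hides the
  # variant from the method by construction).
  if (nrow(truth)) {
    unaff <- if (spec$mode == "trio") reads[c("mother", "father")] else
      reads["normal"]
    n_free <- integer(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      ak <- variant_alt_kmers(truth$chrom[i], truth$pos[i], truth$ref[i],
                              truth$alt[i], reference, k = 27L)
      seen <- rep(FALSE, length(ak))
      for (u in unaff) {
        h <- .kmer_hits_cpp(u$seq, 27L, ak)
        seen <- seen | ak %in% unlist(h$matches, use.names = FALSE)
      }
      n_free[i] <- sum(!seen)
    }
    truth$n_alt_kmers <- vapply(seq_len(nrow(truth)), function(i)
      length(variant_alt_kmers(truth$chrom[i], truth$pos[i], truth$ref[i],
                               truth$alt[i], reference, 27L)), integer(1))
    truth$n_parent_free_kmers <- n_free
    truth$expected_detectable <- truth$expected_detectable & n_free >= 1L
  }

  vectors <- setNames(
    vapply(seq_len(spec$n_vectors), function(i) rand_dna(spec$vector_length),
           character(1)),
    sprintf("synthetic_vector_%02d", seq_len(spec$n_vectors)))
  chimeras <- character(0)
  if (spec$vector_fraction > 0) {
    aff <- if (spec$mode == "trio") "proband" else "diseased"
    inj <- inject_vector(reads[[aff]], vectors, spec$vector_fraction)
    reads[[aff]] <- inj$reads
    chimeras <- inj$chimera_ids
  }
  list(reads = reads, truth = truth,
       inherited = list(mother = mother, father = father),
       vectors = vectors, chimeras = chimeras, spec = spec,
       reference = reference, targets = targets, genes = ref$genes)
}

#' Inject vector chimeras into a read set
#'
#' Replaces the last 20-60 bp of a chosen fraction of reads with vector
#' sequence, emulating residual cloning-vector contamination, and records
#' which reads were chimerized.
#'
#' @param reads A [read_set()].
#' @param vectors Named character vector of vector sequences.
#' @param fraction Fraction of reads to chimerize.
#' @return List with `reads` (modified set) and `chimera_ids`.
#' @export
inject_vector <- function(reads, vectors, fraction) {
  if (fraction <= 0 || nrow(reads) == 0L)
    return(list(reads = reads, chimera_ids = character(0)))
  n <- nrow(reads)
  idx <- which(runif(n) < fraction)
  for (i in idx) {
    vlen <- sample(20:60, 1L)
    v <- sample(length(vectors), 1L)
    vstart <- sample.int(nchar(vectors[[v]]) - vlen, 1L)
    frag <- substring(vectors[[v]], vstart, vstart + vlen - 1L)
    rl <- nchar(reads$seq[i])
    reads$seq[i] <- paste0(substring(reads$seq[i], 1L, rl - vlen), frag)
  }
  list(reads = reads, chimera_ids = reads$id[idx])
}

#' Write a complete runnable fixture to disk
#'
#' Wraps [simulate_reference()] and [simulate_trio()]: writes the
#' reference FASTA, target BED, gene-model TSV, vector FASTA, per-sample
#' FASTQ files and a truth VCF into `dir`.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory.
#' @return Named list of paths plus the in-memory simulation.
#' @export
make_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_trio(spec)
  paths <- list(
    reference = file.path(dir, "reference.fasta"),
    targets = file.path(dir, "targets.bed"),
    genes = file.path(dir, "genes.tsv"),
    vectors = file.path(dir, "vectors.fasta"),
    truth_vcf = file.path(dir, "truth.vcf"))
  write_fasta(sim$reference, paths$reference)
  write_bed(sim$targets, paths$targets)
  write_gene_models(sim$genes, paths$genes)
  write_fasta(sim$vectors, paths$vectors)
  tv <- sim$truth
  if (nrow(tv)) {
    tv$depth <- NA_integer_; tv$alt_count <- NA_integer_
    tv$fraction <- tv$vaf
  }
  write_vcf(tv, sim$reference, paths$truth_vcf)
  for (nm in names(sim$reads)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".fastq"))
    write_fastq(sim$reads[[nm]], paths[[nm]])
  }
  c(paths, list(sim = sim))
}
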