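test_that("identical spec and seed reproduce the fixture byte for byte", {
  spec <- simulation_spec(reference_length = 20000L, n_genes = 2L,
                          coverage = 30L, n_denovo_snv = 1L,
                          n_denovo_indel = 0L, seed = 77L)
  s1 <- simulate_trio(spec)
  s2 <- simulate_trio(spec)
  expect_identical(s1$reads$proband$seq, s2$reads$proband$seq)
  expect_identical(s1$truth, s2$truth)
  spec2 <- simulation_spec(reference_length = 20000L, n_genes = 2L,
                           coverage = 30L, n_denovo_snv = 1L,
                           n_denovo_indel = 0L, seed = 78L)
  s3 <- simulate_trio(spec2)
  expect_false(identical(s1$reads$proband$seq, s3$reads$proband$seq))
})

test_that("simulated genes are valid ORFs with in-frame CDS", {
  spec <- simulation_spec(reference_length = 50000L, n_genes = 5L,
                          seed = 79L)
  ref <- simulate_reference(spec)
  gm <- ref$genes
  for (tx in split(as.data.frame(gm), gm$transcript_id)) {
    tx <- tx[order(tx$start), , drop = FALSE]
    cds <- paste(substring(ref$reference[[1]], tx$start + 1L, tx$end),
                 collapse = "")
    if (tx$strand[1] == "-") cds <- revcomp(cds)
    expect_equal(nchar(cds) %% 3L, 0L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substring(aa, 1, 1), "M")
    expect_equal(substring(aa, nchar(aa)), "*")
    # no internal stops
    expect_false(grepl("\\*", substring(aa, 1, nchar(aa) - 1L)))
  }
  # targets lie within the reference and cover the exons
  expect_true(all(ref$targets$end <= nchar(ref$reference[[1]])))
  for (i in seq_len(nrow(gm)))
    expect_true(any(ref$targets$start <= gm$start[i] &
                    ref$targets$end >= gm$end[i]))
})

test_that("a planted duplication shares k-mers between its two loci", {
  spec <- simulation_spec(reference_length = 30000L, n_genes = 2L,
                          duplication_identity = 0.95, seed = 80L)
  ref <- simulate_reference(spec)
  L <- nchar(ref$reference[[1]])
  src <- substring(ref$reference[[1]], ref$targets$start[1] + 1L,
                   ref$targets$start[1] + 2000L)
  dst <- substring(ref$reference[[1]], L - 2000L + 1L, L)
  shared <- kmer_intersect(count_kmers(src, 27), count_kmers(dst, 27))
  expect_gt(length(shared), 100L)
})

test_that("child variation is Mendelian: no candidates without de novos", {
  spec <- simulation_spec(reference_length = 30000L, n_genes = 3L,
                          coverage = 40L, n_denovo_snv = 0L,
                          n_denovo_indel = 0L, seed = 81L)
  sim <- simulate_trio(spec)
  k <- 27L
  child <- filter_min_count(count_kmers(sim$reads$proband, k), 10L)
  child <- kmer_subtract(child,
                         build_screen_set(sim$reference, k,
                                          intervals = sim$targets))
  child <- kmer_subtract(child, count_kmers(sim$reads$mother, k))
  child <- kmer_subtract(child, count_kmers(sim$reads$father, k))
  expect_equal(length(child), 0L)
})

test_that("de novo alt read counts follow the stated allele fraction", {
  spec <- simulation_spec(reference_length = 30000L, n_genes = 3L,
                          coverage = 80L, n_denovo_snv = 2L,
                          n_denovo_indel = 0L, denovo_vaf = 0.5,
                          seed = 82L)
  sim <- simulate_trio(spec)
  # count proband reads carrying an alt k-mer at each planted locus
  for (i in seq_len(nrow(sim$truth))) {
    ak <- variant_alt_kmers(sim$truth$chrom[i], sim$truth$pos[i],
                            sim$truth$ref[i], sim$truth$alt[i],
                            sim$reference)
    h <- harvest_reads(sim$reads$proband, kmer_table(ak, rep(1L,
                       length(ak)), 27L))
    # Binomial(80, 0.5) spanning reads, minus edge/error losses: a wide
    # but informative band around 40
    expect_gt(nrow(h), 15L)
    expect_lt(nrow(h), 70L)
  }
})

test_that("vector injection chimerizes the requested fraction verbatim", {
  set.seed(83)
  reads <- read_set(sprintf("r%04d", 1:2000), random_reads(2000, 100))
  vec <- c(v1 = random_reads(1, 500))
  none <- inject_vector(reads, vec, 0)
  expect_identical(none$reads, reads)
  expect_length(none$chimera_ids, 0L)
  inj <- inject_vector(reads, vec, 0.05)
  expect_gt(length(inj$chimera_ids), 2000 * 0.05 * 0.5)
  expect_lt(length(inj$chimera_ids), 2000 * 0.05 * 1.5)
  # chimeras carry a verbatim vector suffix of 20-60 bp
  i <- match(inj$chimera_ids[1], inj$reads$id)
  suf <- substring(inj$reads$seq[i], 81, 100)
  expect_true(grepl(suf, vec[[1]], fixed = TRUE))
  # untouched reads are identical
  untouched <- setdiff(reads$id, inj$chimera_ids)
  expect_identical(inj$reads$seq[match(untouched, inj$reads$id)],
                   reads$seq[match(untouched, reads$id)])
})

test_that("make_fixtures writes a complete, runnable fixture", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(reference_length = 20000L, n_genes = 2L,
                          coverage = 30L, n_denovo_snv = 1L,
                          n_denovo_indel = 0L, seed = 84L)
  fx <- make_fixtures(spec, dir)
  expect_true(all(file.exists(unlist(fx[c("reference", "targets", "genes",
                                          "vectors", "truth_vcf",
                                          "proband", "mother",
                                          "father")]))))
  ref <- read_fasta(fx$reference)
  expect_equal(nchar(ref[[1]]), 20000L)
  expect_equal(nrow(read_fastq(fx$proband)),
               nrow(fx$sim$reads$proband))
  # truth VCF row count matches planted de novo count
  body <- readLines(fx$truth_vcf)
  expect_equal(sum(!startsWith(body, "#")), 1L)
})
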