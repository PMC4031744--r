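test_that("pileup calls a heterozygous SNV at fraction one half", {
  set.seed(51)
  ref <- c(chr1 = random_reads(1, 3000))
  cfg <- pipeline_config()
  idx <- reference_index(ref, 27)
  alt_seq <- substring(ref, 1001, 1150)
  altb <- setdiff(c("A", "C", "G", "T"), substring(alt_seq, 75, 75))[1]
  substring(alt_seq, 75, 75) <- altb
  ctg <- place_contig(assemble_reads(read_set("c", alt_seq))[[1]], idx, cfg)
  ec <- extend_contig(ctg, ref, 100L)
  # 40 alt reads and 40 ref reads spanning the site
  starts <- rep(1026:1045, 2)
  mk <- function(s, tpl) substring(tpl, s, s + 99L)
  ref_tpl <- ref[[1]]
  alt_tpl <- paste0(substring(ref_tpl, 1, 1000), alt_seq,
                    substring(ref_tpl, 1151, 3000))
  reads <- read_set(
    sprintf("p%02d", 1:40),
    c(vapply(starts[1:20], mk, character(1), tpl = alt_tpl),
      vapply(starts[21:40], mk, character(1), tpl = ref_tpl)))
  aln <- align_unaffected_reads(reads, list(ec), cfg)
  v <- pileup_call(list(ec), aln, ref)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 1000L + 74L)
  expect_equal(v$alt, altb)
  expect_equal(v$fraction, 0.5)
  expect_equal(v$depth, 40L)
})

test_that("pileup stays silent when all reads match the reference", {
  set.seed(52)
  ref <- c(chr1 = random_reads(1, 2000))
  cfg <- pipeline_config()
  idx <- reference_index(ref, 27)
  alt_seq <- substring(ref, 501, 650)
  substring(alt_seq, 70, 70) <-
    setdiff(c("A", "C", "G", "T"), substring(alt_seq, 70, 70))[1]
  ctg <- place_contig(assemble_reads(read_set("c", alt_seq))[[1]], idx, cfg)
  ec <- extend_contig(ctg, ref, 100L)
  reads <- read_set(sprintf("p%d", 1:10),
                    vapply(521:530, function(s)
                      substring(ref, s, s + 99L), character(1)))
  aln <- align_unaffected_reads(reads, list(ec), cfg)
  v <- pileup_call(list(ec), aln, ref)
  expect_equal(nrow(v), 0L)
})

test_that("a planted deletion is called left-aligned at depth", {
  set.seed(53)
  ref <- c(chr1 = random_reads(1, 3000))
  cfg <- pipeline_config()
  idx <- reference_index(ref, 27)
  # 3-bp deletion at 0-based 1080..1082
  alt_tpl <- paste0(substring(ref, 1, 1080), substring(ref, 1084, 3000))
  alt_seq <- substring(alt_tpl, 1001, 1147)
  ctg <- place_contig(assemble_reads(read_set("c", alt_seq))[[1]], idx, cfg)
  ec <- extend_contig(ctg, ref, 100L)
  reads <- read_set(
    sprintf("p%02d", 1:30),
    c(vapply(1016:1030, function(s) substring(alt_tpl, s, s + 99L),
             character(1)),
      vapply(1016:1030, function(s) substring(ref, s, s + 99L),
             character(1))))
  aln <- align_unaffected_reads(reads, list(ec), cfg)
  v <- pileup_call(list(ec), aln, ref)
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "del")
  expect_equal(nchar(v$ref) - nchar(v$alt), 3L)
  # left-normalized: the reported alleles reproduce the alt template
  rebuilt <- paste0(substring(ref, 1, v$pos),
                    v$alt,
                    substring(ref, v$pos + nchar(v$ref) + 1L, 3000))
  expect_equal(rebuilt, alt_tpl)
  expect_gte(v$fraction, 0.4)
})

test_that("fraction filter is strictly greater-than", {
  v <- data.frame(fraction = c(0.20, 0.05, 0.5, 0.050001))
  kept <- fraction_filter(v, 0.05)
  expect_equal(kept$fraction, c(0.20, 0.5, 0.050001))
})

make_gene_fixture <- function(codon, strand = "+") {
  # reference: 30 bp pad + CDS (ATG <codon> TAA on the coding strand)
  set.seed(sum(utf8ToInt(codon)) + (strand == "-"))
  pad1 <- random_reads(1, 30)
  pad2 <- random_reads(1, 30)
  cds <- paste0("ATG", codon, "TAA")
  genomic <- if (strand == "+") cds else as.character(revcomp(cds))
  ref <- c(chr1 = paste0(pad1, genomic, pad2))
  gm <- validate_gene_models(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = 30L, end = 39L, strand = strand, stringsAsFactors = FALSE))
  list(ref = ref, gm = gm)
}

test_that("consequence annotation matches printed examples", {
  fx <- make_gene_fixture("TCA")  # serine; TCA->TGA introduces a stop
  v <- data.frame(chrom = "chr1", pos = 34L, ref = "C", alt = "G",
                  stringsAsFactors = FALSE)
  a <- annotate_consequence(v, fx$gm, fx$ref)
  expect_equal(a$coding, "coding")
  expect_equal(a$consequence, "nonsense")

  fx <- make_gene_fixture("GCT")  # alanine; GCT->GCC is silent
  v <- data.frame(chrom = "chr1", pos = 35L, ref = "T", alt = "C",
                  stringsAsFactors = FALSE)
  expect_equal(annotate_consequence(v, fx$gm, fx$ref)$consequence,
               "synonymous")

  # minus strand: genomic complement edits must be translated in frame
  fx <- make_gene_fixture("ACG", strand = "-")
  # coding ACG->ATG (Thr->Met): coding offset 1 C->T; genomic base is the
  # complement on the opposite side of the CDS
  # CDS on coding strand occupies genomic 30..39 reversed; coding index 4
  # (0-based) maps to genomic position 39 - 1 - 4 + 30 = genomic 35 - 1
  gpos <- 30L + (9L - 1L - 4L)
  gref <- substring(fx$ref, gpos + 1L, gpos + 1L)
  v <- data.frame(chrom = "chr1", pos = gpos, ref = gref,
                  alt = as.character(revcomp("T")),
                  stringsAsFactors = FALSE)
  a <- annotate_consequence(v, fx$gm, fx$ref)
  expect_equal(a$consequence, "missense")
})

test_that("classifier agrees with full-CDS translation on all 576 SNV cases", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (strand in c("+", "-")) {
    for (codon in codons) {
      fx <- make_gene_fixture(codon, strand)
      for (off in 0:2) {
        cds_idx <- 3L + off  # inside the middle codon
        gpos <- if (strand == "+") 30L + cds_idx
                else 30L + (9L - 1L - cds_idx)
        gref <- substring(fx$ref, gpos + 1L, gpos + 1L)
        coding_ref <- if (strand == "+") gref
                      else as.character(revcomp(gref))
        for (coding_alt in setdiff(bases, coding_ref)) {
          galt <- if (strand == "+") coding_alt
                  else as.character(revcomp(coding_alt))
          v <- data.frame(chrom = "chr1", pos = gpos, ref = gref,
                          alt = galt, stringsAsFactors = FALSE)
          got <- annotate_consequence(v, fx$gm, fx$ref)$consequence
          # oracle: translate the whole mutated CDS with Biostrings
          mut <- codon
          substring(mut, off + 1L, off + 1L) <- coding_alt
          aa0 <- as.character(Biostrings::translate(
            Biostrings::DNAString(codon), no.init.codon = TRUE))
          aa1 <- as.character(Biostrings::translate(
            Biostrings::DNAString(mut), no.init.codon = TRUE))
          expect_equal(got, classify_aa(aa0, aa1),
                       info = paste(strand, codon, off, coding_alt))
        }
      }
    }
  }
})

test_that("CDS indels are frameshift when length is not a multiple of 3", {
  fx <- make_gene_fixture("AAA")
  v <- data.frame(chrom = "chr1", pos = 33L,
                  ref = substring(fx$ref, 34, 36), alt = substring(fx$ref, 34, 34),
                  stringsAsFactors = FALSE)  # 2-bp deletion in CDS
  expect_equal(annotate_consequence(v, fx$gm, fx$ref)$consequence,
               "frameshift")
  v3 <- data.frame(chrom = "chr1", pos = 33L,
                   ref = substring(fx$ref, 34, 37),
                   alt = substring(fx$ref, 34, 34),
                   stringsAsFactors = FALSE)  # in-frame 3-bp deletion
  a <- annotate_consequence(v3, fx$gm, fx$ref)
  expect_equal(a$coding, "coding")
  expect_true(is.na(a$consequence))
})

test_that("variants near exon edges are splice-proximal, else noncoding", {
  fx <- make_gene_fixture("AAA")
  near <- data.frame(chrom = "chr1", pos = 28L, ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  near$ref <- substring(fx$ref, 29, 29)
  near$alt <- setdiff(c("A", "C", "G", "T"), near$ref)[1]
  a <- annotate_consequence(near, fx$gm, fx$ref)
  expect_equal(a$coding, "noncoding")
  expect_equal(a$consequence, "splice-proximal")
  far <- data.frame(chrom = "chr1", pos = 5L, ref = substring(fx$ref, 6, 6),
                    alt = "A", stringsAsFactors = FALSE)
  far$alt <- setdiff(c("A", "C", "G", "T"), far$ref)[1]
  a <- annotate_consequence(far, fx$gm, fx$ref)
  expect_equal(a$coding, "noncoding")
  expect_true(is.na(a$consequence))
})
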