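make_placed_contig <- function(ref, from, to, snv_at = NULL) {
  idx <- reference_index(ref, 27)
  cfg <- pipeline_config()
  seq <- substring(ref, from + 1L, to)
  if (!is.null(snv_at)) {
    off <- snv_at - from
    substring(seq, off + 1L, off + 1L) <-
      setdiff(c("A", "C", "G", "T"), substring(seq, off + 1L, off + 1L))[1]
  }
  ctg <- assemble_reads(read_set("src", seq))[[1]]
  place_contig(ctg, idx, cfg)
}

test_that("contig extension widens by one read length and clamps", {
  set.seed(41)
  ref <- c(chr1 = random_reads(1, 2000))
  ctg <- make_placed_contig(ref, 500, 650)
  ec <- extend_contig(ctg, ref, read_length = 100L)
  expect_equal(c(ec$wstart, ec$wend), c(400L, 750L))
  expect_equal(ec$window, substring(ref[["chr1"]], 401, 750))
  near0 <- make_placed_contig(ref, 30, 180)
  ec0 <- extend_contig(near0, ref, 100L)
  expect_equal(ec0$wstart, 0L)
  unplaced <- assemble_reads(read_set("u", random_reads(1, 150)))[[1]]
  ecu <- extend_contig(unplaced, ref, 100L)
  expect_false(ecu$placed)
  expect_equal(nchar(ecu$window), 150L)
})

test_that("unaffected reads align to windows they came from, not elsewhere", {
  set.seed(42)
  ref <- c(chr1 = random_reads(1, 5000))
  cfg <- pipeline_config()
  ctg <- make_placed_contig(ref, 2000, 2150, snv_at = 2075L)
  ec <- extend_contig(ctg, ref, 100L)
  inside <- substring(ref, 1951, 2050)
  inside_err <- inside
  for (p in c(10L, 60L))  # two errors in 100 bp: 98% identity, kept
    substring(inside_err, p, p) <-
      setdiff(c("A", "C", "G", "T"), substring(inside, p, p))[1]
  outside <- substring(ref, 101, 200)
  reads <- read_set(c("in", "in_err", "out"),
                    c(inside, inside_err, outside))
  aln <- align_unaffected_reads(reads, list(ec), cfg)[[1]]
  expect_setequal(aln$read_id, c("in", "in_err"))
  expect_true(all(aln$matches / aln$columns >= 0.90))
})

test_that("reads with a better placement at a paralog are discarded", {
  set.seed(43)
  # reference with a 95%-identical duplicated segment
  base <- random_reads(1, 2000)
  seg <- substring(base, 501, 1000)
  segchars <- strsplit(seg, "")[[1]]
  at <- sample(500, 25)  # 25 substitutions = 95% identity
  for (p in at) segchars[p] <- setdiff(c("A", "C", "G", "T"),
                                       segchars[p])[1]
  paralog <- paste(segchars, collapse = "")
  ref <- c(chr1 = paste0(base, random_reads(1, 200), paralog))
  idx <- reference_index(ref, 27)
  cfg <- pipeline_config()
  ctg <- make_placed_contig(ref, 550, 700, snv_at = 625L)
  ec <- extend_contig(ctg, ref, 100L)
  true_read <- substring(ref, 551, 650)                 # from the window
  para_start <- 2200L + 50L                             # same offset in paralog
  para_read <- substring(ref, para_start + 1L, para_start + 100L)
  reads <- read_set(c("true", "para"), c(true_read, para_read))
  aln <- align_unaffected_reads(reads, list(ec), cfg)[[1]]
  # the paralog read still clears the 90% identity bar against the window
  expect_setequal(aln$read_id, c("true", "para"))
  kept <- better_placement_check(aln, reads, ec, idx, cfg)
  expect_equal(kept$read_id, "true")
  expect_equal(attr(kept, "n_discarded"), 1L)
})

test_that("a read tied between window and elsewhere is kept", {
  set.seed(44)
  seg <- random_reads(1, 300)
  ref <- c(chr1 = paste0(random_reads(1, 200), seg, random_reads(1, 200),
                         seg, random_reads(1, 100)))
  idx <- reference_index(ref, 27)
  cfg <- pipeline_config()
  # contig over the first copy with one SNV so it places there
  ctg <- make_placed_contig(ref, 210, 360, snv_at = 280L)
  ec <- extend_contig(ctg, ref, 100L)
  read <- substring(ref, 251, 350)  # identical in both copies
  reads <- read_set("tie", read)
  aln <- align_unaffected_reads(reads, list(ec), cfg)[[1]]
  kept <- better_placement_check(aln, reads, ec, idx, cfg)
  expect_equal(kept$read_id, "tie")
})

test_that("parental coverage filter demands every column in every sample", {
  set.seed(45)
  ref <- c(chr1 = random_reads(1, 3000))
  cfg <- pipeline_config()
  ctg <- make_placed_contig(ref, 1000, 1150, snv_at = 1075L)
  ec <- extend_contig(ctg, ref, 100L)
  covering <- read_set(sprintf("m%d", 1:5),
                       vapply(0:4, function(i)
                         substring(ref, 1026 + i, 1125 + i), character(1)))
  away <- read_set("f1", substring(ref, 101, 200))
  cover_aln <- align_unaffected_reads(covering, list(ec), cfg)
  away_aln <- align_unaffected_reads(away, list(ec), cfg)
  # both parents cover -> survives
  res <- parental_coverage_filter(list(ec), list(mother = cover_aln,
                                                 father = cover_aln), 1L)
  expect_length(res$surviving, 1L)
  # father dropout (no aligned reads) -> removed
  res <- parental_coverage_filter(list(ec), list(mother = cover_aln,
                                                 father = away_aln), 1L)
  expect_length(res$removed, 1L)
  expect_equal(res$audit$decision, "removed")
  # a stricter depth demand can also fail a thinly covered parent
  thin <- read_set("m1", substring(ref, 1026, 1125))
  thin_aln <- align_unaffected_reads(thin, list(ec), cfg)
  res <- parental_coverage_filter(list(ec), list(mother = thin_aln,
                                                 father = cover_aln), 5L)
  expect_length(res$removed, 1L)
  res <- parental_coverage_filter(list(ec), list(mother = cover_aln,
                                                 father = cover_aln), 5L)
  expect_length(res$surviving, 1L)
})

test_that("vacuous and unplaced contigs are routed, not silently kept", {
  set.seed(46)
  ref <- c(chr1 = random_reads(1, 3000))
  cfg <- pipeline_config()
  perfect <- make_placed_contig(ref, 1500, 1650)  # no mutation column
  ecp <- extend_contig(perfect, ref, 100L)
  unplaced <- assemble_reads(read_set("u", random_reads(1, 150)))[[1]]
  ecu <- extend_contig(unplaced, ref, 100L)
  no_aln <- align_unaffected_reads(read_set(character(), character()),
                                   list(ecp, ecu), cfg)
  res <- parental_coverage_filter(list(ecp, ecu),
                                  list(mother = no_aln, father = no_aln),
                                  1L)
  expect_length(res$vacuous, 1L)
  expect_length(res$unplaced, 1L)
  expect_length(res$surviving, 0L)
})
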