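test_that("two overlapping reads merge into one contig of the exact length", {
  set.seed(31)
  src <- random_reads(1, 127)
  r1 <- substring(src, 1, 100)
  r2 <- substring(src, 28, 127)  # 73-bp overlap
  ctgs <- assemble_reads(read_set(c("a", "b"), c(r1, r2)))
  expect_length(ctgs, 1L)
  expect_equal(nchar(ctgs[[1]]$seq), 127L)
  expect_equal(ctgs[[1]]$seq, src)
  expect_setequal(ctgs[[1]]$support, c("a", "b"))
  # the same pair merges when one mate is reverse-complemented
  ctgs <- assemble_reads(read_set(c("a", "b"), c(r1, revcomp(r2))))
  expect_length(ctgs, 1L)
  expect_equal(nchar(ctgs[[1]]$seq), 127L)
})

test_that("reads without an admissible overlap stay single-read contigs", {
  set.seed(32)
  reads <- read_set(c("a", "b"), random_reads(2, 100))
  ctgs <- assemble_reads(reads)
  expect_length(ctgs, 2L)
  expect_true(all(vapply(ctgs, function(x) length(x$support), integer(1))
                  == 1L))
})

test_that("deep error-free tiling of a SNV assembles to one bounded contig", {
  set.seed(33)
  src <- random_reads(1, 400)
  alt <- src
  substring(alt, 200, 200) <- if (substring(src, 200, 200) == "A") "C"
                              else "A"
  starts <- sort(sample(101:199, 40, replace = TRUE))
  reads <- read_set(sprintf("r%02d", 1:40),
                    substring(alt, starts, starts + 99))
  ctgs <- assemble_reads(reads)
  expect_length(ctgs, 1L)
  expect_lte(nchar(ctgs[[1]]$seq), 199L)
  expect_true(grepl(substring(alt, 195, 205), ctgs[[1]]$seq, fixed = TRUE))
})

test_that("every contig respects the 2L-1 bound on random inputs", {
  set.seed(34)
  for (rep in 1:5) {
    src <- random_reads(1, 300)
    starts <- sample(200, 30, replace = TRUE)
    reads <- read_set(sprintf("x%02d", 1:30),
                      substring(src, starts, starts + 79))
    ctgs <- assemble_reads(reads)
    expect_true(all(vapply(ctgs, function(x) nchar(x$seq), integer(1))
                    <= 2L * 80L - 1L))
    # per-base depth is at least 1 everywhere
    for (ctg in ctgs) expect_true(all(ctg$depth >= 1L))
  }
})

test_that("consensus majority prevails at a disputed column", {
  set.seed(38)
  src <- random_reads(1, 120)
  a <- substring(src, 1, 80)
  b <- substring(src, 21, 100)
  b_err <- b
  substring(b_err, 1, 1) <-      # disagree with a at the overlap start
    setdiff(c("A", "C", "G", "T"), substring(b, 1, 1))[1]
  # two copies of the majority allele, one of the minority
  ctgs <- assemble_reads(read_set(c("a1", "b1", "a2"),
                                  c(a, b_err, a)),
                         min_overlap = 31L, max_mismatch_frac = 0.05)
  expect_length(ctgs, 1L)
  expect_equal(substring(ctgs[[1]]$seq, 21, 21), substring(src, 21, 21))
})

test_that("contig placement finds exact substrings and rejects aliens", {
  set.seed(35)
  ref <- c(chr1 = random_reads(1, 8000))
  idx <- reference_index(ref, 27)
  cfg <- pipeline_config()
  ctg <- assemble_reads(read_set("a", substring(ref, 3001, 3150)))[[1]]
  placed <- place_contig(ctg, idx, cfg)
  expect_false(is.null(placed$placement))
  expect_equal(placed$placement$start, 3000L)
  expect_equal(placed$placement$end, 3150L)
  expect_equal(placed$placement$identity, 1.0)
  # reverse-complemented contig places at the same locus on minus strand
  ctg_rc <- assemble_reads(read_set("b",
                                    revcomp(substring(ref, 3001, 3150))))[[1]]
  placed_rc <- place_contig(ctg_rc, idx, cfg)
  expect_equal(placed_rc$placement$start, 3000L)
  expect_equal(placed_rc$placement$strand, "-")
  alien <- assemble_reads(read_set("c", random_reads(1, 150)))[[1]]
  expect_null(place_contig(alien, idx, cfg)$placement)
})

test_that("a single-SNV contig yields exactly one mismatch mutation column", {
  set.seed(36)
  ref <- c(chr1 = random_reads(1, 5000))
  idx <- reference_index(ref, 27)
  cfg <- pipeline_config()
  seq <- substring(ref, 2001, 2150)
  substring(seq, 75, 75) <- setdiff(c("A", "C", "G", "T"),
                                    substring(seq, 75, 75))[1]
  ctg <- assemble_reads(read_set("a", seq))[[1]]
  placed <- place_contig(ctg, idx, cfg)
  cols <- mutation_columns(placed, ref)
  expect_equal(cols, 2000L + 74L)  # 0-based reference position
})

test_that("co-located contigs merge transitively and idempotently", {
  set.seed(37)
  ref <- c(chr1 = random_reads(1, 6000))
  idx <- reference_index(ref, 27)
  cfg <- pipeline_config()
  mk <- function(id, from, to)
    assemble_reads(read_set(id, substring(ref, from, to)))[[1]]
  c1 <- place_contig(mk("r1", 1001, 1120), idx, cfg)
  c2 <- place_contig(mk("r2", 1080, 1200), idx, cfg)
  c3 <- place_contig(mk("r3", 1180, 1300), idx, cfg)
  c4 <- place_contig(mk("r4", 4001, 4120), idx, cfg)
  merged <- merge_colocated(list(c1, c2, c3, c4), idx, cfg)
  expect_length(merged, 2L)  # the three overlapping ones collapse
  big <- merged[[which.max(vapply(merged, function(x)
    length(x$support), integer(1)))]]
  expect_setequal(big$support, c("r1", "r2", "r3"))
  again <- merge_colocated(merged, idx, cfg)
  expect_length(again, 2L)
})

test_that("read-support filter keeps four and drops three", {
  mk <- function(n) {
    lay <- data.frame(id = sprintf("r%d", 1:n),
                      seq = strrep("A", 50), offset = 0L)
    denovok:::new_contig("c", lay)
  }
  kept <- filter_min_support(list(mk(4), mk(3)), 4L)
  expect_length(kept, 1L)
  expect_equal(length(kept[[1]]$support), 4L)
  expect_length(filter_min_support(list(), 4L), 0L)
})
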