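test_that("dedup collapses identical (position, UMI) groups only", {
  reads <- aligned_reads(c("a:GTCCG", "b:GTCCG", "c:GTCCA"),
                         "chr1", 100, 130, "+",
                         c("GTCCG", "GTCCG", "GTCCA"), "rep1")
  dd <- dedup(reads)
  expect_equal(dd$reads$read_id, c("a:GTCCG", "c:GTCCA"))
  expect_equal(dd$n_removed, 1)
  # idempotent and order-stable
  dd2 <- dedup(dd$reads)
  expect_equal(dd2$reads, dd$reads)
  expect_equal(dd2$n_removed, 0)
})

test_that("dedup anchors at the strand-aware 5' end by default", {
  # same left coordinate, different spans: on '-' the 5' ends differ
  reads <- aligned_reads(c("a", "b"), "chr1", 100, c(130, 140), "-",
                         "AAAAA", "rep1")
  expect_equal(nrow(dedup(reads)$reads), 2)
  expect_equal(nrow(dedup(reads, anchor = "left_coordinate")$reads), 1)
})

test_that("dedup recovers the generator's unique molecule count exactly", {
  cfg <- sim_config(seed = 3, preset = "tiny", umi_collision_free = TRUE)
  exp <- simulate_experiment(cfg)
  lib <- exp$libraries$rep1
  expect_gte(nrow(lib$aligned), 1000)
  dd <- dedup(lib$aligned)
  expect_equal(nrow(dd$reads), nrow(lib$molecules))
  expect_equal(dd$n_removed, sum(lib$molecules$n_copies - 1L))
})

test_that("crosslink site is read start - 1, strand-mirrored", {
  reads <- aligned_reads(c("a", "b"), "chr1", 100, 130, c("+", "-"),
                         "AAAAA", "rep1")
  xs <- xlink_site(reads)
  expect_equal(xs$points$pos, c(99L, 130L))
  # a plus-strand read starting at 0 has no upstream nucleotide
  edge <- aligned_reads("c", "chr1", 0, 30, "+", "AAAAA", "rep1")
  expect_warning(xs2 <- xlink_site(edge), "out-of-bounds")
  expect_equal(nrow(xs2$points), 0)
  expect_equal(xs2$n_discarded, 1)
  # minus-strand read ending at the chromosome end is likewise discarded
  edge2 <- aligned_reads("d", "chr1", 70, 100, "-", "AAAAA", "rep1")
  expect_warning(xs3 <- xlink_site(edge2, chrom_lengths = c(chr1 = 100L)))
  expect_equal(xs3$n_discarded, 1)
})

test_that("tracks count molecules per position and merge pointwise", {
  reads <- aligned_reads(paste0("r", 1:4), "chr1",
                         c(100, 100, 100, 103), c(130, 131, 132, 133), "+",
                         c("A", "C", "G", "T"), "rep1")
  tr <- build_track(reads, "rep1")
  expect_equal(tr$pos, c(99L, 102L))
  expect_equal(tr$count, c(3L, 1L))
  expect_equal(sum(tr$count), nrow(reads))

  tr2 <- data.frame(chrom = "chr1", pos = c(50L, 99L), strand = "+",
                    count = c(1L, 2L))
  attr(tr2, "library") <- "rep2"
  merged <- merge_tracks(list(tr, tr2))
  expect_equal(merged$pos, c(50L, 99L, 102L))
  expect_equal(merged$count, c(1L, 5L, 1L))
  expect_equal(sum(merged$count), sum(tr$count) + sum(tr2$count))
  expect_error(merge_tracks(list(tr, tr)), "colliding")
})

test_that("alignment TSV write/ingest is the identity", {
  reads <- aligned_reads("r1:GTCCG", "chr1", 100, 130, "+", "GTCCG", "rep1")
  back <- ingest_alignments(write_alignments(reads), "tsv")
  expect_equal(back, reads)
})

test_that("SAM ingestion handles strand flags, multimappers and splices", {
  sam <- c("@HD\tVN:1.6",
           paste("r1:GTCCG", 0, "chr1", 101, 255, "30M", "*", 0, 0,
                 strrep("A", 30), "*", sep = "\t"),
           paste("r2:GTCCG", 16, "chr1", 101, 255, "30M", "*", 0, 0,
                 strrep("A", 30), "*", sep = "\t"),
           paste("r3:GTCCG", 0, "chr1", 101, 3, "30M", "*", 0, 0,
                 strrep("A", 30), "*", "NH:i:4", sep = "\t"),
           # spliced: 5'-terminal block is [100,110) for a plus read
           paste("r4:GTCCG", 0, "chr1", 101, 255, "10M200N20M", "*", 0, 0,
                 strrep("A", 30), "*", sep = "\t"),
           # on minus strand the 5'-terminal block is the last one
           paste("r5:GTCCG", 16, "chr1", 101, 255, "10M200N20M", "*", 0, 0,
                 strrep("A", 30), "*", sep = "\t"))
  al <- ingest_alignments(sam, "sam", replicate = "rep1")
  expect_equal(al$start, c(100L, 100L, 100L, 100L, 310L))
  expect_equal(al$end, c(130L, 130L, 130L, 110L, 330L))
  expect_equal(al$strand, c("+", "-", "+", "+", "-"))
  expect_equal(al$unique, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(ingest_alignments(
    paste("noumi", 0, "chr1", 101, 255, "30M", "*", 0, 0, "AAA", "*",
          sep = "\t"), "sam"), "UMI")
})

test_that("mirroring the genome mirrors the crosslink track exactly", {
  set.seed(19)
  L <- 10000L
  n <- 400
  start <- sample.int(L - 61L, n)
  reads <- aligned_reads(paste0("r", 1:n, ":X"), "chr1", start, start + 30L,
                         sample(c("+", "-"), n, TRUE),
                         random_dna(n, 5), "rep1")
  fwd <- build_track(dedup(reads)$reads, "fwd", c(chr1 = L))
  flipped <- reads
  flipped$start <- L - reads$end
  flipped$end <- L - reads$start
  flipped$strand <- ifelse(reads$strand == "+", "-", "+")
  rev <- build_track(dedup(flipped)$reads, "rev", c(chr1 = L))
  # mirrored positions: x -> L - 1 - x
  mir <- data.frame(chrom = rev$chrom, pos = L - 1L - rev$pos,
                    strand = ifelse(rev$strand == "+", "-", "+"),
                    count = rev$count)
  mir <- mir[order(mir$chrom, mir$strand, mir$pos), , drop = FALSE]
  rownames(mir) <- NULL
  attr(fwd, "library") <- NULL
  expect_equal(fwd, mir)
})
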