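test_that("ingest_peaks accepts only single-nucleotide BED6 intervals", {
  p <- ingest_peaks("chr1\t99\t100\tp\t3.2\t+")
  expect_equal(p, data.frame(chrom = "chr1", pos = 99L, strand = "+",
                             score = 3.2))
  expect_error(ingest_peaks("chr1\t99\t101\tp\t3.2\t+"), "single-nucleotide")
  lines <- sprintf("chr1\t%d\t%d\tp\t1\t+", seq(0, 90, 10), seq(1, 91, 10))
  expect_equal(nrow(ingest_peaks(lines)), length(lines))
})

test_that("naive caller requires local enrichment", {
  flat <- data.frame(chrom = "chr1", pos = 0:99, strand = "+", count = 1L)
  expect_equal(nrow(call_peaks_naive(flat, min_fold = 3)), 0)
  spike <- data.frame(chrom = "chr1", pos = 50L, strand = "+", count = 10L)
  pk <- call_peaks_naive(spike, min_fold = 3)
  expect_equal(pk$pos, 50L)
  expect_equal(pk$score, 10)
})

test_that("naive caller recovers >= 90% of planted peaks within 4 nt", {
  exp <- small_experiment()
  res <- small_result()
  peaks <- res$resolved_peaks
  hit <- vapply(seq_len(nrow(exp$truth)), function(i) {
    any(peaks$chrom == exp$truth$chrom[i] &
          peaks$strand == exp$truth$strand[i] &
          abs(peaks$pos - exp$truth$peak_pos[i]) <= 4)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

# independent oracle: group positions into maximal adjacent runs by direct
# enumeration, then pick the best of each run
brute_resolve <- function(peaks) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    grp <- i
    repeat {
      grow <- which(!(seq_len(nrow(peaks)) %in% grp) &
                      vapply(seq_len(nrow(peaks)), function(j) {
                        any(peaks$chrom[j] == peaks$chrom[grp] &
                              peaks$strand[j] == peaks$strand[grp] &
                              abs(peaks$pos[j] - peaks$pos[grp]) == 1)
                      }, logical(1)))
      if (!length(grow)) break
      grp <- c(grp, grow)
    }
    best <- grp[order(-peaks$score[grp], peaks$pos[grp])][1]
    keep[best] <- TRUE
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

test_that("adjacent-peak resolution matches exhaustive grouping", {
  expect_equal(resolve_adjacent(data.frame(
    chrom = "chr1", pos = c(10L, 11L, 12L), strand = "+",
    score = c(2, 5, 3)))$pos, 11L)
  expect_equal(resolve_adjacent(data.frame(
    chrom = "chr1", pos = c(10L, 12L), strand = "+",
    score = c(2, 5)))$pos, c(10L, 12L))
  expect_equal(resolve_adjacent(data.frame(
    chrom = "chr1", pos = c(10L, 11L), strand = "+",
    score = c(5, 5)))$pos, 10L)

  for (case in 1:25) {
    set.seed(case)
    n <- sample(3:25, 1)
    peaks <- unique(data.frame(
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      pos = sample.int(30L, n, TRUE), strand = sample(c("+", "-"), n, TRUE)))
    peaks$score <- sample(1:5, nrow(peaks), TRUE)
    peaks <- peaks[order(peaks$chrom, peaks$strand, peaks$pos), , drop = FALSE]
    rownames(peaks) <- NULL
    got <- resolve_adjacent(peaks)
    expect_equal(got, brute_resolve(peaks))
    # no two retained peaks at distance 1 on the same chrom+strand
    key <- paste(got$chrom, got$strand)
    for (g in unique(key)) {
      expect_false(any(diff(got$pos[key == g]) == 1))
    }
  }
})

test_that("sites are fixed-width windows centred on their peak", {
  pk <- data.frame(chrom = "chr1", pos = 99L, strand = "+", score = 1)
  s <- make_sites(pk, ext = 4)
  expect_equal(c(s$start, s$end), c(95L, 104L))
  expect_equal(s$end - s$start, 9L)
  expect_equal(s$peak_pos, 99L)
  s0 <- make_sites(pk, ext = 0)
  expect_equal(c(s0$start, s0$end), c(99L, 100L))
  near_edge <- data.frame(chrom = "chr1", pos = 2L, strand = "+", score = 1)
  expect_warning(dropped <- make_sites(near_edge, ext = 4), "dropped")
  expect_equal(nrow(dropped), 0)
  expect_warning(
    make_sites(data.frame(chrom = "chr1", pos = 98L, strand = "+", score = 1),
               ext = 4, chrom_lengths = c(chr1 = 100L)), "dropped")
})

test_that("single-crosslink windows are excluded whatever their count", {
  sites <- data.frame(chrom = "chr1", start = c(95L, 200L), end = c(104L, 209L),
                      strand = "+", peak_pos = c(99L, 204L), score = 1)
  track <- data.frame(chrom = "chr1", pos = c(99L, 204L, 208L), strand = "+",
                      count = c(50L, 1L, 1L))
  kept <- filter_single_xl(sites, track)
  expect_equal(kept$peak_pos, 204L)
  expect_equal(kept$n_xl_positions, 2L)
})

test_that("window crosslink-position counts match brute-force recounts", {
  track <- random_track(600, seed = 23)
  sites <- random_sites(1000, seed = 24)
  kept <- filter_single_xl(sites, track, min_xl_positions = 0L)
  brute <- vapply(seq_len(nrow(sites)), function(i) {
    brute_window_positions(sites[i, ], track)
  }, numeric(1))
  expect_equal(kept$n_xl_positions, as.integer(brute))
})

test_that("the site pipeline only ever narrows the peak set", {
  res <- small_result()
  expect_lte(nrow(res$final_sites), nrow(res$reproducible_sites))
  expect_lte(nrow(res$reproducible_sites), nrow(res$sites))
  expect_lte(nrow(res$sites), nrow(res$resolved_peaks))
  expect_lte(nrow(res$resolved_peaks), nrow(res$peaks))
  # every retained site is 9 nt wide with the peak at its centre
  with(res$sites, {
    expect_true(all(end - start == 9))
    expect_true(all(peak_pos - start == 4))
  })
})
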