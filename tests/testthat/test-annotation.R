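# toy annotation: one coding gene (5'UTR 50, CDS 100, intron 100, 3'UTR 50)
# and one non-coding gene on the minus strand
toy_models <- function() {
  coding <- gene_model("gA", "gA.1", "chr1", "+",
                       exons = data.frame(start = c(0L, 250L),
                                          end = c(150L, 300L)),
                       cds = data.frame(start = 50L, end = 150L))
  nc <- gene_model("gB", "gB.1", "chr1", "-",
                   exons = data.frame(start = 500L, end = 700L))
  list(coding, nc)
}

test_that("sites are assigned by peak position, strand and label priority", {
  models <- toy_models()
  sites <- data.frame(chrom = "chr1",
                      start = c(20L, 270L, 180L, 600L, 600L, 900L) - 4L,
                      end = c(20L, 270L, 180L, 600L, 600L, 900L) + 5L,
                      strand = c("+", "+", "+", "-", "+", "+"),
                      peak_pos = c(20L, 270L, 180L, 600L, 600L, 900L))
  a <- assign_region(sites, models)
  expect_equal(a$region, c("five_prime_utr", "three_prime_utr", "intron",
                           "noncoding", "intergenic", "intergenic"))
  expect_equal(a$transcript_id[1:4], c("gA.1", "gA.1", "gA.1", "gB.1"))
  expect_true(all(is.na(a$transcript_id[5:6])))
})

test_that("overlapping models resolve by the declared feature priority", {
  models <- toy_models()
  # a second gene whose CDS covers the first gene's intron
  models[[3]] <- gene_model("gC", "gC.1", "chr1", "+",
                            exons = data.frame(start = 160L, end = 240L),
                            cds = data.frame(start = 160L, end = 240L))
  site <- data.frame(chrom = "chr1", start = 176L, end = 185L, strand = "+",
                     peak_pos = 180L)
  a <- assign_region(site, models)
  expect_equal(a$region, "cds")
  expect_equal(a$transcript_id, "gC.1")

  # brute-force oracle: enumerate all covering features, apply priority
  feats <- do.call(rbind, lapply(models, function(m) {
    f <- derive_features(m)
    f$strand <- m$strand
    f
  }))
  prio <- c("three_prime_utr", "five_prime_utr", "cds", "intron", "noncoding")
  set.seed(55)
  pos <- sample.int(1000L, 200) - 1L
  strand <- sample(c("+", "-"), 200, TRUE)
  sites <- data.frame(chrom = "chr1", start = pos, end = pos + 1L,
                      strand = strand, peak_pos = pos)
  got <- assign_region(sites, models)$region
  want <- vapply(seq_along(pos), function(i) {
    cover <- feats$label[feats$strand == strand[i] & feats$start <= pos[i] &
                           pos[i] < feats$end]
    if (!length(cover)) "intergenic" else prio[min(match(cover, prio))]
  }, character(1))
  expect_equal(got, want)
})

test_that("region distribution normalises sites and feature lengths", {
  models <- toy_models()[1]
  sites <- data.frame(chrom = "chr1",
                      peak_pos = c(rep(20L, 6), rep(200L + 1:4 * 10L, 1)),
                      strand = "+")
  sites$start <- sites$peak_pos - 4L
  sites$end <- sites$peak_pos + 5L
  a <- assign_region(sites, models)
  # 6 sites in the 5'UTR, 4 in the intron
  rd <- region_distribution(a, models)
  expect_equal(rd$site_percent[rd$region == "five_prime_utr"], 60)
  expect_equal(rd$site_percent[rd$region == "intron"], 40)
  expect_equal(sum(rd$site_percent), 100, tolerance = 1e-9)
  # background shares: 50/100/100/50 nt -> 16.7/33.3/33.3/16.7
  full <- region_distribution(
    assign_region(data.frame(chrom = "chr1", peak_pos = c(20L, 100L, 200L,
                                                          270L),
                             strand = "+", start = 0L, end = 1L), models),
    models)
  expect_equal(full$background_percent[full$region == "five_prime_utr"],
               100 * 50 / 300, tolerance = 1e-9)
  expect_equal(full$background_percent[full$region == "cds"],
               100 * 100 / 300, tolerance = 1e-9)
  expect_equal(full$background_percent[full$region == "intron"],
               100 * 100 / 300, tolerance = 1e-9)
  expect_equal(sum(full$background_percent), 100, tolerance = 1e-9)
  expect_error(region_distribution(a[0, ], models), "zero assigned")
})

test_that("every site gets exactly one label and targets are distinct", {
  res <- small_result()
  fs <- res$final_sites
  expect_true(all(fs$region %in% c("five_prime_utr", "three_prime_utr",
                                   "cds", "intron", "noncoding",
                                   "intergenic")))
  expect_equal(sum(is.na(fs$region)), 0)
  expect_equal(anyDuplicated(res$target_transcripts), 0L)
  expect_true(all(!is.na(res$target_transcripts)))
})

test_that("planted region labels agree with the annotation assignment", {
  exp <- small_experiment()
  tr <- exp$truth
  sites <- data.frame(chrom = tr$chrom, start = tr$peak_pos - 4L,
                      end = tr$peak_pos + 5L, strand = tr$strand,
                      peak_pos = tr$peak_pos)
  a <- assign_region(sites, exp$models)
  expect_gte(mean(a$region == tr$region), 0.99)
})

test_that("the planted UTR share is recovered within 5 points", {
  exp <- small_experiment()
  res <- small_result()
  utr <- c("five_prime_utr", "three_prime_utr")
  truth_share <- 100 * mean(exp$truth$region %in% utr)
  rd <- res$region_distribution
  got_share <- sum(rd$site_percent[rd$region %in% utr])
  expect_lt(abs(got_share - truth_share), 5)
})
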