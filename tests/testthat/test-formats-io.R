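test_that("parse_bed maps fields, defaults BED3, and reports bad lines", {
  iv <- parse_bed("chr1\t4\t13\ts1\t7\t+")
  expect_equal(iv$chrom, "chr1")
  expect_equal(iv$start, 4L)
  expect_equal(iv$end, 13L)
  expect_equal(iv$name, "s1")
  expect_equal(iv$score, 7)
  expect_equal(iv$strand, "+")

  iv3 <- parse_bed("chr2\t0\t10", n_cols = 3)
  expect_equal(iv3$name, ".")
  expect_equal(iv3$score, 0)
  expect_equal(iv3$strand, "+")

  expect_error(parse_bed("chr1\t9\t9\tx\t0\t+"), "line 1.*empty")
  expect_error(parse_bed(c("chr1\t1\t2\ta\t0\t+", "chr1\tx\t9\tb\t0\t+")),
               "line 2")
  expect_error(parse_bed("chr1\t1", n_cols = 3), "line 1")
})

test_that("write_bed round-trips canonical BED6 byte-identically", {
  lines <- c("chr1\t4\t13\ts1\t7\t+",
             "chr1\t40\t50\ts2\t3.25\t-",
             "chr2\t0\t9\t.\t0\t+")
  expect_identical(as.character(write_bed(parse_bed(lines))), lines)
})

test_that("write_bedgraph emits single-nucleotide lines and both dialects", {
  tr <- data.frame(chrom = "chr1", pos = 99L, strand = "+", count = 5L)
  expect_identical(as.character(write_bedgraph(tr, "+")), "chr1\t99\t100\t5")
  expect_identical(as.character(write_bedgraph(tr, "-")), character(0))
  empty <- tr[0, ]
  expect_identical(as.character(write_bedgraph(empty, "+")), character(0))
  neg <- data.frame(chrom = "chr1", pos = 7L, strand = "-", count = 4L)
  expect_identical(as.character(write_bedgraph(neg, "-", signed = TRUE)),
                   "chr1\t7\t8\t-4")
  unsorted <- data.frame(chrom = "chr1", pos = c(9L, 2L), strand = "+",
                         count = 1L)
  expect_error(write_bedgraph(unsorted, "+"), "not sorted")
})

test_that("bedgraph write/parse round-trips 1000 random track points", {
  tr <- random_track(1000, seed = 11)
  back <- rbind(parse_bedgraph(write_bedgraph(tr, "+"), "+"),
                parse_bedgraph(write_bedgraph(tr, "-"), "-"))
  back <- back[order(back$chrom, back$strand, back$pos), , drop = FALSE]
  rownames(back) <- NULL
  expect_equal(back, tr)
  # the signed single-file dialect carries the same information
  signed <- rbind(parse_bedgraph(write_bedgraph(tr, "+", signed = TRUE)),
                  parse_bedgraph(write_bedgraph(tr, "-", signed = TRUE)))
  signed <- signed[order(signed$chrom, signed$strand, signed$pos), ,
                   drop = FALSE]
  rownames(signed) <- NULL
  expect_equal(signed, tr)
})

bed12_line <- function(strand = "+", thick = c(50, 250), name = "g1.1") {
  paste("chr1", 0, 300, name, 0, strand, thick[1], thick[2], "0,0,0", 2,
        "100,100", "0,200", sep = "\t")
}

test_that("BED12 gene models derive UTRs, CDS and introns by strand", {
  m <- parse_gene_models(bed12_line("+"), "bed12")[[1]]
  expect_equal(m$exons, data.frame(start = c(0L, 200L), end = c(100L, 300L)))
  expect_equal(m$cds, data.frame(start = c(50L, 200L), end = c(100L, 250L)))
  f <- derive_features(m)
  expect_equal(f$label[f$start == 0], "five_prime_utr")
  expect_equal(f[f$label == "five_prime_utr", ]$end, 50L)
  expect_equal(f[f$label == "three_prime_utr", ]$start, 250L)
  expect_equal(f[f$label == "intron", c("start", "end")],
               data.frame(start = 100L, end = 200L),
               ignore_attr = TRUE)

  m2 <- parse_gene_models(bed12_line("-"), "bed12")[[1]]
  f2 <- derive_features(m2)
  expect_equal(f2[f2$label == "five_prime_utr", c("start", "end")],
               data.frame(start = 250L, end = 300L), ignore_attr = TRUE)

  m3 <- parse_gene_models(bed12_line("+", thick = c(0, 0)), "bed12")[[1]]
  expect_equal(m3$biotype, "non-coding")
  expect_true(all(derive_features(m3)$label %in% c("noncoding", "intron")))
})

test_that("one representative transcript is kept per gene (the longest)", {
  lines <- c(bed12_line(name = "g1.1"),
             paste("chr1", 400, 450, "g1.2", 0, "+", 400, 440, "0,0,0", 1,
                   "50", "0", sep = "\t"))
  expect_warning(models <- parse_gene_models(lines, "bed12"),
                 "keeping the longest")
  expect_length(models, 1)
  expect_equal(models[[1]]$transcript_id, "g1.1")
})

test_that("GFF3 ingestion converts coordinates and matches BED12 parsing", {
  gff <- c("##gff-version 3",
           "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
           "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.1;Parent=g1",
           "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=g1.1",
           "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=g1.1",
           "chr1\tsrc\tCDS\t51\t100\t.\t+\t0\tParent=g1.1",
           "chr1\tsrc\tCDS\t201\t250\t.\t+\t1\tParent=g1.1")
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  m <- parse_gene_models(path, "gff3")[[1]]
  ref <- parse_gene_models(bed12_line("+"), "bed12")[[1]]
  expect_equal(m$exons, ref$exons)
  expect_equal(m$cds, ref$cds)
  expect_equal(derive_features(m), derive_features(ref))
})

test_that("FASTA/FASTQ readers normalise sequences and enforce structure", {
  fq <- read_fastq(c("@r1", "ACGT", "+", "IIII"))
  expect_equal(fq$read_id, "r1")
  expect_equal(fq$seq, "ACGT")
  expect_equal(utf8ToInt(fq$qual) - 33L, rep(40L, 4))

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g", "acgu"), fa)
  expect_equal(unname(read_fasta(fa)), "ACGT")

  expect_error(read_fastq(c("@r1", "ACGT", "+")), "truncated")
  expect_error(read_fastq(c("@r1", "ACGT", "+", "III")), "length mismatch")

  reads <- data.frame(read_id = c("a", "b"), seq = c("ACGT", "GGTT"),
                      qual = c("IIII", "IIII"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  expect_equal(read_fastq(path), reads)
})

test_that("FASTA writer round-trips with wrapping", {
  seqs <- c(chrA = strrep("ACGT", 60), chrB = "TTTTT")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, path, width = 70)
  expect_equal(read_fasta(path), seqs)
})
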