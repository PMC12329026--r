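# From alignments to deduplicated, strand-aware single-nucleotide crosslink
# tracks. iCLIP reverse transcription truncates at the crosslinked residue,
# so the position one nucleotide 5' of a read's start (in read orientation)
# is the inferred protein-RNA contact.

ALIGNED_COLS <- c("read_id", "chrom", "start", "end", "strand", "umi",
                  "replicate")

#' Construct an aligned-read table
#'
#' @param read_id,chrom,strand,umi,replicate Character vectors.
#' @param start,end 0-based half-open alignment span.
#' @param unique Logical, uniquely mapped (default `TRUE`).
#' @return `data.frame` with columns `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `umi`, `replicate`, `unique`.
#' @export
aligned_reads <- function(read_id, chrom, start, end, strand, umi, replicate,
                          unique = TRUE) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) abort("aligned read with start >= end")
  check_strand(strand)
  if (any(!nzchar(umi))) abort("aligned read with empty UMI")
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, umi = umi, replicate = replicate,
             unique = rep_len(unique, length(read_id)))
}

#' Ingest alignments from SAM text or the 7-column TSV dialect
#'
#' The TSV dialect has columns `read_id, chrom, start, end, strand, umi,
#' replicate` (0-based half-open). SAM records are parsed from plain text;
#' the UMI must be recoverable from the read-ID suffix after the last `:`;
#' multimappers (`NH` tag > 1) are marked non-unique and later excluded from
#' tracks; for spliced alignments the 5'-terminal block determines the span
#' used for crosslink purposes.
#'
#' @param x Path or character vector of lines.
#' @param dialect `"tsv"` or `"sam"`.
#' @param replicate Replicate label for SAM input (TSV carries its own).
#' @return An aligned-read data frame (see [aligned_reads()]).
#' @export
ingest_alignments <- function(x, dialect = c("tsv", "sam"),
                              replicate = "rep1") {
  dialect <- match.arg(dialect)
  lines <- read_text_lines(x)
  if (dialect == "tsv") {
    lines <- lines[nzchar(lines)]
    if (length(lines) && identical(strsplit(lines[1], "\t")[[1]][1], "read_id")) {
      lines <- lines[-1L]
    }
    if (!length(lines)) {
      return(aligned_reads(character(0), character(0), integer(0),
                           integer(0) + 1L, character(0), character(0),
                           character(0)))
    }
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 7L)
    if (length(bad)) abort("alignment TSV parse error at line %d", bad[1])
    g <- function(i) vapply(f, `[[`, character(1), i)
    return(aligned_reads(g(1), g(2), as.integer(g(3)), as.integer(g(4)),
                         g(5), g(6), g(7)))
  }
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(aligned_reads(character(0), character(0), integer(0),
                         integer(0) + 1L, character(0), character(0),
                         character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, character(1), 1L)
  flag <- as.integer(vapply(f, `[[`, character(1), 2L))
  rname <- vapply(f, `[[`, character(1), 3L)
  pos1 <- as.integer(vapply(f, `[[`, character(1), 4L))
  cigar <- vapply(f, `[[`, character(1), 6L)
  mapped <- bitwAnd(flag, 4L) == 0L
  minus <- bitwAnd(flag, 16L) != 0L
  nh <- vapply(f, function(fi) {
    tag <- grep("^NH:i:", fi[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else 1L
  }, integer(1))
  umi <- sub("^.*:", "", qname)
  if (any(umi == qname)) {
    abort("SAM record %s: no ':'-separated UMI suffix in read ID",
          qname[which(umi == qname)[1]])
  }
  # reference span of the 5'-terminal aligned block (read orientation):
  # first M/=/X block for +, last for -; internal N/D gaps ignored
  block_span <- function(cig, p1, is_minus) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cig)[[1]]
    toks <- regmatches(cig, list(ops))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    ref_consuming <- op %in% c("M", "D", "N", "=", "X")
    starts <- p1 - 1L + c(0L, cumsum(lens[ref_consuming]))
    blocks <- which(op[ref_consuming] %in% c("M", "=", "X"))
    if (!length(blocks)) return(c(NA_integer_, NA_integer_))
    b <- if (is_minus) blocks[length(blocks)] else blocks[1L]
    c(starts[b], starts[b + 1L])
  }
  spans <- t(mapply(block_span, cigar, pos1, minus))
  keep <- mapped & !is.na(spans[, 1])
  out <- aligned_reads(qname[keep], rname[keep], spans[keep, 1],
                       spans[keep, 2],
                       ifelse(minus[keep], "-", "+"), umi[keep],
                       rep(replicate, sum(keep)), unique = nh[keep] <= 1L)
  rownames(out) <- NULL
  out
}

#' Write aligned reads in the TSV dialect
#'
#' @param reads Aligned-read data frame.
#' @param file Output path or `NULL`.
#' @param header Write the column-name header line.
#' @return Lines, invisibly.
#' @export
write_alignments <- function(reads, file = NULL, header = TRUE) {
  body <- if (nrow(reads)) {
    do.call(paste, c(unname(as.list(reads[ALIGNED_COLS])), sep = "\t"))
  } else character(0)
  lines <- c(if (header) paste(ALIGNED_COLS, collapse = "\t"), body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Remove PCR duplicates by mapping position and UMI
#'
#' Reads are grouped by (chrom, strand, anchor position, UMI) and only the
#' first of each group in input order is retained: amplification artifacts
#' share both the mapping start position and the random barcode, while
#' distinct molecules at the same position differ in UMI. The anchor is the
#' strand-aware 5'-end position by default (truncation biology anchors the
#' 5' end), with the plain left coordinate available as an alternative.
#'
#' @param reads Aligned-read data frame (must carry `umi` and `strand`).
#' @param anchor `"five_prime"` (default) or `"left_coordinate"`.
#' @return List with `reads` (unique molecules, input order) and `n_removed`.
#' @export
dedup <- function(reads, anchor = c("five_prime", "left_coordinate")) {
  anchor <- match.arg(anchor)
  if (any(!nzchar(reads$umi))) abort("dedup requires non-empty UMIs")
  pos <- if (anchor == "five_prime") {
    ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  } else {
    reads$start
  }
  key <- paste(reads$chrom, reads$strand, pos, reads$umi, sep = "\r")
  keep <- !duplicated(key)
  list(reads = reads[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Crosslink site of aligned reads
#'
#' The crosslink is the nucleotide immediately 5' of the read's 5' end in
#' read orientation: read start − 1 on the plus strand, the alignment end
#' (half-open) on the minus strand.
#'
#' @param reads Aligned-read data frame.
#' @param chrom_lengths Optional named integer vector; reads whose crosslink
#'   would fall outside `[0, length)` are discarded and counted.
#' @return List with `points` (`data.frame(chrom, pos, strand)`, one row per
#'   retained read, count contribution 1 each) and `n_discarded`.
#' @export
xlink_site <- function(reads, chrom_lengths = NULL) {
  if (!all(reads$unique %||% TRUE)) {
    abort("xlink_site requires uniquely mapped reads")
  }
  pos <- ifelse(reads$strand == "+", reads$start - 1L, reads$end)
  ok <- pos >= 0L
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[reads$chrom]
    if (any(is.na(len))) abort("chromosome missing from chrom_lengths")
    ok <- ok & pos < len
  }
  n_bad <- sum(!ok)
  if (n_bad) warnf("%d read(s) with out-of-bounds crosslink discarded", n_bad)
  list(points = data.frame(chrom = reads$chrom[ok], pos = as.integer(pos[ok]),
                           strand = reads$strand[ok]),
       n_discarded = n_bad)
}

#' Build a crosslink track from deduplicated reads
#'
#' @param reads Deduplicated aligned-read data frame (multimappers are
#'   excluded).
#' @param library Library label.
#' @param chrom_lengths Passed to [xlink_site()].
#' @return A crosslink track: `data.frame(chrom, pos, strand, count)` sorted
#'   by (chrom, strand, pos), with attribute `library`. Total count equals
#'   the number of contributing reads.
#' @export
build_track <- function(reads, library = "track", chrom_lengths = NULL) {
  reads <- reads[reads$unique %||% rep(TRUE, nrow(reads)), , drop = FALSE]
  xs <- xlink_site(reads, chrom_lengths)
  dt <- data.table::as.data.table(xs$points)
  tr <- if (nrow(dt)) {
    as.data.frame(dt[, .(count = .N), by = .(chrom, pos, strand)][
      order(chrom, strand, pos)])
  } else {
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               count = integer(0))
  }
  attr(tr, "library") <- library
  tr
}

#' Merge crosslink tracks by pointwise sum
#'
#' @param tracks List of crosslink tracks with distinct `library` labels
#'   (colliding labels are an error).
#' @param library Label for the merged track.
#' @return The merged crosslink track.
#' @export
merge_tracks <- function(tracks, library = "merged") {
  labels <- vapply(tracks, function(t) attr(t, "library") %||% "", character(1))
  if (anyDuplicated(labels[nzchar(labels)])) {
    abort("merge_tracks: colliding library labels: %s",
          paste(labels[duplicated(labels)], collapse = ", "))
  }
  dt <- data.table::rbindlist(lapply(tracks, as.data.frame))
  tr <- if (nrow(dt)) {
    as.data.frame(dt[, .(count = as.integer(sum(count))),
                     by = .(chrom, pos, strand)][order(chrom, strand, pos)])
  } else {
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               count = integer(0))
  }
  attr(tr, "library") <- library
  tr
}
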