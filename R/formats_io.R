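# Reading and writing of the genomic text formats the pipeline touches.
#
# All internal coordinates are 0-based half-open (BED native). Conversion to and
# from 1-based closed coordinates happens only at the GFF3 boundary.

#' Construct a set of genomic intervals
#'
#' The package's interval container is a plain data frame with columns
#' `chrom`, `start`, `end`, `name`, `score`, `strand`, using 0-based
#' half-open coordinates.
#'
#' @param chrom Chromosome identifiers.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`start < end`).
#' @param name Free-text names (default `"."`).
#' @param score Numeric scores (default 0).
#' @param strand `"+"` or `"-"` (default `"+"`).
#' @return A `data.frame` with the six BED columns.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = 0,
                              strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) abort("non-integer coordinates")
  if (any(start < 0L)) abort("negative start coordinate")
  if (any(start >= end)) abort("empty or inverted interval (start >= end)")
  check_strand(strand)
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = as.character(name), score = as.numeric(score),
             strand = rep_len(as.character(strand), length(chrom)),
             stringsAsFactors = FALSE)
}

# format a numeric score the way BED files usually carry it: integers without
# a decimal point, everything else via R's default formatting
format_score <- function(score) {
  out <- vapply(score, function(s) {
    if (is.finite(s) && s == round(s)) format(as.integer(s)) else format(s)
  }, character(1))
  out
}

#' Parse a BED3/BED6 stream
#'
#' @param x Path to a BED file, or a character vector of lines.
#' @param n_cols Number of columns to interpret: 3 or 6. Missing name/score/
#'   strand are defaulted to `"."`, 0 and `"+"` only when `n_cols = 3`.
#' @return A genomic-interval data frame (see [genomic_intervals()]), in file
#'   order.
#' @export
parse_bed <- function(x, n_cols = 6L) {
  if (!n_cols %in% c(3L, 6L)) abort("n_cols must be 3 or 6")
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(genomic_intervals(character(0), integer(0), integer(0) + 1L)[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_cols)
  if (length(bad)) {
    abort("BED parse error at line %d: %d field(s), expected >= %d",
          bad[1], nf[bad[1]], n_cols)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) abort("BED parse error at line %d: non-integer coordinate", bad[1])
  bad <- which(start >= end)
  if (length(bad)) {
    abort("BED parse error at line %d: empty interval (start %d >= end %d)",
          bad[1], start[bad[1]], end[bad[1]])
  }
  if (n_cols == 3L) {
    name <- "."; score <- 0; strand <- "+"
  } else {
    name <- vapply(fields, `[[`, character(1), 4L)
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
    strand <- vapply(fields, `[[`, character(1), 6L)
    if (!all(strand %in% STRANDS)) {
      abort("BED parse error at line %d: invalid strand",
            which(!strand %in% STRANDS)[1])
    }
  }
  genomic_intervals(chrom, start, end, name, score, strand)
}

#' Write intervals as BED6
#'
#' `write_bed(parse_bed(f))` is byte-identical to `f` for canonical 6-column
#' input.
#'
#' @param intervals Genomic-interval data frame.
#' @param file Output path, or `NULL` to return the lines invisibly.
#' @return The written lines, invisibly.
#' @export
write_bed <- function(intervals, file = NULL) {
  lines <- if (nrow(intervals)) {
    paste(intervals$chrom, intervals$start, intervals$end, intervals$name,
          format_score(intervals$score), intervals$strand, sep = "\t")
  } else character(0)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a crosslink track as BEDGRAPH
#'
#' One line `chrom<TAB>pos<TAB>pos+1<TAB>count` per crosslinked position.
#' Strands go to separate streams by default; with `signed = TRUE` the
#' minus-strand counts are negated (for the single-file signed dialect).
#'
#' @param track A crosslink track (`data.frame` with `chrom`, `pos`, `strand`,
#'   `count`), sorted by (`chrom`, `pos`). Unsorted input is an error, never
#'   silently re-sorted.
#' @param strand Which strand to emit.
#' @param file Output path, or `NULL` to return the lines.
#' @param signed Negate minus-strand counts.
#' @return The written lines, invisibly.
#' @export
write_bedgraph <- function(track, strand = "+", file = NULL, signed = FALSE) {
  check_strand(strand)
  sel <- track[track$strand == strand, , drop = FALSE]
  if (nrow(sel) > 1L) {
    o <- order(sel$chrom, sel$pos)
    if (!identical(o, seq_len(nrow(sel)))) {
      abort("write_bedgraph: track is not sorted by (chrom, pos)")
    }
  }
  count <- sel$count
  if (signed && strand == "-") count <- -count
  lines <- if (nrow(sel)) {
    paste(sel$chrom, sel$pos, sel$pos + 1L, count, sep = "\t")
  } else character(0)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Parse a BEDGRAPH stream into track points
#'
#' @param x Path or character vector of lines.
#' @param strand Strand to attach to the parsed points (BEDGRAPH itself is
#'   unstranded); negative counts are taken as signed-dialect minus-strand
#'   points regardless.
#' @return A track `data.frame` (`chrom`, `pos`, `strand`, `count`).
#' @export
parse_bedgraph <- function(x, strand = "+") {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) abort("BEDGRAPH parse error at line %d", bad[1])
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  count <- as.numeric(vapply(fields, `[[`, character(1), 4L))
  if (any(is.na(pos)) || any(end != pos + 1L)) {
    abort("BEDGRAPH parse error: expected single-nucleotide intervals")
  }
  st <- rep(strand, length(pos))
  st[count < 0] <- "-"
  data.frame(chrom = chrom, pos = pos, strand = st,
             count = as.integer(abs(count)))
}

# read lines from a path or pass a character vector through
read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# ---------------------------------------------------------------------------
# Gene models

#' Construct a gene model
#'
#' A representative transcript with exon/CDS structure. 5'UTR, 3'UTR and
#' introns are always derived (see [derive_features()]), never stored.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom,strand Location.
#' @param exons `data.frame(start, end)`, sorted and disjoint, 0-based
#'   half-open.
#' @param cds `data.frame(start, end)` contained in exons; empty for
#'   non-coding models.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds = NULL) {
  check_strand(strand)
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (!nrow(exons)) abort("gene model %s has no exons", transcript_id)
  if (any(exons$start >= exons$end)) abort("empty exon in %s", transcript_id)
  if (is.unsorted(exons$start) ||
      (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))) {
    abort("exons of %s are unsorted or overlapping", transcript_id)
  }
  if (is.null(cds) || !NROW(cds)) {
    cds <- data.frame(start = integer(0), end = integer(0))
  } else {
    cds <- as.data.frame(cds)[, c("start", "end")]
    cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
    in_exon <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(in_exon)) abort("CDS outside exons in %s", transcript_id)
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 biotype = if (nrow(cds)) "coding" else "non-coding"),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s (%s) %s:%d-%d %s, %d exon(s), %s>\n",
              x$transcript_id, x$gene_id, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons), x$biotype))
  invisible(x)
}

#' Derive transcript sub-features of a gene model
#'
#' Exonic-minus-CDS intervals become UTRs (5' vs 3' resolved by strand), gaps
#' between exons become introns; exons of non-coding models are labelled
#' `noncoding`.
#'
#' @param model A [gene_model()].
#' @return `data.frame(label, start, end)` with labels in
#'   `five_prime_utr`, `cds`, `intron`, `three_prime_utr`, `noncoding`.
#' @export
derive_features <- function(model) {
  ex <- model$exons
  out <- list()
  if (nrow(ex) > 1L) {
    out$intron <- data.frame(label = "intron",
                             start = ex$end[-nrow(ex)], end = ex$start[-1L])
  }
  if (model$biotype == "non-coding") {
    out$nc <- data.frame(label = "noncoding", start = ex$start, end = ex$end)
  } else {
    cds <- model$cds
    out$cds <- data.frame(label = "cds", start = cds$start, end = cds$end)
    cds_lo <- min(cds$start); cds_hi <- max(cds$end)
    utr <- list()
    for (i in seq_len(nrow(ex))) {
      if (ex$start[i] < cds_lo) {
        utr[[length(utr) + 1L]] <-
          data.frame(side = "low", start = ex$start[i],
                     end = min(ex$end[i], cds_lo))
      }
      if (ex$end[i] > cds_hi) {
        utr[[length(utr) + 1L]] <-
          data.frame(side = "high", start = max(ex$start[i], cds_hi),
                     end = ex$end[i])
      }
    }
    if (length(utr)) {
      utr <- do.call(rbind, utr)
      lab5 <- if (model$strand == "+") "low" else "high"
      utr$label <- ifelse(utr$side == lab5, "five_prime_utr", "three_prime_utr")
      out$utr <- utr[, c("label", "start", "end")]
    }
  }
  feats <- do.call(rbind, unname(out))
  if (is.null(feats)) {
    feats <- data.frame(label = character(0), start = integer(0),
                        end = integer(0))
  }
  feats <- feats[order(feats$start), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Parse gene models from BED12 or GFF3
#'
#' Exactly one representative transcript is kept per gene; when an annotation
#' carries several transcripts of a gene, the longest (summed exon length) is
#' chosen and a warning is logged. Transcripts without exons, or with CDS
#' outside exons, are rejected with a warning.
#'
#' @param x Path to the annotation (or lines for `bed12`).
#' @param dialect `"bed12"` or `"gff3"`.
#' @return A list of [gene_model()] objects.
#' @export
parse_gene_models <- function(x, dialect = c("bed12", "gff3")) {
  dialect <- match.arg(dialect)
  models <- if (dialect == "bed12") parse_models_bed12(x) else parse_models_gff3(x)
  pick_representative(models)
}

parse_models_bed12 <- function(x) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(lines)]
  models <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) abort("BED12 parse error at line %d: %d fields", i, length(f))
    chrom <- f[1]; start <- as.integer(f[2]); name <- f[4]; strand <- f[6]
    thick_s <- as.integer(f[7]); thick_e <- as.integer(f[8])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    offs <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != as.integer(f[10]) || length(sizes) != length(offs)) {
      abort("BED12 parse error at line %d: block count mismatch", i)
    }
    ex <- data.frame(start = start + offs, end = start + offs + sizes)
    cds <- if (thick_e > thick_s) {
      cs <- pmax(ex$start, thick_s); ce <- pmin(ex$end, thick_e)
      keep <- cs < ce
      data.frame(start = cs[keep], end = ce[keep])
    } else NULL
    gene_id <- sub("\\.\\d+$", "", name)
    m <- tryCatch(gene_model(gene_id, name, chrom, strand, ex, cds),
                  error = function(e) {
                    warnf("rejecting model at line %d: %s", i, conditionMessage(e))
                    NULL
                  })
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  models
}

parse_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  tx_rows <- which(type %in% c("mRNA", "transcript", "ncRNA", "lncRNA",
                               "tRNA", "rRNA", "snoRNA", "snRNA", "miRNA"))
  models <- list()
  parent1 <- function(p) if (length(p)) as.character(p[[1]])[1] else NA_character_
  child_parent <- vapply(df$Parent, parent1, character(1))
  for (i in tx_rows) {
    tid <- as.character(df$ID[i])
    gid <- child_parent[i]
    if (is.na(gid)) gid <- tid
    kid <- which(child_parent == tid)
    ex <- df[kid[type[kid] == "exon"], , drop = FALSE]
    cd <- df[kid[type[kid] == "CDS"], , drop = FALSE]
    if (!nrow(ex)) {
      warnf("rejecting transcript %s: no exons", tid)
      next
    }
    to0 <- function(d) {
      d <- data.frame(start = d$start - 1L, end = d$end)
      d[order(d$start), , drop = FALSE]
    }
    m <- tryCatch(
      gene_model(gid, tid, as.character(df$seqnames[i]),
                 as.character(df$strand[i]), to0(ex),
                 if (nrow(cd)) to0(cd) else NULL),
      error = function(e) {
        warnf("rejecting model %s: %s", tid, conditionMessage(e))
        NULL
      })
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  models
}

pick_representative <- function(models) {
  if (!length(models)) return(models)
  gid <- vapply(models, `[[`, character(1), "gene_id")
  len <- vapply(models, function(m) sum(m$exons$end - m$exons$start), integer(1))
  keep <- logical(length(models))
  for (g in unique(gid)) {
    idx <- which(gid == g)
    if (length(idx) > 1L) {
      warnf("gene %s has %d transcripts; keeping the longest", g, length(idx))
      idx <- idx[which.max(len[idx])]
    }
    keep[idx] <- TRUE
  }
  models[keep]
}

# ---------------------------------------------------------------------------
# Sequences

#' Read a FASTA file
#'
#' Sequences are upper-cased; `U` is accepted and mapped to `T` on ingestion.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  # drop description after first whitespace, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ path, or a character vector of lines.
#' @return `data.frame(read_id, seq, qual)` in file order; sequences
#'   upper-cased with `U` mapped to `T`. A truncated final record or a
#'   sequence/quality length mismatch is an error.
#' @export
read_fastq <- function(path) {
  lines <- read_text_lines(path)
  n <- length(lines)
  if (n %% 4L != 0L) abort("FASTQ parse error: truncated record at end of input")
  if (n == 0L) {
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0)))
  }
  idx <- seq(1L, n, by = 4L)
  heads <- lines[idx]
  if (!all(startsWith(heads, "@"))) {
    abort("FASTQ parse error: record %d header does not start with '@'",
          which(!startsWith(heads, "@"))[1])
  }
  seqs <- toupper(chartr("U", "T", lines[idx + 1L]))
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    abort("FASTQ parse error: record %d sequence/quality length mismatch", bad[1])
  }
  data.frame(read_id = sub("\\s.*$", "", substring(heads, 2L)),
             seq = seqs, qual = quals)
}

#' Write reads as FASTQ
#'
#' @param reads `data.frame(read_id, seq, qual)`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  if (!nrow(reads)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}
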