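# Strand-specific sequence windows around binding sites and k-mer
# enrichment with positional density relative to the site centres. This is
# a deliberately simple, fully specified stand-in for external de novo
# motif discovery tools: exhaustive k-mers scored by z-score against
# dinucleotide-preserving shuffles.

#' Extract strand-specific sequence windows around binding sites
#'
#' Each site is extended by `ext` nucleotides on both sides and the genomic
#' sequence of `[start - ext, end + ext)` extracted; minus-strand sites are
#' reverse-complemented, so all windows read 5'->3' with the binding site at
#' the centre (length `width + 2 * ext`, 69 nt at the defaults). Sites whose
#' extended window leaves the chromosome are dropped with a warning, as are
#' windows with more than `max_n_frac` ambiguous bases.
#'
#' @param sites Binding-site data frame.
#' @param genome Named character vector of chromosome sequences.
#' @param ext Extension on each side (default 30).
#' @param max_n_frac Maximum tolerated fraction of `N` (default 0.1).
#' @return Character vector of window sequences (named by
#'   `chrom:start-end(strand)` of the window).
#' @export
extract_site_sequences <- function(sites, genome, ext = 30L,
                                   max_n_frac = 0.1) {
  missing_chrom <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chrom)) {
    abort("chromosome(s) absent from genome: %s",
          paste(missing_chrom, collapse = ", "))
  }
  w_start <- sites$start - ext
  w_end <- sites$end + ext
  len <- nchar(genome)[sites$chrom]
  ok <- w_start >= 0L & w_end <= len
  if (any(!ok)) {
    warnf("%d site window(s) outside chromosome bounds dropped", sum(!ok))
  }
  idx <- which(ok)
  seqs <- substr(genome[sites$chrom[idx]], w_start[idx] + 1L, w_end[idx])
  minus <- sites$strand[idx] == "-"
  seqs[minus] <- revcomp(seqs[minus])
  names(seqs) <- sprintf("%s:%d-%d(%s)", sites$chrom[idx], w_start[idx],
                         w_end[idx], sites$strand[idx])
  n_frac <- vapply(seqs, function(s) {
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s)
  }, numeric(1))
  if (any(n_frac > max_n_frac)) {
    warnf("%d window(s) with > %d%% N dropped", sum(n_frac > max_n_frac),
          round(100 * max_n_frac))
  }
  seqs[n_frac <= max_n_frac]
}

#' Dinucleotide-preserving shuffle of one sequence
#'
#' Eulerian-path shuffle: the shuffled sequence has exactly the original
#' dinucleotide (and hence mononucleotide) composition. The random "last
#' edge" arborescence construction is used, with rejection until the last
#' edges form a tree into the terminal vertex.
#'
#' @param seq A sequence string.
#' @return A shuffled string of the same length.
#' @export
dinuc_shuffle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n <= 3L) return(seq)
  verts <- unique(chars)
  if (length(verts) == 1L) return(seq)
  s_last <- chars[n]
  adj <- split(chars[-1L], factor(chars[-n], levels = verts))
  # choose a random last edge per non-terminal vertex until they form an
  # arborescence into the terminal vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      e <- adj[[v]]
      if (v == s_last || !length(e)) NA_character_
      else e[[sample.int(length(e), 1L)]]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == s_last || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != s_last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute the remaining edges and append each vertex's last edge
  for (v in verts) {
    e <- adj[[v]]
    if (!length(e)) next
    if (!is.na(last_edge[[v]])) {
      drop1 <- match(last_edge[[v]], e)
      e <- e[-drop1]
    }
    e <- if (length(e) > 1L) e[sample.int(length(e))] else e
    if (!is.na(last_edge[[v]])) e <- c(e, last_edge[[v]])
    adj[[v]] <- e
  }
  # walk the Eulerian path from the original first vertex
  out <- character(n)
  out[1L] <- chars[1L]
  ptr <- setNames(integer(length(verts)), verts)
  cur <- chars[1L]
  for (i in 2:n) {
    ptr[cur] <- ptr[cur] + 1L
    nxt <- adj[[cur]][ptr[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste0(out, collapse = "")
}

#' Mononucleotide shuffle of one sequence
#'
#' @param seq A sequence string.
#' @return A shuffled string (same base composition).
#' @export
mono_shuffle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  paste0(chars[sample.int(length(chars))], collapse = "")
}

# total k-mer occurrence counts across a set of equal-length sequences
count_kmers <- function(seqs, k) {
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  colSums(counts)
}

#' k-mer enrichment against a shuffled background
#'
#' Foreground counts are the occurrences of every k-mer across the windows;
#' the background is `n_shuffles` rounds of per-sequence
#' dinucleotide-preserving shuffles (composition-bias control), and each
#' k-mer's z-score is `(fg - bg_mean) / max(bg_sd, 1)`. Results are ranked
#' by z-score descending, ties broken lexicographically. Identical seeds
#' yield identical rankings and z-scores.
#'
#' @param seqs Equal-length sequence windows from
#'   [extract_site_sequences()].
#' @param k k-mer length.
#' @param n_shuffles Number of shuffle rounds (>= 10).
#' @param seed Integer seed for the shuffles.
#' @param shuffle `"dinuc"` (default) or `"mono"`.
#' @return `data.frame(kmer, fg_count, bg_mean, bg_sd, zscore)` ranked by
#'   z-score.
#' @export
kmer_enrichment <- function(seqs, k, n_shuffles = 50L, seed = 1L,
                            shuffle = c("dinuc", "mono")) {
  shuffle <- match.arg(shuffle)
  stopifnot(length(seqs) > 0, n_shuffles >= 10L)
  if (length(unique(nchar(seqs))) != 1L) {
    abort("kmer_enrichment expects equal-length windows")
  }
  if (k > nchar(seqs[[1]])) abort("k exceeds the window length")
  shuf_fun <- if (shuffle == "dinuc") dinuc_shuffle else mono_shuffle
  fg <- count_kmers(seqs, k)
  # each sequence's shuffle stream is seeded from its content, so results do
  # not depend on the order in which windows are supplied
  hashes <- vapply(seqs, function(s) {
    as.integer(sum(utf8ToInt(s) * seq_len(nchar(s))) %% 1048573L)
  }, integer(1))
  bg <- matrix(0, nrow = n_shuffles, ncol = length(fg),
               dimnames = list(NULL, names(fg)))
  for (s in seq_len(n_shuffles)) {
    shuffled <- vapply(seq_along(seqs), function(j) {
      set.seed((seed + hashes[j] * 613L + s * 7919L) %% 2147483647L)
      shuf_fun(seqs[[j]])
    }, character(1))
    bg[s, ] <- count_kmers(shuffled, k)
  }
  bg_mean <- colMeans(bg)
  bg_sd <- apply(bg, 2L, sd)
  z <- (fg - bg_mean) / pmax(bg_sd, 1)
  out <- data.frame(kmer = names(fg), fg_count = as.integer(fg),
                    bg_mean = bg_mean, bg_sd = bg_sd, zscore = z,
                    row.names = NULL)
  out <- out[order(-out$zscore, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional density of a k-mer relative to window centres
#'
#' Histogram of k-mer start offsets relative to the centre position
#' `(L - 1) / 2` of the windows, normalised to sum to 1. A motif always
#' centred on the binding site has a point mass at offset `-floor(k / 2)`.
#'
#' @param kmer The k-mer.
#' @param seqs Equal-length windows.
#' @return `data.frame(offset, density)` over every possible start offset;
#'   all-zero (with attribute `no_hits = TRUE`) when the k-mer never
#'   occurs.
#' @export
positional_density <- function(kmer, seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("positional_density expects equal-length windows")
  k <- nchar(kmer)
  center <- (L - 1) / 2
  hits <- Biostrings::vmatchPattern(kmer, Biostrings::DNAStringSet(seqs))
  starts <- unlist(lapply(hits, IRanges::start), use.names = FALSE)
  offsets <- (starts - 1) - center  # 0-based start relative to centre
  all_off <- (0:(L - k)) - center
  dens <- as.numeric(table(factor(offsets, levels = all_off)))
  no_hits <- sum(dens) == 0
  if (!no_hits) dens <- dens / sum(dens)
  out <- data.frame(offset = all_off, density = dens)
  attr(out, "no_hits") <- no_hits
  out
}
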