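# Single-nucleotide crosslink peaks and fixed-width binding-site windows.
# Binding sites are peak positions extended by `ext` nucleotides on both
# sides (9-nt windows at the default ext = 4); windows with a single
# crosslinked position are excluded as mapping artifacts.

#' Ingest single-nucleotide peaks from BED6
#'
#' Accepts external narrow-peak caller output: 6-column BED with
#' single-nucleotide intervals (`end = start + 1`), score in column 5.
#'
#' @param x Path or lines.
#' @return `data.frame(chrom, pos, strand, score)`.
#' @export
ingest_peaks <- function(x) {
  iv <- parse_bed(x, n_cols = 6L)
  wide <- which(iv$end - iv$start != 1L)
  if (length(wide)) {
    abort(paste0("peak %d spans %d nt; expected single-nucleotide intervals ",
                 "(narrow-peak caller output)"),
          wide[1], iv$end[wide[1]] - iv$start[wide[1]])
  }
  data.frame(chrom = iv$chrom, pos = iv$start, strand = iv$strand,
             score = iv$score)
}

#' Naive local-enrichment peak caller
#'
#' A clearly-labelled stand-in for an external HMM-based caller: position
#' `p` is a peak iff `count(p) >= min_count` and
#' `count(p) >= min_fold * (mean count over [p - flank, p + flank] excluding
#' p, plus a pseudocount of 1)`; the score is that fold ratio. The default
#' parameters (`min_count = 2`, `flank = 15`, `min_fold = 2`) are stand-in
#' values, not derived from any external caller.
#'
#' @param track A crosslink track.
#' @param min_count Minimum crosslink count at a peak position.
#' @param flank Half-width of the local background window.
#' @param min_fold Minimum fold enrichment over local mean + 1.
#' @return `data.frame(chrom, pos, strand, score)` sorted by
#'   (chrom, strand, pos).
#' @export
call_peaks_naive <- function(track, min_count = 2L, flank = 15L,
                             min_fold = 2) {
  stopifnot(min_count >= 1L, flank >= 1L)
  out <- list()
  dt <- data.table::as.data.table(track)
  if (nrow(dt)) {
    groups <- dt[, .(grp = .GRP), by = .(chrom, strand)]
    for (g in seq_len(nrow(groups))) {
      sub <- dt[chrom == groups$chrom[g] & strand == groups$strand[g]]
      pos <- sub$pos; cnt <- as.numeric(sub$count)
      lo <- min(pos); hi <- max(pos)
      dense <- numeric(hi - lo + 1L + 2L * flank)
      dense[pos - lo + 1L + flank] <- cnt
      cs <- cumsum(dense)
      idx <- pos - lo + 1L + flank
      win_sum <- cs[idx + flank] - c(0, cs)[idx - flank]
      mean_excl <- (win_sum - cnt) / (2 * flank)
      score <- cnt / (mean_excl + 1)
      is_peak <- cnt >= min_count & score >= min_fold
      if (any(is_peak)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = groups$chrom[g], pos = pos[is_peak], strand = groups$strand[g],
          score = score[is_peak])
      }
    }
  }
  peaks <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(0), pos = integer(0), strand = character(0),
               score = numeric(0))
  }
  peaks <- peaks[order(peaks$chrom, peaks$strand, peaks$pos), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Resolve adjacent single-nucleotide peaks
#'
#' Maximal runs of directly adjacent positions (genomic distance exactly 1,
#' same chromosome and strand) are each reduced to their single
#' highest-scoring member to minimise redundancy; score ties keep the
#' 5'-most genomic position (smallest `pos`).
#'
#' @param peaks Peak data frame sorted by (chrom, strand, pos).
#' @return The resolved peak data frame (no two retained peaks at distance 1
#'   on the same chromosome and strand).
#' @export
resolve_adjacent <- function(peaks) {
  if (!nrow(peaks)) return(peaks)
  o <- order(peaks$chrom, peaks$strand, peaks$pos)
  if (!identical(o, seq_len(nrow(peaks)))) {
    abort("resolve_adjacent: peaks must be sorted by (chrom, strand, pos)")
  }
  new_run <- c(TRUE, !(peaks$chrom[-1L] == peaks$chrom[-nrow(peaks)] &
                         peaks$strand[-1L] == peaks$strand[-nrow(peaks)] &
                         peaks$pos[-1L] == peaks$pos[-nrow(peaks)] + 1L))
  run <- cumsum(new_run)
  keep <- vapply(split(seq_len(nrow(peaks)), run), function(idx) {
    idx[which.max(peaks$score[idx])]  # which.max takes the first maximum
  }, integer(1))
  out <- peaks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build fixed-width binding sites around resolved peaks
#'
#' One site per peak, spanning `[pos - ext, pos + ext + 1)` (width
#' `2 * ext + 1`, 9 nt at the default). Sites that would be clipped at
#' chromosome bounds are dropped with a warning, because the width must stay
#' fixed.
#'
#' @param peaks Resolved peak data frame.
#' @param ext Extension in nucleotides on each side (default 4).
#' @param chrom_lengths Optional named integer vector of chromosome lengths.
#' @return `data.frame(chrom, start, end, strand, peak_pos, score)`.
#' @export
make_sites <- function(peaks, ext = 4L, chrom_lengths = NULL) {
  stopifnot(ext >= 0L)
  start <- peaks$pos - ext
  end <- peaks$pos + ext + 1L
  ok <- start >= 0L
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[peaks$chrom]
    if (any(is.na(len))) abort("chromosome missing from chrom_lengths")
    ok <- ok & end <= len
  }
  if (any(!ok)) {
    warnf("%d site(s) clipped at chromosome bounds dropped", sum(!ok))
  }
  data.frame(chrom = peaks$chrom[ok], start = as.integer(start[ok]),
             end = as.integer(end[ok]), strand = peaks$strand[ok],
             peak_pos = peaks$pos[ok], score = peaks$score[ok])
}

#' Exclude binding sites with a single crosslinked position
#'
#' A site is retained iff at least `min_xl_positions` distinct positions in
#' `[start, end)` carry a crosslink (count >= 1) on the merged
#' across-replicate track; single-position windows are considered mapping
#' artifacts. The number of distinct crosslinked positions is recorded on
#' each retained site as `n_xl_positions`.
#'
#' @param sites Binding-site data frame from [make_sites()].
#' @param merged_track The across-replicate merged crosslink track.
#' @param min_xl_positions Minimum number of distinct crosslinked positions
#'   (default 2).
#' @return The retained sites with an `n_xl_positions` column.
#' @export
filter_single_xl <- function(sites, merged_track, min_xl_positions = 2L) {
  sites$n_xl_positions <- count_window_positions(sites, merged_track)
  out <- sites[sites$n_xl_positions >= min_xl_positions, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-site window statistics against a track: number of distinct crosslinked
# positions and summed crosslink count within [start, end), same chrom+strand.
# Track positions per group are sorted, so interval queries reduce to
# findInterval on the position vector and a cumulative count sum.
window_stats <- function(sites, track) {
  n_pos <- integer(nrow(sites))
  n_sum <- integer(nrow(sites))
  if (!nrow(sites) || !nrow(track)) {
    return(list(n_positions = n_pos, count_sum = n_sum))
  }
  skey <- paste(sites$chrom, sites$strand)
  tkey <- paste(track$chrom, track$strand)
  for (g in unique(skey)) {
    si <- which(skey == g)
    ti <- which(tkey == g)
    if (!length(ti)) next
    pos <- sort(track$pos[ti])
    cnt <- track$count[ti][order(track$pos[ti])]
    cum <- c(0L, cumsum(cnt))
    hi <- findInterval(sites$end[si] - 1L, pos)
    lo <- findInterval(sites$start[si] - 1L, pos)
    n_pos[si] <- hi - lo
    n_sum[si] <- as.integer(cum[hi + 1L] - cum[lo + 1L])
  }
  list(n_positions = n_pos, count_sum = n_sum)
}

# number of distinct crosslinked track positions within each site window
count_window_positions <- function(sites, track) {
  window_stats(sites, track)$n_positions
}

# summed crosslink count of a track within each site window
sum_window_counts <- function(sites, track) {
  window_stats(sites, track)$count_sum
}
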