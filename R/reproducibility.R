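# Replicate-reproducibility classification of binding sites: per-replicate
# crosslink support within each site window, per-replicate 30%-quantile
# thresholds over positive support counts, a k-of-n rule, and subtraction of
# control-library sites.

#' Count per-replicate crosslink support within binding sites
#'
#' `counts[i, r]` is the total number of crosslink events of replicate `r`
#' at positions within site `i`'s window, strand-matched.
#'
#' @param sites Binding-site data frame.
#' @param replicate_tracks Named list of per-replicate deduplicated crosslink
#'   tracks; names are the replicate labels.
#' @return A support matrix (sites x replicates) of non-negative integers.
#' @export
count_support <- function(sites, replicate_tracks) {
  labels <- names(replicate_tracks)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    abort("replicate_tracks must be a uniquely named list")
  }
  counts <- vapply(replicate_tracks, function(tr) sum_window_counts(sites, tr),
                   integer(nrow(sites)))
  counts <- matrix(as.integer(counts), nrow = nrow(sites),
                   dimnames = list(NULL, labels))
  counts
}

#' Quantile support threshold of one replicate
#'
#' Over the multiset of strictly positive support counts of a replicate, the
#' threshold is the smallest observed count `c` such that the fraction of
#' values `<= c` is at least `q` (empirical CDF inversion, no
#' interpolation). A replicate with no positive counts supports nothing
#' (threshold `+Inf`).
#'
#' @param counts_column Integer vector of per-site support counts.
#' @param q Quantile in (0, 1); default 0.30.
#' @return The integer threshold (or `Inf`).
#' @export
quantile_threshold <- function(counts_column, q = 0.30) {
  stopifnot(q > 0, q < 1)
  pos <- counts_column[counts_column > 0]
  if (!length(pos)) return(Inf)
  vals <- sort(unique(pos))
  cdf <- vapply(vals, function(v) mean(pos <= v), numeric(1))
  vals[which(cdf >= q)[1]]
}

#' Classify binding sites as reproducible
#'
#' A site is supported in replicate `r` iff its count passes that
#' replicate's threshold (`>=` by default; "above the threshold" counts
#' attainment as passing because the thresholds are minimal required
#' crosslink numbers), and classified reproducible iff it is supported in at
#' least `k` of the replicates. Also tallies the replicate-overlap
#' histogram: the number of sites supported in exactly 1, 2, ..., n
#' replicates, with below-threshold sites (supported in none) counted
#' separately.
#'
#' @param counts Support matrix from [count_support()].
#' @param thresholds Named numeric vector of per-replicate thresholds; when
#'   `NULL`, computed per column by [quantile_threshold()] at `q`.
#' @param k Minimum number of supporting replicates (default 2).
#' @param q Quantile passed to [quantile_threshold()].
#' @param cmp `">="` (default) or `">"`: how a count is compared with the
#'   threshold.
#' @return List with `reproducible` (logical per site),
#'   `n_replicates_supported` (integer per site), `supported` (logical
#'   matrix), `thresholds`, and `histogram` (counts of sites by number of
#'   supporting replicates, names `"0"` (below threshold) to `"n"`).
#' @export
classify_reproducible <- function(counts, thresholds = NULL, k = 2L,
                                  q = 0.30, cmp = c(">=", ">")) {
  cmp <- match.arg(cmp)
  n_rep <- ncol(counts)
  stopifnot(k >= 1L, k <= n_rep)
  if (is.null(thresholds)) {
    thresholds <- apply(counts, 2L, quantile_threshold, q = q)
  }
  if (is.null(names(thresholds))) names(thresholds) <- colnames(counts)
  thresholds <- thresholds[colnames(counts)]
  if (any(is.na(thresholds))) abort("threshold missing for some replicate")
  thr <- matrix(thresholds, nrow = nrow(counts), ncol = n_rep, byrow = TRUE)
  supported <- if (cmp == ">=") counts >= thr else counts > thr
  n_sup <- as.integer(rowSums(supported))
  hist <- vapply(0:n_rep, function(i) sum(n_sup == i), integer(1))
  names(hist) <- as.character(0:n_rep)
  list(reproducible = n_sup >= k, n_replicates_supported = n_sup,
       supported = supported, thresholds = thresholds, histogram = hist)
}

# strand-aware interval overlap (>= 1 shared nucleotide) between two
# binding-site data frames, via GenomicRanges
sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = sites$strand)
}

#' Subtract control-library binding sites
#'
#' A site is removed iff it overlaps (at least one shared nucleotide, same
#' strand) any site in the union of the control sets; retained sites are
#' unchanged. Control sets are binding-site tables produced by the same
#' pipeline from control libraries (e.g. GFP-only and RNA-binding-dead
#' samples).
#'
#' @param sites Binding-site data frame.
#' @param control_site_sets List of control binding-site data frames.
#' @return The retained sites.
#' @export
subtract_controls <- function(sites, control_site_sets) {
  if (!nrow(sites)) return(sites)
  ctrl <- control_site_sets[vapply(control_site_sets, NROW, integer(1)) > 0]
  if (!length(ctrl)) return(sites)
  ctrl_df <- do.call(rbind, lapply(ctrl, function(s) {
    s[, c("chrom", "start", "end", "strand"), drop = FALSE]
  }))
  hits <- GenomicRanges::findOverlaps(sites_granges(sites),
                                      sites_granges(ctrl_df),
                                      ignore.strand = FALSE)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- sites[setdiff(seq_len(nrow(sites)), drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcript-level set overlap
#'
#' Set algebra on distinct transcript identifiers, for comparing two target
#' compendia.
#'
#' @param ids_a,ids_b Character vectors of transcript ids (duplicates
#'   ignored).
#' @return List `only_a`, `only_b`, `shared` (counts), plus the id sets.
#' @export
set_overlap <- function(ids_a, ids_b) {
  a <- unique(ids_a); b <- unique(ids_b)
  shared <- intersect(a, b)
  list(only_a = length(setdiff(a, b)), only_b = length(setdiff(b, a)),
       shared = length(shared), shared_ids = shared)
}
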