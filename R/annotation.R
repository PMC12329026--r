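# Transcript-region assignment of binding sites and the region distribution
# against a genomic-length background.

REGION_LABELS <- c("three_prime_utr", "five_prime_utr", "cds", "intron",
                   "noncoding")  # in assignment priority order

# flatten derived features of all models into one table
feature_table <- function(models) {
  feats <- lapply(models, function(m) {
    f <- derive_features(m)
    if (!nrow(f)) return(NULL)
    f$chrom <- m$chrom; f$strand <- m$strand
    f$transcript_id <- m$transcript_id
    f
  })
  feats <- do.call(rbind, feats)
  if (is.null(feats)) {
    feats <- data.frame(label = character(0), start = integer(0),
                        end = integer(0), chrom = character(0),
                        strand = character(0), transcript_id = character(0))
  }
  feats
}

#' Assign binding sites to transcript regions
#'
#' Each site is anchored at its `peak_pos` (the window centre), located
#' within same-strand gene models only (iCLIP is strand-specific), and
#' among all features covering that position the label is chosen by the
#' fixed priority `three_prime_utr > five_prime_utr > cds > intron >
#' noncoding`. A site covered by no feature is `intergenic` with no
#' transcript. The centre anchor guarantees exactly one label per site.
#'
#' @param sites Binding-site data frame with `peak_pos`.
#' @param models List of [gene_model()] objects.
#' @param priority Label priority order (highest first); configurable.
#' @return `sites` with `region` and `transcript_id` columns appended.
#' @export
assign_region <- function(sites, models,
                          priority = REGION_LABELS) {
  stopifnot(setequal(priority, REGION_LABELS))
  feats <- feature_table(models)
  region <- rep("intergenic", nrow(sites))
  transcript <- rep(NA_character_, nrow(sites))
  if (nrow(feats) && nrow(sites)) {
    fg <- GenomicRanges::GRanges(feats$chrom,
                                 IRanges::IRanges(feats$start + 1L, feats$end),
                                 strand = feats$strand)
    sg <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$peak_pos + 1L,
                                                  sites$peak_pos + 1L),
                                 strand = sites$strand)
    hits <- GenomicRanges::findOverlaps(sg, fg, ignore.strand = FALSE)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      rank <- match(feats$label[sh], priority)
      best <- tapply(seq_along(qh), qh, function(i) i[which.min(rank[i])])
      bi <- unlist(best, use.names = FALSE)
      region[qh[bi]] <- feats$label[sh[bi]]
      transcript[qh[bi]] <- feats$transcript_id[sh[bi]]
    }
  }
  sites$region <- region
  sites$transcript_id <- transcript
  sites
}

#' Region distribution of assigned sites vs cumulative feature length
#'
#' Site percentages are over assigned (non-intergenic) sites by default; the
#' background percentage of a label is the share of the summed length of all
#' features of that label across the gene models, with overlaps within a
#' label merged. Both columns sum to 100 over the same labels.
#'
#' @param assigned Output of [assign_region()].
#' @param models List of gene models.
#' @param include_intergenic Include intergenic sites in the site
#'   percentages (they have no length background; default `FALSE`).
#' @return `data.frame(region, site_count, site_percent,
#'   background_percent)`.
#' @export
region_distribution <- function(assigned, models, include_intergenic = FALSE) {
  keep <- if (include_intergenic) rep(TRUE, nrow(assigned)) else
    assigned$region != "intergenic"
  counted <- assigned[keep, , drop = FALSE]
  if (!nrow(counted)) abort("region_distribution: zero assigned sites")
  labels <- intersect(c("five_prime_utr", "cds", "intron", "three_prime_utr",
                        "noncoding", "intergenic"),
                      if (include_intergenic) unique(counted$region) else
                        setdiff(unique(counted$region), "intergenic"))
  site_count <- vapply(labels, function(l) sum(counted$region == l), integer(1))
  feats <- feature_table(models)
  bg_len <- vapply(labels, function(l) {
    f <- feats[feats$label == l, , drop = FALSE]
    if (!nrow(f)) return(0)
    r <- IRanges::reduce(GenomicRanges::GRanges(
      paste(f$chrom, f$strand), IRanges::IRanges(f$start + 1L, f$end)))
    sum(GenomicRanges::width(r))
  }, numeric(1))
  data.frame(region = labels,
             site_count = site_count,
             site_percent = 100 * site_count / sum(site_count),
             background_percent = if (sum(bg_len) > 0)
               100 * bg_len / sum(bg_len) else NA_real_,
             row.names = NULL)
}

#' Target transcripts of a site set
#'
#' A target transcript is a transcript carrying at least one reproducible
#' binding site.
#'
#' @param assigned Output of [assign_region()].
#' @return Character vector of distinct transcript ids.
#' @export
target_transcripts <- function(assigned) {
  sort(unique(assigned$transcript_id[!is.na(assigned$transcript_id)]))
}
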