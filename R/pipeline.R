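# Orchestration of the full binding-site workflow: preprocess -> ingest and
# deduplicate -> crosslink tracks -> peaks -> sites -> reproducibility ->
# control subtraction -> region assignment -> motif enrichment, with a
# per-stage accounting table and a JSON run manifest. Execution is
# single-threaded and deterministic: identical config and inputs give
# byte-identical outputs.

#' Pipeline run configuration
#'
#' Defaults match the stated analysis parameters: binding-site extension 4
#' (9-nt windows), at least 2 crosslinked positions per window, 30% quantile
#' support threshold, 2-of-n replicate rule, 24-nt minimum insert length,
#' motif windows extended by 30 nt. The naive peak caller's parameters are
#' stand-in values for an external caller.
#'
#' @param ext Site extension per side (nt).
#' @param min_xl_positions Minimum distinct crosslinked positions per window.
#' @param q Support quantile.
#' @param k_of_n Minimum supporting replicates.
#' @param support_cmp `">="` or `">"`.
#' @param motif_ext Motif window extension per side (nt).
#' @param motif_k k-mer lengths to score.
#' @param n_shuffles Background shuffle rounds.
#' @param min_len Minimum insert length for the read preprocessor.
#' @param adapter 3' adapter sequence.
#' @param dedup_anchor `"five_prime"` or `"left_coordinate"`.
#' @param peak_min_count,peak_flank,peak_min_fold Naive caller parameters.
#' @param subtract_controls Subtract control-library sites.
#' @param seed Seed for the motif shuffles.
#' @return A `run_config` list.
#' @export
run_config <- function(ext = 4L, min_xl_positions = 2L, q = 0.30,
                       k_of_n = 2L, support_cmp = ">=", motif_ext = 30L,
                       motif_k = 5L, n_shuffles = 50L, min_len = 24L,
                       adapter = NULL, dedup_anchor = "five_prime",
                       peak_min_count = 2L, peak_flank = 15L,
                       peak_min_fold = 2, subtract_controls = TRUE,
                       seed = 1L) {
  as.list(environment())
}

# single-library site calling used for control samples: own track, own
# peaks, own thresholds, k = 1
call_library_sites <- function(track, config, chrom_lengths) {
  peaks <- call_peaks_naive(track, config$peak_min_count, config$peak_flank,
                            config$peak_min_fold)
  sites <- make_sites(resolve_adjacent(peaks), config$ext, chrom_lengths)
  sites <- filter_single_xl(sites, track, config$min_xl_positions)
  if (!nrow(sites)) return(sites)
  counts <- count_support(sites, setNames(list(track),
                                          attr(track, "library") %||% "lib"))
  cls <- classify_reproducible(counts, k = 1L, q = config$q,
                               cmp = config$support_cmp)
  out <- sites[cls$reproducible, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full binding-site determination pipeline
#'
#' @param input A [simulate_experiment()] result, or a fixture directory
#'   written by [sim_fixture()] (containing `genome.fa`, `models.bed12` and
#'   `<lib>.aligned.tsv` files; libraries named `rep*` are replicates,
#'   `ctrl*` are controls).
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, BED/BEDGRAPH/TSV
#'   artifacts and a JSON manifest are written (stable sorts before every
#'   write, so reruns are byte-identical).
#' @return A list with the per-stage results: `tracks`, `merged_track`,
#'   `peaks`, `resolved_peaks`, `sites`, `support`, `classification`,
#'   `reproducible_sites`, `control_sites`, `final_sites` (region-annotated),
#'   `region_distribution`, `target_transcripts`, `motifs` (per k),
#'   `densities`, `accounting`, `config`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  if (is.character(input)) input <- load_fixture(input)
  genome <- input$genome
  chrom_lengths <- input$chrom_lengths %||%
    setNames(nchar(genome), names(genome))
  models <- input$models
  libs <- input$libraries
  rep_labels <- grep("^rep", names(libs), value = TRUE)
  ctrl_labels <- grep("^ctrl", names(libs), value = TRUE)
  if (!length(rep_labels)) abort("no replicate libraries in input")

  # per-replicate dedup and crosslink tracks
  tracks <- list()
  acct <- list()
  for (lab in c(rep_labels, ctrl_labels)) {
    al <- libs[[lab]]$aligned
    dd <- dedup(al, config$dedup_anchor)
    tracks[[lab]] <- build_track(dd$reads, lab, chrom_lengths)
    acct[[lab]] <- data.frame(library = lab, aligned = nrow(al),
                              after_dedup = nrow(dd$reads),
                              crosslink_events = sum(tracks[[lab]]$count))
  }
  accounting <- do.call(rbind, acct)
  rownames(accounting) <- NULL

  merged <- merge_tracks(tracks[rep_labels])

  peaks <- call_peaks_naive(merged, config$peak_min_count, config$peak_flank,
                            config$peak_min_fold)
  resolved <- resolve_adjacent(peaks)
  sites <- make_sites(resolved, config$ext, chrom_lengths)
  sites <- filter_single_xl(sites, merged, config$min_xl_positions)

  support <- count_support(sites, tracks[rep_labels])
  cls <- classify_reproducible(support, k = config$k_of_n, q = config$q,
                               cmp = config$support_cmp)
  repro <- sites[cls$reproducible, , drop = FALSE]
  repro$n_replicates_supported <-
    cls$n_replicates_supported[cls$reproducible]
  rownames(repro) <- NULL

  control_sites <- lapply(tracks[ctrl_labels], call_library_sites, config,
                          chrom_lengths)
  final <- if (isTRUE(config$subtract_controls) && length(control_sites)) {
    subtract_controls(repro, control_sites)
  } else repro

  final <- assign_region(final, models)
  region_dist <- if (nrow(final)) region_distribution(final, models) else NULL
  targets <- target_transcripts(final)

  motifs <- list(); densities <- list(); site_seqs <- character(0)
  if (nrow(final) && !is.null(genome)) {
    site_seqs <- extract_site_sequences(final, genome, config$motif_ext)
    if (length(site_seqs)) {
      for (k in config$motif_k) {
        key <- as.character(k)
        motifs[[key]] <- kmer_enrichment(site_seqs, k, config$n_shuffles,
                                         seed = config$seed)
        densities[[key]] <- positional_density(motifs[[key]]$kmer[1L],
                                               site_seqs)
      }
    }
  }

  result <- list(tracks = tracks, merged_track = merged, peaks = peaks,
                 resolved_peaks = resolved, sites = sites, support = support,
                 classification = cls, reproducible_sites = repro,
                 control_sites = control_sites, final_sites = final,
                 region_distribution = region_dist,
                 target_transcripts = targets, site_sequences = site_seqs,
                 motifs = motifs, densities = densities,
                 accounting = accounting, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

load_fixture <- function(dir) {
  genome_path <- file.path(dir, "genome.fa")
  models_path <- file.path(dir, "models.bed12")
  genome <- if (file.exists(genome_path)) read_fasta(genome_path) else NULL
  models <- if (file.exists(models_path)) {
    parse_gene_models(models_path, "bed12")
  } else list()
  tsvs <- list.files(dir, pattern = "\\.aligned\\.tsv$", full.names = TRUE)
  if (!length(tsvs)) abort("no *.aligned.tsv libraries found in %s", dir)
  labs <- sub("\\.aligned\\.tsv$", "", basename(tsvs))
  libs <- setNames(lapply(tsvs, function(p) {
    list(aligned = ingest_alignments(p, "tsv"))
  }), labs)
  list(genome = genome, models = models, libraries = libs,
       chrom_lengths = if (!is.null(genome))
         setNames(nchar(genome), names(genome)) else NULL)
}

sites_to_bed <- function(sites, score = sites$score,
                         name = as.character(sites$peak_pos)) {
  if (!nrow(sites)) {
    return(genomic_intervals(character(0), integer(0), integer(0) + 1L)[0, ])
  }
  genomic_intervals(sites$chrom, sites$start, sites$end, name = name,
                    score = score, strand = sites$strand)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  for (lab in names(result$tracks)) {
    tr <- result$tracks[[lab]]
    write_bedgraph(tr, "+", p(paste0(lab, ".plus.bedgraph")))
    write_bedgraph(tr, "-", p(paste0(lab, ".minus.bedgraph")))
  }
  write_bedgraph(result$merged_track, "+", p("merged.plus.bedgraph"))
  write_bedgraph(result$merged_track, "-", p("merged.minus.bedgraph"))
  rp <- result$resolved_peaks
  write_bed(genomic_intervals(rp$chrom, rp$pos, rp$pos + 1L, name = "peak",
                              score = rp$score, strand = rp$strand)[
    seq_len(nrow(rp)), , drop = FALSE], p("resolved_peaks.bed"))
  write_bed(sites_to_bed(result$sites), p("sites.bed"))
  write_bed(sites_to_bed(result$reproducible_sites,
                         score = result$reproducible_sites$n_replicates_supported),
            p("reproducible_sites.bed"))
  fs <- result$final_sites
  if (nrow(fs)) {
    bed <- sites_to_bed(fs, score = fs$n_replicates_supported)
    bed$region <- fs$region
    bed$transcript_id <- ifelse(is.na(fs$transcript_id), ".",
                                fs$transcript_id)
    writeLines(do.call(paste, c(unname(as.list(bed)), sep = "\t")),
               p("final_sites.bed"))
  } else writeLines(character(0), p("final_sites.bed"))
  write_tsv(cbind(data.frame(site = seq_len(nrow(result$support))),
                  as.data.frame(result$support)), p("support_matrix.tsv"))
  hist_df <- data.frame(n_replicates = names(result$classification$histogram),
                        n_sites = as.integer(result$classification$histogram))
  write_tsv(hist_df, p("replicate_overlap_histogram.tsv"))
  if (!is.null(result$region_distribution)) {
    write_tsv(result$region_distribution, p("region_distribution.tsv"))
  }
  writeLines(result$target_transcripts, p("target_transcripts.txt"))
  for (k in names(result$motifs)) {
    write_tsv(result$motifs[[k]], p(paste0("kmers_k", k, ".tsv")))
    write_tsv(result$densities[[k]], p(paste0("density_top_k", k, ".tsv")))
  }
  write_tsv(result$accounting, p("accounting.tsv"))
  manifest <- c(result$config,
                list(thresholds = as.list(result$classification$thresholds),
                     n_sites = nrow(result$sites),
                     n_reproducible = nrow(result$reproducible_sites),
                     n_final = nrow(result$final_sites)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' Evaluate pipeline recovery against the generator truth
#'
#' A planted site counts as recovered (recall) when a final site on the
#' same chromosome and strand has its peak within `tol` nt of the planted
#' peak; a final site counts as correct (precision) under the mirrored
#' criterion.
#'
#' @param result A [run_pipeline()] result.
#' @param truth Planted-site table (`$truth` of the simulation).
#' @param tol Matching tolerance in nt (default 4).
#' @return List `recall`, `precision`, `n_truth`, `n_called`, plus the
#'   per-site match indicators.
#' @export
evaluate_recovery <- function(result, truth, tol = 4L) {
  called <- result$final_sites
  match_any <- function(chrom, pos, strand, ref) {
    vapply(seq_along(pos), function(i) {
      any(ref$chrom == chrom[i] & ref$strand == strand[i] &
            abs(ref$pos - pos[i]) <= tol)
    }, logical(1))
  }
  truth_hit <- match_any(truth$chrom, truth$peak_pos, truth$strand,
                         data.frame(chrom = called$chrom,
                                    pos = called$peak_pos,
                                    strand = called$strand))
  called_hit <- match_any(called$chrom, called$peak_pos, called$strand,
                          data.frame(chrom = truth$chrom,
                                     pos = truth$peak_pos,
                                     strand = truth$strand))
  list(recall = if (nrow(truth)) mean(truth_hit) else NA_real_,
       precision = if (nrow(called)) mean(called_hit) else NA_real_,
       n_truth = nrow(truth), n_called = nrow(called),
       truth_recovered = truth_hit, called_correct = called_hit)
}
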