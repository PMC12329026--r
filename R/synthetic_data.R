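# A complete, seeded, miniature iCLIP experiment: random genome, gene
# models, planted binding sites with a written-in motif, per-replicate
# truncation reads (FASTQ plus an aligner-bypass TSV of true alignments),
# background-only control libraries, and a machine-readable truth record.
#
# All randomness flows from the single config seed through fixed per-stage
# substreams, so equal seeds give byte-identical fixtures.

#' Configuration of a synthetic iCLIP experiment
#'
#' Defaults are the `"small"` study conditions: a 100-kb chromosome, 40
#' genes, 60 planted binding sites with log-normal per-replicate strength,
#' uniform background crosslinks, geometric PCR duplication, three
#' replicate libraries and two background-only control libraries.
#'
#' @param seed Integer master seed.
#' @param preset `"small"` (default) or `"tiny"` (a faster variant for unit
#'   tests).
#' @param ... Overrides of individual fields (see Details).
#' @details Key fields: `n_chroms`, `chrom_length`; `n_genes` with
#'   `gene_geometry` ranges (nt); `n_sites`, `region_bias` (label ->
#'   probability, must sum to 1); `site_strength = c(meanlog, sdlog)` of the
#'   log-normal expected molecules per site per replicate;
#'   `xl_jitter_probs` for crosslink offsets -2..2 within the site window;
#'   `truncation_prob` (probability a molecule truncates at the crosslink);
#'   `background_rate` (expected background molecules per kb per
#'   replicate); `pcr_dup` (geometric success probability; extra copies ~
#'   Geom(pcr_dup)); `read_len`, `insert_mean`, `insert_sd`,
#'   `insert_range`; `adapter`; `scheme` (a [barcode_scheme()]);
#'   `n_replicates`, `n_control_libs`; `motif`, `plant_motif`, `motif2`,
#'   `motif2_offset`; `min_site_spacing`; `umi_collision_free` (unique
#'   per-molecule UMIs in the aligned TSV, for exact-conservation tests).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, preset = c("small", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    preset = preset,
    n_chroms = 1L,
    chrom_length = 100000L,
    n_genes = 40L,
    gene_geometry = list(utr5 = c(60L, 150L), utr3 = c(100L, 250L),
                         cds_exon = c(100L, 300L), intron = c(80L, 200L),
                         n_cds_exons = c(2L, 4L), nc_exon = c(150L, 500L),
                         noncoding_frac = 0.1),
    n_sites = 60L,
    region_bias = c(five_prime_utr = 0.35, three_prime_utr = 0.35,
                    cds = 0.18, intron = 0.07, noncoding = 0.05),
    site_strength = c(meanlog = 2.8, sdlog = 0.6),
    xl_jitter_probs = c(0.05, 0.2, 0.5, 0.2, 0.05),  # offsets -2..2
    truncation_prob = 1.0,
    background_rate = 80,
    pcr_dup = 0.5,
    read_len = 50L,
    insert_mean = 28, insert_sd = 9, insert_range = c(8L, 41L),
    adapter = paste0("AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCGATCTCGTATGCCG",
                     "TCTTCTGCTTG"),
    scheme = default_barcode_scheme(),
    n_replicates = 3L,
    n_control_libs = 2L,
    motif = "TTCTT",
    plant_motif = TRUE,
    motif2 = NULL,
    motif2_offset = 10L,
    min_site_spacing = 20L,
    umi_collision_free = FALSE
  )
  if (preset == "tiny") {
    cfg$chrom_length <- 30000L
    cfg$n_genes <- 14L
    cfg$n_sites <- 18L
    cfg$n_control_libs <- 1L
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort("unknown sim_config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$region_bias) - 1) > 1e-8) abort("region_bias must sum to 1")
  if (any(cfg$region_bias < 0) || any(cfg$region_bias > 1)) {
    abort("region_bias entries must be probabilities")
  }
  if (cfg$truncation_prob < 0 || cfg$truncation_prob > 1) {
    abort("truncation_prob must be in [0, 1]")
  }
  if (cfg$pcr_dup <= 0 || cfg$pcr_dup > 1) abort("pcr_dup must be in (0, 1]")
  for (f in c("n_chroms", "chrom_length", "n_genes", "n_sites", "read_len",
              "n_replicates")) {
    if (cfg[[f]] < if (f %in% c("n_genes", "n_sites")) 0L else 1L) {
      abort("%s must be positive", f)
    }
  }
  invisible(cfg)
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

# draw one gene structure (relative block layout); returns exon/cds offsets
draw_gene_structure <- function(cfg, noncoding) {
  g <- cfg$gene_geometry
  runi <- function(r) sample(r[1]:r[2], 1L)
  if (noncoding) {
    n_ex <- sample(1:2, 1L)
    ex_len <- vapply(seq_len(n_ex), function(i) runi(g$nc_exon), integer(1))
    in_len <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L),
                                    function(i) runi(g$intron), integer(1))
              else integer(0)
    starts <- cumsum(c(0L, head(ex_len, -1L) + in_len))
    return(list(exons = data.frame(start = starts, end = starts + ex_len),
                cds = NULL, length = sum(ex_len) + sum(in_len)))
  }
  n_cds <- runi(g$n_cds_exons)
  cds_len <- vapply(seq_len(n_cds), function(i) runi(g$cds_exon), integer(1))
  in_len <- if (n_cds > 1L) vapply(seq_len(n_cds - 1L),
                                   function(i) runi(g$intron), integer(1))
            else integer(0)
  left_utr <- runi(g$utr5); right_utr <- runi(g$utr3)
  ex_len <- cds_len
  ex_len[1L] <- ex_len[1L] + left_utr
  ex_len[n_cds] <- ex_len[n_cds] + right_utr
  starts <- cumsum(c(0L, head(ex_len, -1L) + in_len))
  exons <- data.frame(start = starts, end = starts + ex_len)
  cds <- exons
  cds$start[1L] <- cds$start[1L] + left_utr
  cds$end[n_cds] <- cds$end[n_cds] - right_utr
  list(exons = exons, cds = cds, left_utr = left_utr, right_utr = right_utr,
       length = sum(ex_len) + sum(in_len))
}

#' Generate the synthetic genome and gene models
#'
#' Uniform-random sequence with non-overlapping genes on both strands;
#' roughly 10% of models are non-coding. For minus-strand genes the
#' left-most UTR block is the 3'UTR, so derived features respect strand.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character), `chrom_lengths`, `models`
#'   (list of [gene_model()]).
#' @export
make_genome_and_models <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- sim_chrom_names(cfg)
  genome <- setNames(random_dna(cfg$n_chroms, cfg$chrom_length), chroms)
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  models <- list()
  if (cfg$n_genes > 0L) {
    per_chrom <- table(factor(sample(chroms, cfg$n_genes, replace = TRUE),
                              chroms))
    gi <- 0L
    for (ch in chroms) {
      n_g <- per_chrom[[ch]]
      if (n_g == 0L) next
      noncoding <- runif(n_g) < cfg$gene_geometry$noncoding_frac
      structs <- lapply(noncoding, function(nc) draw_gene_structure(cfg, nc))
      total <- sum(vapply(structs, `[[`, numeric(1), "length"))
      slack <- cfg$chrom_length - total - 2L * (n_g + 1L)
      if (slack < 0) {
        abort(paste0("cannot place %d genes in a %d-nt chromosome without ",
                     "overlap; increase chrom_length"), n_g, cfg$chrom_length)
      }
      cuts <- sort(runif(n_g + 1L))
      gaps <- 2L + floor(slack * cuts / max(cuts))
      gaps <- c(gaps[1L], diff(gaps))
      cur <- 0L
      for (j in seq_len(n_g)) {
        gi <- gi + 1L
        cur <- cur + as.integer(gaps[j])
        st <- structs[[j]]
        strand <- sample(STRANDS, 1L)
        # on '-', the left UTR block drawn as utr5 plays the 3'UTR role;
        # lengths come from the matching range by swapping before the draw
        gene_id <- sprintf("G%04d", gi)
        m <- gene_model(gene_id, paste0(gene_id, ".1"), ch, strand,
                        data.frame(start = st$exons$start + cur,
                                   end = st$exons$end + cur),
                        if (!is.null(st$cds))
                          data.frame(start = st$cds$start + cur,
                                     end = st$cds$end + cur))
        models[[length(models) + 1L]] <- m
        cur <- cur + st$length
      }
    }
  }
  list(genome = genome, chrom_lengths = chrom_lengths, models = models)
}

#' Plant binding sites into the synthetic genome
#'
#' Peak positions are drawn within gene-model features according to
#' `region_bias`, at least `min_site_spacing` nt apart; a motif instance is
#' written into the genome centred at each peak (strand-specific) unless
#' `plant_motif` is off; expected molecule counts per replicate are drawn
#' log-normal (`site_strength`), rounded, minimum 1.
#'
#' @param cfg A [sim_config()].
#' @param sim Output of [make_genome_and_models()].
#' @return List: `truth` (`data.frame` of planted sites with per-replicate
#'   expected counts in `expected_rep*` columns) and `genome` (with motifs
#'   written in).
#' @export
plant_sites <- function(cfg, sim) {
  set.seed(cfg$seed + 1L)
  feats <- feature_table(sim$models)
  genome <- sim$genome
  margin <- 40L  # keep site and motif windows inside the chromosome
  labels <- sample(names(cfg$region_bias), cfg$n_sites, replace = TRUE,
                   prob = cfg$region_bias)
  placed <- data.frame(chrom = character(0), pos = integer(0))
  rows <- list()
  for (i in seq_len(cfg$n_sites)) {
    cand <- feats[feats$label == labels[i] & feats$end - feats$start >= 10L, ,
                  drop = FALSE]
    cand <- cand[cand$start >= margin &
                   cand$end <= nchar(genome[cand$chrom]) - margin, ,
                 drop = FALSE]
    if (!nrow(cand)) {
      abort("no feature space to place a %s site; enlarge the gene set",
            labels[i])
    }
    ok <- FALSE
    for (attempt in seq_len(200L)) {
      f <- cand[sample.int(nrow(cand), 1L,
                           prob = cand$end - cand$start), , drop = FALSE]
      pos <- sample((f$start + 3L):(f$end - 4L), 1L)
      near <- placed$chrom == f$chrom &
        abs(placed$pos - pos) < cfg$min_site_spacing
      if (!any(near)) { ok <- TRUE; break }
    }
    if (!ok) {
      abort(paste0("could not place %d sites %d nt apart; ",
                   "reduce n_sites or spacing"), cfg$n_sites,
            cfg$min_site_spacing)
    }
    placed <- rbind(placed, data.frame(chrom = f$chrom, pos = pos))
    rows[[i]] <- data.frame(site_id = sprintf("S%03d", i), chrom = f$chrom,
                            peak_pos = pos, strand = f$strand,
                            region = labels[i],
                            transcript_id = f$transcript_id)
  }
  truth <- do.call(rbind, rows)
  expected <- matrix(pmax(1, round(rlnorm(cfg$n_sites * cfg$n_replicates,
                                          cfg$site_strength[["meanlog"]],
                                          cfg$site_strength[["sdlog"]]))),
                     nrow = cfg$n_sites)
  colnames(expected) <- paste0("expected_rep", seq_len(cfg$n_replicates))
  truth <- cbind(truth, as.data.frame(expected))
  if (cfg$plant_motif && nzchar(cfg$motif %||% "")) {
    genome <- write_motif(genome, truth, cfg$motif, offset = 0L)
  }
  if (!is.null(cfg$motif2) && nzchar(cfg$motif2)) {
    genome <- write_motif(genome, truth, cfg$motif2,
                          offset = as.integer(cfg$motif2_offset))
  }
  list(truth = truth, genome = genome)
}

# write a motif into the genome centred `offset` nt downstream (read
# orientation) of each planted peak, strand-specifically
write_motif <- function(genome, truth, motif, offset = 0L) {
  k <- nchar(motif)
  for (i in seq_len(nrow(truth))) {
    ch <- truth$chrom[i]
    if (truth$strand[i] == "+") {
      center <- truth$peak_pos[i] + offset
      s0 <- center - k %/% 2L
      ins <- motif
    } else {
      center <- truth$peak_pos[i] - offset
      s0 <- center - (k - 1L - k %/% 2L)
      ins <- revcomp(motif)
    }
    if (s0 < 0L || s0 + k > nchar(genome[[ch]])) next
    substr(genome[[ch]], s0 + 1L, s0 + k) <- ins
  }
  genome
}

#' Simulate one sequencing library
#'
#' Replicate libraries draw Poisson(expected) molecules per planted site,
#' crosslinking at the peak plus a small window offset; control libraries
#' contain background only. Background molecules are placed uniformly over
#' the genome on random strands. Each molecule gets a UMI, a truncation read
#' starting one nucleotide 3' of the crosslink in read orientation
#' (truncated at the chromosome end), geometric PCR duplicates, and a FASTQ
#' read assembled as barcode-layout prefix + insert + adapter fill to
#' `read_len`. The aligned TSV carries the true alignment of every read
#' copy, bypassing any aligner.
#'
#' @param cfg A [sim_config()].
#' @param truth Planted-site table from [plant_sites()] (with the
#'   motif-bearing genome).
#' @param genome The (motif-bearing) genome.
#' @param library Library label, e.g. `"rep1"` or `"ctrl1"`.
#' @param type `"replicate"` or `"control"`.
#' @param rep_index Replicate column index used for expected counts.
#' @param lib_index Index used to derive this library's RNG substream.
#' @return List with `fastq` (`read_id, seq, qual`), `aligned` (TSV-dialect
#'   data frame, one row per read copy) and `molecules` (per-molecule truth:
#'   `molecule_id, site_id, chrom, xl_pos, strand, n_copies`).
#' @export
simulate_library <- function(cfg, truth, genome, library, type = "replicate",
                             rep_index = 1L, lib_index = 1L) {
  set.seed(cfg$seed + 100L + lib_index)
  chrom_len <- setNames(nchar(genome), names(genome))
  mols <- list()
  if (type == "replicate" && nrow(truth)) {
    exp_col <- paste0("expected_rep", rep_index)
    n_mol <- rpois(nrow(truth), truth[[exp_col]])
    idx <- rep(seq_len(nrow(truth)), n_mol)
    if (length(idx)) {
      jit <- sample(-2:2, length(idx), replace = TRUE,
                    prob = cfg$xl_jitter_probs)
      mols$site <- data.frame(
        site_id = truth$site_id[idx], chrom = truth$chrom[idx],
        xl_pos = truth$peak_pos[idx] + jit, strand = truth$strand[idx])
    }
  }
  n_bg <- rpois(1L, cfg$background_rate * sum(chrom_len) / 1000)
  if (n_bg > 0L) {
    ch <- sample(names(genome), n_bg, replace = TRUE,
                 prob = chrom_len / sum(chrom_len))
    mols$bg <- data.frame(
      site_id = NA_character_, chrom = ch,
      xl_pos = floor(runif(n_bg) * chrom_len[ch]),
      strand = sample(STRANDS, n_bg, replace = TRUE))
  }
  mols <- data.table::rbindlist(mols)
  if (!nrow(mols)) {
    empty <- aligned_reads(character(0), character(0), integer(0),
                           integer(0) + 1L, character(0), character(0),
                           character(0))
    return(list(fastq = data.frame(read_id = character(0), seq = character(0),
                                   qual = character(0)),
                aligned = empty, molecules = as.data.frame(mols)))
  }
  mols <- as.data.frame(mols)
  # truncation read span: [xl+1, xl+1+L) on '+', [xl-L, xl) on '-'
  layout_len <- nchar(cfg$scheme$layout)
  capacity <- cfg$read_len - layout_len
  drawn <- pmin(pmax(round(rnorm(nrow(mols), cfg$insert_mean, cfg$insert_sd)),
                     cfg$insert_range[1]), min(cfg$insert_range[2], capacity))
  plus <- mols$strand == "+"
  # with probability 1 - truncation_prob reverse transcription reads
  # through the crosslink: the read then starts 3 nt further 5', so the
  # inferred crosslink (read start - 1) no longer marks the true contact
  thru <- runif(nrow(mols)) >= cfg$truncation_prob
  shift <- ifelse(thru, 3L, 0L)
  a_start <- ifelse(plus, pmax(mols$xl_pos + 1L - shift, 0L),
                    pmax(mols$xl_pos - drawn, 0L))
  a_end <- ifelse(plus, pmin(mols$xl_pos + 1L + drawn, chrom_len[mols$chrom]),
                  pmin(mols$xl_pos + shift, chrom_len[mols$chrom]))
  keep <- a_start < a_end & a_start >= 0L & a_end <= chrom_len[mols$chrom]
  mols <- mols[keep, , drop = FALSE]
  a_start <- as.integer(a_start[keep]); a_end <- as.integer(a_end[keep])
  plus <- plus[keep]
  n <- nrow(mols)
  umi_len <- length(cfg$scheme$n_pos)
  umi <- if (cfg$umi_collision_free) sprintf("M%07d", seq_len(n))
         else random_dna(n, umi_len)
  n_copies <- 1L + rgeom(n, cfg$pcr_dup)
  mols$molecule_id <- sprintf("%s.m%06d", library, seq_len(n))
  mols$n_copies <- n_copies
  mols$umi <- umi
  # insert sequence in read orientation
  ins <- substr(genome[mols$chrom], a_start + 1L, a_end)
  ins[!plus] <- revcomp(ins[!plus])
  # layout prefix: barcode at B positions, UMI bases at N positions
  barcode <- if (type == "replicate") {
    names(cfg$scheme$barcode_map)[match(library, cfg$scheme$barcode_map)]
  } else {
    names(cfg$scheme$barcode_map)[1L]
  }
  if (is.na(barcode)) barcode <- names(cfg$scheme$barcode_map)[1L]
  prefix <- character(n)
  if (n) {
    pm <- matrix("", nrow = n, ncol = layout_len)
    pm[, cfg$scheme$b_pos] <- matrix(strsplit(barcode, "")[[1]], nrow = n,
                                     ncol = length(cfg$scheme$b_pos),
                                     byrow = TRUE)
    fastq_umi <- if (cfg$umi_collision_free) random_dna(n, umi_len) else umi
    um <- do.call(rbind, strsplit(fastq_umi, ""))
    pm[, cfg$scheme$n_pos] <- um
    prefix <- do.call(paste0, asplit(pm, 2L))
  }
  full <- substr(paste0(prefix, ins, strrep(cfg$adapter, 2L)), 1L,
                 cfg$read_len)
  copy_of <- rep(seq_len(n), n_copies)
  copy_no <- sequence(n_copies)
  read_id <- sprintf("%s.c%d", mols$molecule_id[copy_of], copy_no)
  fastq <- data.frame(read_id = read_id, seq = full[copy_of],
                      qual = strrep("I", nchar(full[copy_of])))
  aligned <- aligned_reads(
    read_id = paste0(read_id, ":", mols$umi[copy_of]),
    chrom = mols$chrom[copy_of], start = a_start[copy_of],
    end = a_end[copy_of], strand = mols$strand[copy_of],
    umi = mols$umi[copy_of], replicate = rep(library, length(copy_of)))
  list(fastq = fastq, aligned = aligned,
       molecules = mols[, c("molecule_id", "site_id", "chrom", "xl_pos",
                            "strand", "umi", "n_copies")])
}

#' Simulate the complete experiment in memory
#'
#' @param cfg A [sim_config()].
#' @return List with `genome`, `chrom_lengths`, `models`, `truth`, and
#'   `libraries` (named list of [simulate_library()] outputs; replicates
#'   `rep1..n`, controls `ctrl1..m`).
#' @export
simulate_experiment <- function(cfg) {
  sim <- make_genome_and_models(cfg)
  pl <- plant_sites(cfg, sim)
  genome <- pl$genome
  libs <- list()
  for (r in seq_len(cfg$n_replicates)) {
    lab <- paste0("rep", r)
    libs[[lab]] <- simulate_library(cfg, pl$truth, genome, lab,
                                    type = "replicate", rep_index = r,
                                    lib_index = r)
  }
  for (c0 in seq_len(cfg$n_control_libs)) {
    lab <- paste0("ctrl", c0)
    libs[[lab]] <- simulate_library(cfg, pl$truth, genome, lab,
                                    type = "control",
                                    lib_index = cfg$n_replicates + c0)
  }
  list(genome = genome, chrom_lengths = sim$chrom_lengths,
       models = sim$models, truth = pl$truth, libraries = libs, config = cfg)
}

# BED12 line for one gene model
model_to_bed12 <- function(m) {
  lo <- min(m$exons$start); hi <- max(m$exons$end)
  thick <- if (nrow(m$cds)) c(min(m$cds$start), max(m$cds$end)) else c(lo, lo)
  sizes <- m$exons$end - m$exons$start
  offs <- m$exons$start - lo
  paste(m$chrom, lo, hi, m$transcript_id, 0, m$strand, thick[1], thick[2],
        "0,0,0", nrow(m$exons), paste(sizes, collapse = ","),
        paste(offs, collapse = ","), sep = "\t")
}

#' Write gene models as BED12
#'
#' @param models List of gene models.
#' @param file Output path or `NULL`.
#' @return Lines, invisibly.
#' @export
write_models_bed12 <- function(models, file = NULL) {
  lines <- vapply(models, model_to_bed12, character(1))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a self-contained end-to-end fixture directory
#'
#' Emits `genome.fa`, `models.bed12`, `<lib>.fastq` and `<lib>.aligned.tsv`
#' per library, and `truth.json`; the directory drives every pipeline stage
#' without external data. Equal seeds give byte-identical directories.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The [simulate_experiment()] result, invisibly, with `dir`
#'   attached.
#' @export
sim_fixture <- function(cfg, dir) {
  exp <- simulate_experiment(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(exp$genome, file.path(dir, "genome.fa"))
  write_models_bed12(exp$models, file.path(dir, "models.bed12"))
  for (lab in names(exp$libraries)) {
    lib <- exp$libraries[[lab]]
    write_fastq(lib$fastq, file.path(dir, paste0(lab, ".fastq")))
    write_alignments(lib$aligned, file.path(dir, paste0(lab, ".aligned.tsv")))
  }
  truth <- list(
    sites = exp$truth,
    motif = exp$config$motif,
    motif2 = exp$config$motif2,
    motif2_offset = exp$config$motif2_offset,
    molecules = lapply(exp$libraries, `[[`, "molecules"),
    chrom_lengths = as.list(exp$chrom_lengths),
    seed = exp$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  exp$dir <- dir
  invisible(exp)
}
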