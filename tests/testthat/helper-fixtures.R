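# Shared, lazily built simulation fixtures. Heavy objects are computed once
# per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the headline study-conditions experiment and its pipeline result
small_experiment <- function() {
  cached("small_exp", function() simulate_experiment(sim_config(seed = 101)))
}

small_result <- function() {
  cached("small_res", function() run_pipeline(small_experiment()))
}

# a fast variant for unit-level checks
tiny_experiment <- function() {
  cached("tiny_exp", function() {
    simulate_experiment(sim_config(seed = 7, preset = "tiny"))
  })
}

# deterministic random crosslink track for property tests
random_track <- function(n, seed, chroms = c("chr1", "chr2"),
                         max_pos = 5000L, max_count = 9L) {
  set.seed(seed)
  pts <- unique(data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE)))
  pts$count <- sample.int(max_count, nrow(pts), replace = TRUE)
  pts <- pts[order(pts$chrom, pts$strand, pts$pos), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

random_sites <- function(n, seed, chroms = c("chr1", "chr2"),
                         max_pos = 5000L, ext = 4L) {
  set.seed(seed)
  pos <- sample(seq(ext, max_pos - ext - 1L), n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = pos - ext, end = pos + ext + 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             peak_pos = pos)
}

# independent brute-force window sum (per-position re-summation)
brute_window_sum <- function(site, track) {
  sum(track$count[track$chrom == site$chrom &
                    track$strand == site$strand &
                    track$pos >= site$start & track$pos < site$end])
}

brute_window_positions <- function(site, track) {
  sum(track$chrom == site$chrom & track$strand == site$strand &
        track$pos >= site$start & track$pos < site$end & track$count >= 1)
}
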