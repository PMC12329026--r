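# clipsites

Binding-site determination from iCLIP crosslink data, as a tested and
reusable R pipeline.

iCLIP (individual-nucleotide resolution crosslinking and
immunoprecipitation) locates the contacts of an RNA-binding protein on its
target transcriptome with single-nucleotide precision: reverse
transcription stalls at the UV-crosslinked residue, so each read starts one
nucleotide 3' of a protein–RNA contact. `clipsites` is for analysts who
have (or simulate) such libraries and want the read-level bookkeeping and
the site-level statistics handled by one auditable, deterministic package:

* read preprocessing — 3' adapter trimming, demultiplexing of the
  `NN-XXXX-NNN` barcode/UMI prefix, 24-nt minimum-length filter;
* PCR-duplicate removal by (position, UMI) grouping, and strand-aware
  single-nucleotide **crosslink tracks** (crosslink = read start − 1);
* peak handling — ingest an external narrow-peak caller's output or use
  the built-in naive local-enrichment stand-in; adjacent peaks resolve to
  the best-scoring position;
* **binding sites** = peaks ± 4 nt (9-nt windows), with single-crosslink
  windows excluded as mapping artifacts;
* **reproducibility** — per-replicate support counts, a 30% quantile
  threshold over positive support per replicate, and a 2-of-3 rule;
* subtraction of sites found in control libraries (GFP-only /
  RNA-binding-dead);
* transcript-region assignment (5'UTR / CDS / intron / 3'UTR / non-coding)
  against representative gene models, with a cumulative-length background;
* k-mer motif enrichment in ±30-nt windows against
  dinucleotide-preserving shuffles, with positional density profiles;
* a fully seeded **synthetic iCLIP experiment generator** with a
  machine-readable truth record, so every stage is testable offline.

The core classification rule: site *i* with support count `c[i, r]` in
replicate *r* is reproducible iff

    #{ r : c[i, r] >= t_r } >= k,        t_r = Q30( positive support of r ),

where `Q30` is the empirical 30% quantile by CDF inversion and `k = 2` of
`n = 3` replicates.

## Worked example

Simulate the default study conditions (100-kb genome, 40 genes, 60 planted
sites, 3 replicates + 2 background-only controls) and run the full
pipeline:

```r
library(clipsites)

cfg <- sim_config(seed = 101)
exp <- simulate_experiment(cfg)
res <- run_pipeline(exp)

res$accounting
#>   library aligned after_dedup crosslink_events
#> 1    rep1   18058        9171             9171
#> 2    rep2   18369        9170             9170
#> 3    rep3   18122        9250             9250
#> 4   ctrl1   16284        8185             8185
#> 5   ctrl2   16024        8095             8095

res$classification$thresholds   # per-replicate minimal crosslink support
#> rep1 rep2 rep3
#>    3    3    2

res$classification$histogram    # sites by number of supporting replicates
#>  0  1  2  3
#>  6 27  6 58
```

Reading this: ~18k aligned reads per replicate collapse to ~9.2k unique
molecules after UMI deduplication, each contributing one crosslink event.
Of 97 candidate 9-nt windows, 64 are supported in at least two replicates
at the quantile thresholds (the rest are mostly weak background pileups),
and all 64 survive control subtraction. Region assignment and motif
scoring on the final sites:

```r
res$region_distribution
#>            region site_count site_percent background_percent
#> 1  five_prime_utr         29        47.54              11.37
#> 2             cds         10        16.39              49.90
#> 3          intron          6         9.84              23.79
#> 4 three_prime_utr         11        18.03              11.28
#> 5       noncoding          5         8.20               3.66

head(res$motifs[["5"]], 3)
#>    kmer fg_count bg_mean bg_sd zscore
#> 1 TTCTT       65   10.72  2.67  20.31
#> 2 ATTCT       23    6.76  2.25   7.23
#> 3 TCTTG       22    6.54  2.44   6.33
```

Sites concentrate in UTRs far above the length-based expectation (65.6% of
sites vs 22.6% of feature length), and the planted motif `TTCTT` ranks
first by shuffle z-score. Against the generator's truth record:

```r
evaluate_recovery(res, exp$truth)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 0.9375
```

`run_pipeline(input, out_dir = "out/")` additionally writes BEDGRAPH
tracks, BED6 peak/site files, the support matrix, the replicate-overlap
histogram, region and motif tables, and a JSON manifest that fully echoes
the effective configuration; reruns are byte-identical. A self-contained
fixture directory (FASTQ, aligned TSV, FASTA, BED12, truth JSON) comes
from `sim_fixture(cfg, dir)`, and `run_pipeline(dir)` consumes it.

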