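---
title: "Methods: binding-site determination from iCLIP crosslink data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site determination from iCLIP crosslink data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

iCLIP (individual-nucleotide resolution crosslinking and immunoprecipitation)
maps where an RNA-binding protein touches its target RNAs. UV light
covalently stabilises native protein–RNA contacts; after immunoprecipitation
and proteinase digestion, a residual polypeptide remains at the contact site
and stalls reverse transcription, so the cDNA — and hence the sequencing
read — begins one nucleotide 3' of the crosslinked residue. The genomic
position immediately 5' of a mapped read's start, in read orientation, is
therefore the inferred contact: `start − 1` on the plus strand and the
half-open alignment `end` on the minus strand. Everything downstream of the
read sequence itself hangs on that one coordinate, which is why the package's
central object is the *crosslink track*: strand-aware per-position counts of
deduplicated read starts, not read coverage.

The read-level structure this package models:

* a 3' sequencing adapter that appears at the read end whenever the cDNA
  insert is shorter than the read;
* a composite 9-nt 5' prefix, `NNXXXXNNN`: a 4-nt experimental barcode
  (`XXXX`) identifying the replicate library, flanked by 2 + 3 random
  nucleotides that together form a 5-nt unique molecular identifier (UMI);
* PCR duplicates, recognisable as reads with the same mapping position *and*
  the same UMI — reads sharing a position but differing in UMI are distinct
  molecules and both kept.

## From crosslinks to binding sites

1. **Peaks.** Single-nucleotide peaks come either from an external
   narrow-peak caller (ingested as single-nucleotide BED6) or from the
   built-in naive caller, a deliberately simple stand-in: position *p* is a
   peak iff its merged-track count is at least `min_count` and at least
   `min_fold × (local mean over ±flank, excluding p, + 1)`. The pseudocount
   keeps isolated single events from scoring as infinitely enriched.
2. **Adjacent-peak resolution.** Maximal runs of directly adjacent peak
   positions (distance exactly 1, same chromosome and strand) collapse to
   their highest-scoring member; score ties keep the smallest coordinate, a
   deterministic 5'-most-on-plus convention.
3. **Binding sites.** Each resolved peak is extended by `ext = 4` nt on both
   sides into a fixed 9-nt window. Windows that would be clipped at a
   chromosome boundary are dropped rather than narrowed, so every site has
   identical width and a centred peak.
4. **Single-crosslink exclusion.** A window in which only one distinct
   position carries crosslinks — however many events pile on it — is treated
   as a mapping artifact and removed. Genuine binding footprints spread
   crosslinks over neighbouring residues; a solitary spike usually does not
   come from binding.
5. **Reproducibility.** For each site and replicate, support is the summed
   crosslink count of that replicate's track inside the window. Each
   replicate gets its own threshold: the 30% quantile of its *strictly
   positive* support counts, by empirical CDF inversion without
   interpolation (the smallest observed count whose cumulative fraction
   reaches 0.30). A site is *reproducible* when its support reaches the
   threshold (`>=`; attainment counts, because the thresholds are minimal
   required crosslink numbers) in at least `k = 2` of the replicates.
6. **Control subtraction.** Control libraries (e.g. GFP-only and
   RNA-binding-dead constructs) pass through the identical pipeline; any
   site overlapping a control site by one or more same-strand nucleotides is
   removed.
7. **Region assignment.** Each surviving site is anchored at its peak
   position and located within same-strand representative gene models.
   Among features covering the anchor the label priority is
   3'UTR > 5'UTR > CDS > intron > noncoding; uncovered anchors are
   intergenic. Anchoring at the centre (instead of any-overlap) guarantees
   exactly one label per site; UTRs outrank CDS because boundary-straddling
   centres are rare and the biology of interest here is UTR-dominant
   binding. The region distribution is reported against the cumulative
   genomic length of each feature class.
8. **Motifs.** Sites are extended by 30 nt per side and their strand-specific
   sequences extracted (69-nt windows). Instead of re-implementing an
   external motif tool's objective, enrichment is scored exhaustively over
   k-mers: the background is per-window dinucleotide-preserving Eulerian
   shuffles, and each k-mer gets `z = (fg − bg_mean) / max(bg_sd, 1)`; the
   sd floor keeps degenerate (single-letter) windows finite. Positional
   density profiles locate k-mer starts relative to window centres. Each
   window's shuffle stream is seeded from the window's own content, making
   results invariant to input order and reproducible for a fixed seed.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_len` | 24 nt | minimum insert length kept after preprocessing; shorter reads rarely map uniquely |
| `ext` | 4 nt | site half-width; sites are 9 nt |
| `min_xl_positions` | 2 | distinct crosslinked positions a window must contain |
| `q` | 0.30 | per-replicate support quantile over positive counts |
| `k_of_n` | 2 | replicates that must support a site |
| `support_cmp` | `>=` | whether attaining the threshold counts as support |
| `motif_ext` | 30 nt | motif window half-extension (69-nt windows) |
| `dedup_anchor` | `five_prime` | duplicate grouping anchor; truncation biology anchors the 5' end, so the strand-aware 5' coordinate is the default over the plain left coordinate |
| `peak_min_count`, `peak_flank`, `peak_min_fold` | 2, 15, 2 | naive caller; stand-in values, see below |

Open choices resolved here, and why: the support quantile is computed over
strictly positive counts only, because zero-inflated columns would otherwise
collapse every threshold to zero and the rule would stop filtering anything;
controls are reduced to their own binding-site sets (same pipeline, `k = 1`
for a single library) before subtraction, for symmetry with the treatment
samples; peaks are called on the merged replicate track with per-replicate
assessment afterwards, matching the workflow order in which filtering
precedes reproducibility.

## The synthetic experiment

`sim_config()` / `simulate_experiment()` generate a complete miniature iCLIP
study: a uniform-random genome, non-overlapping gene models on both strands
(~10% non-coding), planted binding sites, three replicate libraries, two
background-only control libraries, and a truth record tying every read to
its molecule and every molecule to its site.

What the generator emulates, and the conditions it fixes:

* **Site placement.** 60 sites on a 100-kb chromosome (the `small` preset),
  drawn inside gene features with a 70% UTR bias — the UTR-dominant binding
  landscape typical of the glycine-rich RNA-binding proteins this kind of
  experiment profiles — and at least 20 nt apart.
* **Site strength.** Expected molecules per site per replicate are
  log-normal (meanlog 2.8, sdlog 0.6; median ≈ 16), drawn independently per
  replicate, with realised counts Poisson around the expectation. Crosslink
  support across binding sites in real libraries is approximately
  log-normal, which is exactly what makes a quantile threshold a sensible
  support filter.
* **Crosslink dispersion.** Molecules crosslink at the site peak plus a
  small offset in −2..2 (probabilities 0.05/0.2/0.5/0.2/0.05). A point-mass crosslink model would put all events on one position
  and the single-crosslink exclusion rule would then delete every true
  site; real footprints spread over a few residues, which is the premise of
  the 9-nt window in the first place.
* **Background.** 80 background molecules per kb per replicate, placed
  uniformly over both strands. This rate was derived, not tuned: it makes
  single-position background pileups of three or more deduplicated
  molecules (the naive caller's admission bar) yield roughly 30 weak decoy
  candidate windows — about a third of the candidate set, matching the
  fraction of candidate sites that fails the 2-of-3 rule in real data of
  this kind. Those decoys are what the 30% quantile threshold is *for*:
  they populate the lower tail of the support distribution, the thresholds
  settle among them (typically 2–6), and essentially all planted sites pass
  while decoys are rejected. With a background too sparse to produce decoys
  the quantile would instead cut the bottom ~30% of true sites — a property
  of the published rule itself, not of this implementation.
* **Reads.** Each molecule gets a 5-nt UMI, a truncation read starting one
  nucleotide 3' of its crosslink, an insert length ~N(28, 9) clamped to
  8–41 nt (so most reads run into the adapter, as after RNase
  fragmentation), geometric PCR duplication (p = 0.5, mean two copies), a
  constant Q40 quality string, and a FASTQ record `prefix + insert +
  adapter fill` of 50 nt. An aligned TSV gives every read's true placement,
  bypassing alignment entirely. With `truncation_prob < 1`, read-through
  molecules start 3 nt further 5', corrupting their inferred crosslink —
  the biological noise mode of incomplete truncation.
* **Controls.** Control libraries draw background only, at the same rate.

What it deliberately does **not** emulate: sequencing errors, splice-aware
reads (reads are genomic, so alignment-free testing stays exact), fragment
3'-end chemistry, barcode mutations, non-uniform (expression-weighted)
background, or chromatin-scale covariates that real HMM peak callers model.
Passing the recovery tests therefore demonstrates the pipeline's rules and
bookkeeping are correct under the stated statistical structure, not that any
particular biological dataset would yield a particular site list.

### The naive caller's fold threshold

The caller's parameters are stand-ins for an external HMM caller and are not
taken from any published analysis. The fold default is 2: at fold 3 a
single-position background pileup must reach four deduplicated molecules to
be called (the local-mean pseudocount raises the bar in step with any
background rate), which empties the weak-candidate subpopulation and, with
it, makes the quantile threshold cut true sites — the regime described
above. Fold 2 admits three-molecule pileups, the sensitivity class of the
HMM callers used on real data, whose candidate lists demonstrably contain a
weak third.

### Numerical conventions and degenerate inputs

All internal coordinates are 0-based half-open; GFF3 is converted at the
boundary. Score ties in peak resolution break toward the smaller
coordinate. Quantile thresholds are exact order statistics, never
interpolated; a replicate with no positive support supports nothing
(threshold +Inf). Duplicate groups keep their first read in input order.
BEDGRAPH output refuses unsorted tracks instead of silently re-sorting.
Annotations with several transcripts per gene keep the longest transcript
with a warning. Empty inputs (no reads, empty track, zero assigned sites)
either produce structurally empty results or a named error, as documented
per function. All randomness flows from a single seed through fixed
per-stage substreams, and reruns with equal seed and config are
byte-identical.

## Problem sizes

The shipped study conditions (`preset = "small"`: 1 × 100 kb chromosome, 40
genes, 60 sites, 3 replicates + 2 controls, ~50k reads) run the full
simulation plus pipeline in well under a minute on one CPU; the `tiny`
preset (30 kb, 14 genes, 18 sites) backs the fast unit tests. These sizes
were chosen so that every property of interest — duplicate collapse,
threshold placement, recovery, motif ranking — is measurable with stable
statistics while the whole test suite stays quick to run.

## Known limitations

* The naive caller is a stand-in; for real data, ingest an external
  narrow-peak caller's output (`ingest_peaks()`).
* Adapter trimming models substitutions only (no indels), and is idempotent
  only up to coincidental terminal matches shorter than the overlap
  threshold (~2% of random termini at the default `min_overlap = 3`).
* 5-nt UMIs can collide at saturated positions, so duplicate removal can
  undercount molecules; the generator's `umi_collision_free` mode exists to
  test exact conservation separately.
* Region assignment uses one representative transcript per gene; sites on
  minor isoform-specific features inherit the representative's label.
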