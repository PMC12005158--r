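---
title: "Measuring point mutations and repeat-mediated recombination in plant organellar genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring point mutations and repeat-mediated recombination in plant organellar genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgvar)
library(data.table)
```

## The measurement problem

Plant mitochondrial and plastid genomes combine two unusual properties: point
mutation rates so low that de novo variants are invisible to ordinary
sequencing (frequencies of 10^-8^ to 10^-7^ per base), and frequent
non-allelic recombination between dispersed repeats of intermediate size
(tens to hundreds of bp). Measuring either signal requires error rates far
below those of the raw instruments, and both measurements are easily biased
by bookkeeping choices: what counts as coverage, which strand a change is
reported on, and which reads count as informative for a repeat.

`orgvar` implements both measurements as a tested pipeline:

* **Duplex consensus calling** — reads are grouped into tagged families, each
  family representing both strands of one source molecule. A variant is
  accepted only when the consensus of each strand-family independently shows
  it, which suppresses sequencing error and single-strand DNA damage. The
  headline quantity is a frequency: pass-filter variant count divided by the
  total number of callable duplex consensus bases.
* **Mutation spectrum analyses** — six pyrimidine-keyed substitution classes,
  per-region frequencies (intergenic, CDS, intron, rRNA, tRNA),
  transcriptional strand asymmetry (template vs non-template strand of genic
  sites), and trinucleotide-context profiles. Every frequency is normalized
  by the duplex coverage of the exact site stratum it counts, so
  composition differences between regions, strands or contexts cannot
  inflate it.
* **Structural variants from long reads** — reads are classified by their
  split-alignment geometry (single hit; two hits inverted; two hits direct
  with a deletion-type or circular/tandem-type junction; three or more hits
  excluded), junctions are matched to a catalog of repeat pairs, and
  per-repeat recombination frequency is recombined reads over
  repeat-spanning reads. Genome-wide frequencies pool repeats with at least
  10 (mtDNA) or 3 (cpDNA) recombining reads summed across replicates.
  Candidate indels need at least 2 reads supporting the identical position
  and length. Copy-number perturbations are displayed as mutant:WT depth
  ratios in 1-kb windows, rescaled to mean 1.

A synthetic-data module generates circular genomes with annotated features
and planted repeat pairs, duplex families with planted mutations, and long
reads with planted recombination events — all with exhaustive truth records,
so that every stage of the pipeline can be validated by parameter recovery
rather than by fixture matching.

## Conventions that the data pin down

Several conventions are validated against printed values from the field's
repeat catalogs rather than chosen freely:

* Coordinates are 1-based inclusive; a repeat printed as 19,682–20,237 has
  length 20,237 − 19,682 + 1 = 556. The shipped catalog
  (`inst/extdata/athaliana_mt_repeats.tsv`) round-trips through
  `read_repeat_table()`/`write_repeat_table()` and its recomputed lengths
  equal the printed column.
* Inverted repeat pairs are printed with descending second-copy coordinates;
  internally both copies are ascending intervals plus an orientation flag.
* A called deletion is reported as (first deleted base, number of reference
  bases skipped). This makes the junction route (split alignment) and the
  CIGAR route produce identical call keys, and reproduces the printed 106 bp
  for a deletion whose flanking coordinates are 148,490 and 148,596.
* "Template strand" is the strand RNA polymerase reads: the non-template
  (sense) strand of a gene is the strand the gene is annotated on. A
  pyrimidine change whose pyrimidine sits on the gene's strand is reported
  as occurring on the non-template strand; all four (pyrimidine strand ×
  gene strand) cases are unit-tested.
* Purine-reference substitutions collapse onto the complementary pyrimidine
  class (G→A ≡ C→T) with the strand flag flipped.

## Parameters and defaults

Parameters the upstream protocols fix are defaults here; parameters the
protocols leave open are package choices, tagged `artifact-default` in every
run manifest so users can tell the two apart:

| parameter | default | rationale |
|---|---|---|
| `min_reads_per_strand` | 3 | a strand consensus from fewer reads is not meaningfully error-corrected |
| `strand_consensus_threshold` | 0.9 | a base is called only on near-unanimity; ties and minorities give N, never a guess |
| `end_trim` | 10 bp | fragment termini are enriched for artifacts in duplex libraries; trimmed positions are excluded from both numerator and denominator |
| `numt_k_flank`, `numt_max_mismatch` | 20 bp, 0 | the variant haplotype (alternate allele plus 20 bp of consensus flank) must match the nuclear genome exactly, on either strand, to be discarded — the strictest faithful reading of "compare putative mutations directly against the nuclear genome" |
| `min_hit_len` | 100 bp | shorter local hits on noisy long reads are unreliable anchors |
| `max_unexplained` | 50 bp + 5% of read length | a single hit must explain the read up to clipping noise to count as clean |
| `breakpoint_tolerance` | 100 bp | junction placement inside a near-identical repeat is ambiguous up to the homology |
| spanning `flank` | 100 bp | a read is informative about a repeat only if it anchors uniquely on both sides |
| `min_recomb_mt` / `min_recomb_cp` | 10 / 3 | read-support thresholds for genome-wide pooling |
| indel `min_support` | 2 | independent-read support for indels on a high-error platform |
| `window` | 1,000 bp | coverage-ratio window size |

## The synthetic generators as study conditions

`simulate_genome()` builds a random circular sequence, places
non-overlapping genes of the four classes, and plants repeat pairs whose
second copy differs from the first at exactly
`round((1 − identity/100) × length)` positions (reverse-complemented for
inverted pairs). Copies can be pinned to chosen coordinates; the packaged
recombination benchmark (`example_recomb_dataset()`) pins the ten copies of
its five pairs — sized and weighted like the most recombinationally active
mitochondrial repeats (127–556 bp, 99.2–100% identity) — farther apart than
the longest read, so each read receives an independent recombination trial
per spanned repeat and the per-repeat estimator is unbiased.

`simulate_duplex_families()` represents reads sparsely: an aligned interval
plus deviations from the reference. Planted mutations appear on every read
of both strand-families; sequencing errors are i.i.d. per read base.
Mutations are planted by Poisson thinning over per-position weights (class
rate × context multiplier × template-strand bias), which is exact in the
sparse-mutation regime the generator enforces and lets runs with 10^8^
duplex bases finish in seconds. What this generator does *not* model — PCR
duplication families, quality-score variation, tag collisions, mapping
ambiguity of real short reads — bounds what passing tests show: they
validate the calling, filtering and normalization logic, not robustness to
upstream artifacts.

`simulate_long_reads()` draws lognormal read lengths (default meanlog
log(4000), sdlog 0.35, truncated at 1 kb) on the circular genome. A read
whose source molecule spans a repeat copy plus 100 bp of flank recombines
there with the repeat's configured frequency; the crossover point is uniform
within the repeat (no positional model is imposed), inverted repeats switch
strand at the junction, and direct repeats emit deletion-type or
circular-type products in a configurable mix (default 0.5, a free parameter
because the product ratio is not established). The nanopore error model is
i.i.d. substitution/indel noise without homopolymer bias — adequate because
downstream classification depends on alignment geometry, not base accuracy.

## Alignment of synthetic long reads

Long reads are aligned with minimap2 (`-x map-ont -c --secondary=no
--mask-level 0.95`) against a doubled copy of the circular genome, with hit
coordinates folded back. Two settings matter and are worth explaining:

* **`--mask-level 0.95`** — a recombinant junction arm aligns through the
  near-identical other repeat copy, so its hit overlaps the primary
  alignment on the read by up to the repeat length. At the default mask
  level such arms are demoted to secondary alignments and lost; raising it
  keeps them while still suppressing true duplicates.
* **Splitting at large deletions** — a chained aligner can absorb a long
  deletion into one alignment as a `D` CIGAR operation, which would hide
  deletion-type recombination from split-hit classification.
  `split_hits_at_deletions()` (default threshold 100 bp) restores the
  local-hit view that a local aligner such as BLASTn reports natively.
  Deletions of 10–99 bp remain CIGAR candidates; both routes share one
  coordinate convention, verified by test.

## Numerical choices and degenerate inputs

* Consensus positions that fail the threshold, disagree between strands, or
  conflict at an indel become N — never a guessed base — and are subtracted
  from the coverage denominator, as are deleted bases and trimmed ends.
* Two adjacent changed bases on one molecule are a single dinucleotide call
  (excluded from the SNV numerator; runs of three or more are reported as
  `multinucleotide` and excluded from both). Indels are left-aligned so
  identical molecules give identical call keys.
* Fold enrichments pool numerators and denominators before dividing; a mean
  of per-cell ratios would blow up on empty cells.
* Zero-coverage strata are flagged `NA`, never 0; zero-depth WT windows are
  excluded from the mean-1 rescaling of coverage ratios.
* Breakpoint matches that tie between two repeats at equal distance are
  ambiguous and match nothing. Exactly contiguous split hits (junction
  difference 1) classify as deletion-type with length 0; real events always
  exceed this.
* Paired strand-asymmetry tests with fewer than two usable replicate pairs,
  or identical pairs, are skipped with a reason rather than run. No
  multiple-testing correction is applied by default (raw p-values are
  reported); a Benjamini–Hochberg step can be applied to the returned
  p-values.
* Log-scale displays of frequencies leave zero cells out rather than adding
  pseudocounts; no statistic is computed on pseudocounted values.

## Validation design and problem sizes

The test suite validates by truth recovery at sizes chosen to make the
statistical checks sharp:

* Recombination: 8,000 reads over the pinned five-repeat benchmark give
  500–700 spanning reads per repeat; every planted frequency in
  {0, 0.1, 0.3, 0.7, 1} must fall inside its 99% binomial CI, in error-free
  and 5%-error modes.
* Point mutations: 340,000 molecules × 300 bp ≈ 10^8^ duplex bases with all
  six classes planted at a summed 10^-6^ per site; the recovered frequency
  must sit within 3 Poisson SE, with zero calls that are not planted events
  (the duplex guarantee, checked at scale and by construction in unit
  tests).
* Spectrum biases: an 8.4× multiplier on 5′-pyrimidine contexts and a
  template-strand bias of 5 are each recovered inside 95% Poisson-ratio CIs
  from single-effect simulations (joint simulations would couple the two
  estimators through sequence composition).
* Null calibration: 100 cohorts of 8 replicates from a symmetric generator;
  the paired Wilcoxon and paired t tests must reject at the nominal 5% rate
  up to binomial error. The per-class rate in these cohorts (4 × 10^-4^ per
  site) is deliberately accelerated relative to organellar reality so each
  replicate holds enough events for the tests to be well-defined; the
  type-I property depends only on the generator's symmetry, not on the
  absolute rate.
* NUMT filtering: a synthetic nuclear genome carrying a paralog of an
  organellar segment with 6 planted paralogous variants; contaminant
  families must be filtered completely while no genuine call is lost.

`scripts/acceptance.R` reruns all of these from scratch and writes the
recovered numbers as JSON.

## A short worked example

```{r example, eval = FALSE}
sg <- simulate_genome(30000, c(CDS = 6, intron = 2, rRNA = 2, tRNA = 8),
                      seed = 1)
model <- mutation_model(base_rate_per_class = c("C>T" = 2e-5, "T>C" = 1e-5))
cfg <- load_config(list(seed = 1, duplex = list(n_molecules = 50000L)))
res <- run_duplex(cfg, sg$genome, sg$features, model = model, replicates = 3)
res$frequencies
writeLines(make_report(duplex_result = res))
```

## Known limitations

* The exact-match FASTQ placer suits error-free synthetic reads only; real
  duplex data should arrive as externally aligned records converted to the
  reads/devs tables.
* Reads with three or more local hits are excluded, not reconstructed, so
  genome-wide recombination frequencies are conservative in highly
  rearranged genomes.
* The NUMT filter's exact-match default is strict; divergent, older nuclear
  insertions require raising `max_mismatch`, at some cost in genuine calls.
* Published per-repeat frequency tables are not always the ratio of their
  own printed pooled counts (averaging across replicates is one
  explanation); this package reports both the pooled ratio and the mean of
  per-replicate frequencies and does not attempt to reproduce any printed
  frequency column.
* Real-data headline frequencies require the corresponding raw libraries;
  nothing in the package asserts them.
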