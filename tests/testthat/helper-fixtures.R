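## shared fixtures built in code at test time

library(data.table)

repeat_catalog_path <- function() {
  system.file("extdata", "athaliana_mt_repeats.tsv", package = "orgvar")
}

tiny_genome <- function(seq = "AACGTTGCAT", circular = TRUE) {
  organelle_genome("tiny", seq, circular = circular)
}

## deterministic annotated genome for duplex tests
small_dataset <- function(seed = 42, length = 20000,
                          n_genes = c(CDS = 3, intron = 1, rRNA = 1, tRNA = 3)) {
  simulate_genome(length, n_genes, seed = seed)
}

## one hit-table row builder for classifier tests
mk_hit <- function(read_id, read_len, qstart, qend, tstart, tend, strand) {
  local_hits(read_id, read_len, qstart, qend, tstart, tend, strand)
}

## exhaustive two-hit classification cases with hand-assigned expected
## classes. Geometry encoding for same-orientation pairs: the junction
## coordinates are (end of hit1, start of hit2) read along the alignment
## orientation; deletion-type means the genome resumes further ahead in the
## direction of travel, circular/tandem-type means it resumes behind.
classifier_truth_table <- function() {
  rl <- 2000L
  cases <- list()
  add <- function(expected, h) cases[[length(cases) + 1L]] <<-
    list(expected = expected, hits = h)
  q1 <- c(1L, 900L); gaps <- c(wide = 400L, contig = 1L, overlap = -300L)
  ## read-side gap between the hits: contiguous or with unexplained middle
  for (qgap in c(0L, 120L)) {
    q2 <- c(901L + qgap, 1900L + qgap)
    ## same orientation, forward: genome resumes ahead -> deletion,
    ## at/behind -> circular
    for (gn in names(gaps)) {
      t2s <- 5900L + gaps[[gn]]
      expected <- if (gaps[[gn]] >= 1L) "two_hit_direct_deletion"
                  else "two_hit_direct_circular"
      add(expected, mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                           c(5000L, t2s), c(5899L, t2s + 999L), c("+", "+")))
      ## hit2 far behind hit1 in the genome: always circular/tandem
      add("two_hit_direct_circular",
          mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                 c(5000L, 2000L), c(5899L, 2999L), c("+", "+")))
      ## same orientation, both reverse: the mirrored molecule; genome
      ## "ahead" along the alignment means decreasing coordinates
      expected_rev <- if (gaps[[gn]] >= 1L) "two_hit_direct_deletion"
                      else "two_hit_direct_circular"
      t1s <- 5900L + gaps[[gn]]
      add(expected_rev, mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                               c(t1s, 5000L), c(t1s + 999L, 5899L), c("-", "-")))
      add("two_hit_direct_circular",
          mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                 c(2000L, 5000L), c(2999L, 5899L), c("-", "-")))
      ## opposite orientations: inverted, regardless of order and gap
      t2s <- 8000L + gaps[[gn]]
      add("two_hit_inverted",
          mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                 c(5000L, t2s), c(5899L, t2s + 999L), c("+", "-")))
      add("two_hit_inverted",
          mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                 c(5000L, t2s), c(5899L, t2s + 999L), c("-", "+")))
      add("two_hit_inverted",
          mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                 c(8000L, 2000L), c(8999L, 2999L), c("+", "-")))
      add("two_hit_inverted",
          mk_hit("r", rl + qgap, c(q1[1], q2[1]), c(q1[2], q2[2]),
                 c(8000L, 2000L), c(8999L, 2999L), c("-", "+")))
    }
  }
  ## single-hit cases: clean vs indel-bearing, both orientations
  add("single_hit_clean", mk_hit("r", 2000L, 1L, 1995L, 5000L, 6994L, "+"))
  add("single_hit_clean", mk_hit("r", 2000L, 1L, 1995L, 5000L, 6994L, "-"))
  add("single_hit_indel", mk_hit("r", 2000L, 1L, 1500L, 5000L, 6499L, "+"))
  add("single_hit_indel", mk_hit("r", 2000L, 400L, 2000L, 5000L, 6600L, "-"))
  ## >= 3 hits always excluded
  add("multi_hit_excluded",
      mk_hit("r", 3000L, c(1L, 1001L, 2001L), c(1000L, 2000L, 3000L),
             c(5000L, 8000L, 11000L), c(5999L, 8999L, 11999L),
             c("+", "+", "+")))
  add("multi_hit_excluded",
      mk_hit("r", 3000L, c(1L, 1001L, 2001L), c(1000L, 2000L, 3000L),
             c(5000L, 8000L, 11000L), c(5999L, 8999L, 11999L),
             c("+", "-", "+")))
  ## all hits shorter than min_hit_len -> unmapped
  add("unmapped", mk_hit("r", 2000L, 1L, 40L, 5000L, 5039L, "+"))
  cases
}

## per-replicate pooled genic strand-asymmetry frequencies under a model
## (used by the null-calibration checks)
asymmetry_pair <- function(sg, model, n_molecules, seed) {
  sim <- simulate_duplex_families(sg$genome, sg$features, model,
                                  n_molecules = n_molecules, seed = seed)
  fams <- group_families(sim$reads)
  cons <- build_consensuses(fams, sim$devs)
  calls <- call_variants(cons, sg$genome, sg$features)
  cov <- coverage_profile(cons, sg$genome$length)
  tab <- strand_asymmetry(calls, cov$depth, sg$features, sg$genome, "C>T",
                          test = "none")$table
  c(fn = sum(tab$count_nontemplate) / sum(tab$coverage_nontemplate),
    ft = sum(tab$count_template) / sum(tab$coverage_template))
}
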