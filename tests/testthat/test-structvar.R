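test_that("the classifier reproduces the exhaustive two-hit truth table", {
  cases <- classifier_truth_table()
  expect_gte(length(cases), 48L)
  got <- vapply(cases, function(cs) classify_reads(cs$hits)$class, character(1))
  want <- vapply(cases, `[[`, character(1), "expected")
  expect_equal(got, want)
})

test_that("breakpoints match the catalog by containment, geometry, and distance", {
  rp <- read_repeat_table(repeat_catalog_path())
  st <- data.table(read_id = c("r1", "r2"),
                   read_len = 20000L, n_hits = 2L,
                   class = "two_hit_direct_deletion",
                   j1 = c(19700L, 150000L), j2 = c(346300L, 160000L))
  m <- match_breakpoints(st, rp, tolerance = 50L)
  ## junctions inside repeat A's copies -> A; junctions far from any repeat
  expect_equal(m$repeat_name, c("A", NA))
  ## geometry must agree with repeat orientation: the same junctions with
  ## inverted geometry cannot match the direct pair A
  st_inv <- data.table::copy(st[1])[, class := "two_hit_inverted"]
  expect_true(is.na(match_breakpoints(st_inv, rp, tolerance = 50L)$repeat_name))
  ## an exact tie between two catalog entries is ambiguous
  rp2 <- repeat_pairs(c("P", "Q"), c(1000L, 1000L), c(1199L, 1199L),
                      c(5000L, 5000L), c(5199L, 5199L), c(99, 99))
  st2 <- data.table(read_id = "t", read_len = 10000L, n_hits = 2L,
                    class = "two_hit_direct_deletion", j1 = 1100L, j2 = 5100L)
  expect_true(is.na(match_breakpoints(st2, rp2, tolerance = 50L)$repeat_name))
})

test_that("spanning requires full copy coverage plus flanks", {
  rp <- repeat_pairs("R", 1000L, 1299L, 5000L, 5299L, 100)
  hits <- local_hits(c("covers", "ends_inside"), c(3000L, 3000L),
                     c(1L, 1L), c(2500L, 1500L),
                     c(800L, 700L), c(3300L, 1150L), c("+", "+"))
  st <- classify_reads(hits)
  st <- match_breakpoints(st, rp)
  ps <- count_spanning(hits, st, rp, flank = 100L)
  expect_equal(ps$spanning, 1L)
  expect_equal(ps$recombined, 0L)
  ## a matched recombinant enters numerator and denominator even without a
  ## covering hit
  st$repeat_name[2] <- "R"
  ps2 <- count_spanning(hits, st, rp, flank = 100L)
  expect_equal(ps2$spanning, 2L)
  expect_equal(ps2$recombined, 1L)
})

test_that("per-repeat and genome-wide frequencies apply the read-support thresholds", {
  expect_equal(repeat_frequency(0, 274)$frequency, 0)
  expect_equal(repeat_frequency(5, 20)$frequency, 0.25)
  expect_true(is.na(repeat_frequency(0, 0)$frequency))
  expect_error(repeat_frequency(5, 3), "<=")
  st <- data.table(replicate = rep(c("r1", "r2"), each = 2),
                   name = rep(c("big", "small"), 2),
                   recombined = c(7, 5, 5, 4), spanning = rep(100L, 4))
  gmt <- genome_frequency(st, "mt")
  expect_equal(gmt$included, "big")             # 12 >= 10, 9 < 10
  expect_equal(gmt$pooled, 12 / 200)
  gcp <- genome_frequency(st, "cp")
  expect_setequal(gcp$included, c("big", "small"))
  ## lowering the threshold can only grow the included set
  expect_true(all(gmt$included %in% gcp$included))
  g0 <- genome_frequency(data.table(name = "x", recombined = 0L,
                                    spanning = 50L), "mt")
  expect_equal(length(g0$included), 0L)
  expect_true(is.na(g0$pooled))
})

test_that("indel calls demand identical coordinates in independent reads", {
  cand <- data.table(read_id = "only", pos = 1000L, type = "deletion",
                     len = 106L)
  expect_equal(nrow(call_supported_indels(cand)), 0L)
  cand18 <- data.table(read_id = sprintf("r%02d", 1:18), pos = 1000L,
                       type = "deletion", len = 106L)
  out <- call_supported_indels(cand18)
  expect_equal(out$support, 18L)
  expect_equal(out$len, 106L)
  ## 1-bp disagreement in position blocks the call
  cand2 <- data.table(read_id = c("a", "b"), pos = c(1000L, 1001L),
                      type = "deletion", len = 106L)
  expect_equal(nrow(call_supported_indels(cand2)), 0L)
  ## duplicate observations in one read count once
  dup <- data.table(read_id = c("a", "a"), pos = 1000L, type = "deletion",
                    len = 106L)
  expect_equal(nrow(call_supported_indels(dup)), 0L)
})

test_that("CIGAR indels and split junctions share one coordinate convention", {
  ## 2000M then 106D then 1000M starting at reference 10001
  hits <- local_hits("r", 3000L, 1L, 3000L, 10001L, 13106L, "+",
                     cigar = "2000M106D1000M")
  st <- classify_reads(hits)
  cand <- candidate_indels(hits, st, min_indel_len = 10L)
  expect_equal(cand$pos, 12001L)   # first deleted base
  expect_equal(cand$len, 106L)
  ## the same deletion via a split junction gives the identical key
  sp <- split_hits_at_deletions(hits, min_del = 100L)
  expect_equal(nrow(sp), 2L)
  st2 <- classify_reads(sp)
  expect_equal(st2$class, "two_hit_direct_deletion")
  cand2 <- candidate_indels(sp, st2)
  expect_equal(cand2[, .(pos, type, len)], cand[, .(pos, type, len)])
  ## insertions are keyed by the base preceding them
  hi <- local_hits("r", 3000L, 1L, 3000L, 10001L, 12980L, "+",
                   cigar = "2000M20I980M")
  ci <- candidate_indels(hi, classify_reads(hi), min_indel_len = 10L)
  expect_equal(ci$type, "insertion")
  expect_equal(ci$len, 20L)
})

test_that("coverage-ratio windows normalize to mean one", {
  dm <- c(rep(20, 1000), rep(10, 1000))
  dw <- rep(10, 2000)
  cw <- coverage_ratio_windows(dm, dw, 1000)
  expect_equal(cw$ratio_normalized, c(4 / 3, 2 / 3))
  expect_identical(mean(cw$ratio_normalized), 1)
  ## identical depth: all ratios 1
  cw1 <- coverage_ratio_windows(dw, dw, 1000)
  expect_true(all(cw1$ratio_normalized == 1))
  ## genome shorter than one window collapses to a single window
  cw2 <- coverage_ratio_windows(rep(5, 300), rep(5, 300), 1000)
  expect_equal(nrow(cw2), 1L)
  ## zero-depth WT windows are flagged NA and excluded from the rescaling
  dw3 <- c(rep(0, 1000), rep(10, 1000))
  cw3 <- coverage_ratio_windows(dm, dw3, 1000)
  expect_true(is.na(cw3$ratio_normalized[1]))
  expect_equal(cw3$ratio_normalized[2], 1)
})

test_that("PAF and BLAST tabular hits import with coordinate folding", {
  paf <- tempfile(fileext = ".paf")
  writeLines(c(
    "read1\t5000\t0\t2000\t+\tref\t20000\t1000\t3000\t1990\t2000\t60\ttp:A:P\tcg:Z:2000M",
    "read1\t5000\t2000\t5000\t-\tref\t20000\t12000\t15000\t2980\t3000\t60\ttp:A:P",
    "read2\t4000\t0\t4000\t+\tref\t20000\t11000\t15000\t3990\t4000\t60\ttp:A:S"),
    paf)
  h <- read_paf(paf)
  expect_equal(nrow(h), 2L)                       # secondary dropped
  expect_equal(h$qstart, c(1L, 2001L))            # 1-based conversion
  expect_equal(h$tstart, c(1001L, 12001L))
  ## folding a doubled circular reference
  h2 <- read_paf(paf, fold_length = 10000L)
  expect_equal(h2$tstart, c(1001L, 2001L))
  bl <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("read1", "ref", 99.2, 2000, 10, 2, 1, 2000, 1000,
                       2999, 0, 3000, 5000), collapse = "\t"),
               paste(c("read1", "ref", 98.0, 3000, 20, 3, 2001, 5000, 15000,
                       12001, 0, 4000, 5000), collapse = "\t")), bl)
  hb <- read_blast_hits(bl)
  expect_equal(hb$strand, c("+", "-"))
  expect_equal(hb$tstart, c(1000L, 12001L))
})

test_that("end-to-end: planted recombinants are recovered at their true repeats", {
  ds <- example_recomb_dataset(seed = 7, n_reads = 1200, error_rate = 0)
  h <- align_long_reads_minimap2(ds$reads, ds$genome)
  st <- classify_reads(h, all_read_ids = ds$reads$read_id)
  st <- match_breakpoints(st, ds$repeats)
  tm <- merge(st, ds$truth, by = "read_id")
  rec <- tm[tm$recombinant == TRUE]
  expect_gt(nrow(rec), 50)
  ## virtually every error-free planted event is matched to its true repeat
  expect_gte(mean(!is.na(rec$repeat_name.x) &
                    rec$repeat_name.x == rec$repeat_name.y), 0.99)
  ## and no non-recombinant read is matched to any repeat
  expect_true(all(is.na(tm[tm$recombinant == FALSE]$repeat_name.x)))
})
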