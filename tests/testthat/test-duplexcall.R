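## hand-built family: n reads per strand at one locus, with chosen deviations
mk_family <- function(tag = "T1", n_a = 3, n_b = 3, start = 101, len = 200) {
  n <- n_a + n_b
  data.table(read_id = seq_len(n), molecule = 1L, tag = tag,
             strand_fam = rep(c("A", "B"), c(n_a, n_b)),
             start = start, len = len)
}
no_devs <- data.table(read_id = integer(), pos = integer(), type = character(),
                      alt = character(), len = integer())

test_that("families group by tag and split by locus", {
  r <- rbind(mk_family("T1"), mk_family("T2")[, read_id := read_id + 6L])
  fams <- group_families(r)
  expect_equal(length(unique(fams$family)), 2L)
  ## one tag at two loci 10 kb apart -> two families
  r2 <- mk_family("T1")
  r2$start[4:6] <- 10101L
  fams2 <- group_families(r2)
  expect_equal(length(unique(fams2$family)), 2L)
  ## untagged reads are rejected and counted
  r3 <- mk_family("T1")
  r3$tag[1] <- NA
  fams3 <- group_families(r3)
  expect_equal(attr(fams3, "n_untagged"), 1L)
  expect_equal(nrow(fams3), 5L)
})

test_that("duplex consensus requires agreement of both strand families", {
  fam <- group_families(mk_family())
  ## identical reads, no deviations: consensus equals the reference
  cons <- build_consensuses(fam, no_devs)
  expect_equal(cons$consensus$status, "pass")
  expect_equal(nrow(cons$cdevs), 0L)
  ## unanimous C on strand A, unanimous reference on strand B -> N
  d <- data.table(read_id = 1:3, pos = 150L, type = "M", alt = "C", len = 1L)
  consN <- build_consensuses(fam, d)
  expect_equal(consN$cdevs$alt, "N")
  ## both strands unanimous on the same alt -> called
  d2 <- data.table(read_id = 1:6, pos = 150L, type = "M", alt = "C", len = 1L)
  cons2 <- build_consensuses(fam, d2)
  expect_equal(cons2$cdevs$alt, "C")
  ## 2/3 reads on one strand is below the 0.9 threshold -> N
  d3 <- data.table(read_id = c(1:2, 4:6), pos = 150L, type = "M", alt = "C",
                   len = 1L)
  cons3 <- build_consensuses(fam, d3)
  expect_equal(cons3$cdevs$alt, "N")
  ## family with an empty strand family is rejected, not an error
  fam0 <- group_families(mk_family(n_b = 0))
  cons0 <- build_consensuses(fam0, no_devs)
  expect_equal(cons0$consensus$status, "rejected")
  ## a single-strand artifact never becomes a pass call (duplex guarantee)
  g <- small_dataset(seed = 1, length = 3000, n_genes = c(CDS = 1, tRNA = 1))
  calls <- call_variants(consN, g$genome, g$features)
  expect_equal(nrow(calls), 0L)
})

test_that("variant calling classifies, pairs adjacent SNVs, and trims ends", {
  sg <- small_dataset(seed = 1, length = 3000, n_genes = c(CDS = 1, tRNA = 1))
  b <- strsplit(sg$genome$sequence, "")[[1]]
  fam <- group_families(mk_family())
  ## consensus equal to reference -> no calls
  expect_equal(nrow(call_variants(build_consensuses(fam, no_devs),
                                  sg$genome, sg$features)), 0L)
  ## a purine-reference change reports the complementary pyrimidine class
  pA <- which(b == "A")[10]
  dA <- data.table(read_id = 1:6, pos = pA, type = "M", alt = "G", len = 1L)
  cA <- call_variants(build_consensuses(fam <- group_families(
    mk_family(start = pA - 50L)), dA), sg$genome, sg$features)
  expect_equal(cA$type, "SNV")
  expect_equal(cA$class, "T>C")
  expect_equal(cA$pyr_strand, "-")
  ## two adjacent changed bases merge into one dinucleotide call
  p <- 500L
  alt1 <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  alt2 <- setdiff(c("A", "C", "G", "T"), b[p + 1])[1]
  dd <- data.table(read_id = rep(1:6, 2), pos = rep(c(p, p + 1L), each = 6),
                   type = "M", alt = rep(c(alt1, alt2), each = 6), len = 1L)
  cd <- call_variants(build_consensuses(group_families(mk_family(start = 450L)),
                                        dd), sg$genome, sg$features)
  expect_equal(nrow(cd), 1L)
  expect_equal(cd$type, "dinucleotide")
  expect_equal(nchar(cd$alt), 2L)
  ## calls near molecule ends are flagged end_trimmed
  pe <- 455L
  alt3 <- setdiff(c("A", "C", "G", "T"), b[pe])[1]
  de <- data.table(read_id = 1:6, pos = pe, type = "M", alt = alt3, len = 1L)
  ce <- call_variants(build_consensuses(group_families(mk_family(start = 450L)),
                                        de), sg$genome, sg$features,
                      end_trim = 10L)
  expect_equal(ce$status, "end_trimmed")
})

test_that("indels are left-aligned to a canonical key", {
  g <- organelle_genome("h", paste0(strrep("ACGC", 50), "TTTTT",
                                    strrep("GACT", 50)))
  fam <- group_families(mk_family(start = 180L, len = 100L))
  ## delete the last T of the homopolymer TTTTT at 201..205
  d <- data.table(read_id = 1:6, pos = 205L, type = "D", alt = NA_character_,
                  len = 1L)
  cc <- call_variants(build_consensuses(fam, d), g,
                      gene_features(character(), character(), integer(),
                                    integer(), character()))
  expect_equal(cc$type, "deletion")
  expect_equal(cc$pos, 201L)   # shifted to the leftmost equivalent placement
})

test_that("variant frequencies normalize by callable duplex coverage", {
  calls <- data.table(type = c("SNV", "SNV", "deletion"),
                      status = c("pass", "pass", "pass"))
  expect_equal(variant_frequency(calls, 1e6, "SNV"), 2e-6)
  expect_equal(variant_frequency(calls, 1e6, "indel"), 1e-6)
  expect_equal(variant_frequency(calls[0], 1e6, "SNV"), 0)
  expect_error(variant_frequency(calls, 0, "SNV"), "zero")
})

test_that("frequencies are invariant under read and family order", {
  sg <- small_dataset(seed = 8)
  mm <- mutation_model(c("C>T" = 2e-4, "T>A" = 1e-4))
  sim <- simulate_duplex_families(sg$genome, sg$features, mm,
                                  n_molecules = 1500, seq_error = 1e-3,
                                  seed = 9)
  run <- function(reads, devs) {
    cons <- build_consensuses(group_families(reads), devs)
    calls <- call_variants(cons, sg$genome, sg$features)
    cov <- coverage_profile(cons, sg$genome$length)
    variant_frequency(calls, cov, "SNV")
  }
  f1 <- run(sim$reads, sim$devs)
  perm <- sample(nrow(sim$reads))
  f2 <- run(sim$reads[perm], sim$devs[sample(nrow(sim$devs))])
  expect_identical(f1, f2)
})

test_that("context-stratified coverage sums back to total depth (conservation)", {
  sg <- small_dataset(seed = 10)
  sim <- simulate_duplex_families(sg$genome, sg$features,
                                  mutation_model(c("C>T" = 1e-4)),
                                  n_molecules = 800, seed = 11)
  cons <- build_consensuses(group_families(sim$reads), sim$devs)
  calls <- call_variants(cons, sg$genome, sg$features)
  cov <- coverage_profile(cons, sg$genome$length)
  tf <- trinucleotide_frequencies(calls, cov$depth, sg$genome, "C>T")
  b <- strsplit(sg$genome$sequence, "")[[1]]
  expect_equal(sum(tf$coverage),
               sum(as.numeric(cov$depth[b %in% c("C", "G")])))
  ## marginal consistency: context counts sum to the class count
  expect_equal(sum(tf$count),
               sum(calls$status == "pass" & calls$type == "SNV" &
                     calls$class == "C>T"))
})

test_that("the nuclear-paralog filter removes planted NUMT artifacts exactly", {
  sg <- small_dataset(seed = 12)
  g <- sg$genome
  nf <- simulate_numt_fixture(g, 5000, 9000, n_paralog_variants = 6, seed = 13)
  gen <- simulate_duplex_families(g, sg$features,
                                  mutation_model(c("C>T" = 2e-4, "C>A" = 1e-4)),
                                  n_molecules = 1500, seed = 14)
  con <- simulate_numt_contamination(g, nf, 5000, 9000, n_molecules = 200,
                                     seed = 15)
  both <- combine_duplex_sets(gen, con)
  cons <- build_consensuses(group_families(both$reads), both$devs)
  calls <- call_variants(cons, g, sg$features)
  calls <- numt_filter(calls, cons, g, nf$nuclear)
  is_paralog <- grepl("^NUMT", calls$tag)
  expect_true(all(calls$status[is_paralog & calls$status != "end_trimmed"] ==
                    "numt"))
  expect_false(any(calls$status[!is_paralog] == "numt"))
  ## the haplotype window itself: verbatim presence flags, absence passes
  expect_gt(sum(calls$status == "numt"), 0)
})
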