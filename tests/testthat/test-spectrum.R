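test_that("substitutions collapse onto the six pyrimidine classes", {
  cs <- classify_substitution(c("G", "C", "A", "T"), c("A", "T", "C", "G"))
  expect_equal(cs$class, c("C>T", "C>T", "T>G", "T>G"))
  expect_equal(cs$pyr_strand, c("-", "+", "-", "+"))
  expect_equal(cs$transition, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(classify_substitution("N", "A"), "non-ACGT")
  expect_error(classify_substitution("A", "A"), "substitution")
})

test_that("region frequencies localize calls and flag empty regions", {
  sg <- small_dataset(seed = 30)
  rmap <- region_map(sg$features, sg$genome$length)
  cds_pos <- which(rmap$region == "CDS")[1:5]
  calls <- data.table(pos = cds_pos, type = "SNV", class = "C>T",
                      status = "pass", region = "CDS")
  depth <- rep(10L, sg$genome$length)
  rf <- region_frequencies(calls, depth, sg$features, sg$genome$length)
  tab <- rf$table
  expect_gt(tab[tab$region == "CDS"]$frequency, 0)
  expect_true(all(tab[tab$region != "CDS"]$frequency == 0))
  ## zero calls -> all-zero frequencies
  rf0 <- region_frequencies(calls[0], depth, sg$features, sg$genome$length)
  expect_true(all(rf0$table$frequency == 0))
})

test_that("strand asymmetry assigns all four pyrimidine x gene strand cases", {
  sg <- small_dataset(seed = 31)
  rmap <- region_map(sg$features, sg$genome$length)
  b <- strsplit(sg$genome$sequence, "")[[1]]
  depth <- rep(5L, sg$genome$length)
  pick <- function(gs, base) {
    which(rmap$strand == gs & b == base & rmap$region == "CDS")[1]
  }
  ## C on + in a + gene: pyrimidine on the sense strand -> non-template
  ## G on + in a + gene: pyrimidine on - -> template; mirrored for - genes
  pos <- c(pick("+", "C"), pick("+", "G"), pick("-", "C"), pick("-", "G"))
  calls <- data.table(pos = pos, type = "SNV", class = "C>T", status = "pass",
                      pyr_strand = c("+", "-", "+", "-"),
                      gene_strand = c("+", "+", "-", "-"),
                      region = "CDS")
  sa <- strand_asymmetry(calls, depth, sg$features, sg$genome, "C>T",
                         test = "none")
  cds <- sa$table[sa$table$region == "CDS"]
  expect_equal(cds$count_nontemplate, 2L)  # cases 1 and 4
  expect_equal(cds$count_template, 2L)     # cases 2 and 3
})

test_that("calls planted exclusively on template strands are all assigned template", {
  sg <- small_dataset(seed = 32)
  sim <- simulate_duplex_families(sg$genome, sg$features,
                                  mutation_model(c("C>T" = 1e-9),
                                                 template_strand_bias = 1e6),
                                  n_molecules = 3000, seed = 33)
  cons <- build_consensuses(group_families(sim$reads), sim$devs)
  calls <- call_variants(cons, sg$genome, sg$features)
  genic <- calls[calls$gene_strand %in% c("+", "-") & calls$class == "C>T"]
  expect_gt(nrow(genic), 10)
  expect_true(all(genic$pyr_strand != genic$gene_strand))
  sa <- strand_asymmetry(calls, rep(1L, sg$genome$length), sg$features,
                         sg$genome, "C>T", test = "none")
  expect_equal(sum(sa$table$count_nontemplate), 0L)
})

test_that("asymmetry tables are invariant under reverse-complementing the world", {
  sg <- small_dataset(seed = 34)
  L <- sg$genome$length
  sim <- simulate_duplex_families(sg$genome, sg$features,
                                  mutation_model(c("C>T" = 3e-4),
                                                 template_strand_bias = 4),
                                  n_molecules = 2000, seed = 35)
  cons <- build_consensuses(group_families(sim$reads), sim$devs)
  calls <- call_variants(cons, sg$genome, sg$features)
  cov <- coverage_profile(cons, L)
  sa1 <- strand_asymmetry(calls, cov$depth, sg$features, sg$genome, "C>T",
                          test = "none")$table
  ## mirrored dataset: genome, features, calls and depth reverse-complemented
  g2 <- organelle_genome(sg$genome$id, revcomp(sg$genome$sequence))
  f2 <- gene_features(sg$features$name, sg$features$region_class,
                      L - sg$features$end + 1L, L - sg$features$start + 1L,
                      ifelse(sg$features$strand == "+", "-", "+"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  calls2 <- data.table::copy(calls)
  calls2[, pos := L - pos + 1L]
  calls2[, pyr_strand := ifelse(pyr_strand == "+", "-", "+")]
  calls2[, gene_strand := ifelse(gene_strand == "+", "-", "+")]
  sa2 <- strand_asymmetry(calls2, rev(cov$depth), f2, g2, "C>T",
                          test = "none")$table
  expect_equal(sa2$count_nontemplate, sa1$count_nontemplate)
  expect_equal(sa2$count_template, sa1$count_template)
  expect_equal(sa2$coverage_nontemplate, sa1$coverage_nontemplate)
  expect_equal(sa2$freq_template, sa1$freq_template)
})

test_that("fold enrichment pools counts before dividing", {
  expect_equal(fold_enrichment(84, 1e8, 10, 1e8), 8.4)
  expect_equal(fold_enrichment(5, 1e6, 5, 1e6), 1)
  ## pooling rule: (2+6)/(1e6+1e6) over (1+1)/(1e6+1e6) = 4, not mean(2, 6)
  expect_equal(fold_enrichment(c(2, 6), c(1e6, 1e6), c(1, 1), c(1e6, 1e6)), 4)
  expect_true(is.na(fold_enrichment(3, 1e6, 0, 1e6)))
})

test_that("trinucleotide table isolates the planted context", {
  g <- tiny_genome(strrep("TCAGGGAT", 50))
  depth <- rep(0L, g$length)
  ## coverage only at the TCA context sites (C at positions 2 mod 8)
  cpos <- seq(2, g$length, by = 8)
  depth[cpos] <- 100L
  calls <- data.table(pos = cpos[1], type = "SNV", class = "C>T",
                      status = "pass", context = "TCA")
  tf <- trinucleotide_frequencies(calls, depth, g, "C>T")
  cell <- tf[tf$context == "TCA"]
  expect_equal(cell$count, 1L)
  expect_equal(cell$frequency, 1 / (length(cpos) * 100))
  expect_true(all(is.na(tf[tf$context != "TCA"]$frequency)))
})

test_that("group tests wrap the standard routines with degenerate-input handling", {
  ## identical groups: non-significant
  r <- group_tests(c(1, 1, 1, 2, 2, 2) * 1e-7,
                   group = rep(c("wt", "wt2"), each = 3), method = "kruskal")
  expect_false(r$skipped)
  ## 10x shift with zero variance: called significant by group means
  r2 <- group_tests(c(1, 1, 1, 10, 10, 10) * 1e-7,
                    group = rep(c("wt", "mut"), each = 3), method = "t")
  expect_false(r2$skipped)
  expect_lt(r2$p_value, 0.05)
  r2b <- group_tests(rep(1e-7, 6), group = rep(c("a", "b"), each = 3),
                     method = "t")
  expect_equal(r2b$p_value, 1)
  ## paired methods need pairs
  expect_true(group_tests(1:3, method = "wilcoxon_paired")$skipped)
  p <- group_tests(c(1, 2, 3, 4, 5, 6), freq2 = c(2, 2.4, 4.1, 5.6, 6.2, 7.9),
                   method = "t_paired")
  expect_false(p$skipped)
  ## anova + tukey returns pairwise table
  a <- group_tests(c(1, 2, 1.5, 9, 10, 11, 5, 6, 5.5),
                   group = rep(c("a", "b", "c"), each = 3),
                   method = "anova_tukey")
  expect_false(a$skipped)
  expect_true(!is.null(a$tukey))
  expect_true(group_tests(1:4, group = rep("a", 4), method = "t")$skipped)
})

test_that("simulated null cohorts give nominal region-effect type-I error", {
  ## uniform mutation rate: the Kruskal-Wallis region test should reject at
  ## about the nominal level
  sg <- small_dataset(seed = 36)
  mm <- mutation_model(c("C>T" = 3e-4, "T>C" = 3e-4))
  n_cohorts <- 40
  pvals <- numeric(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    depth <- list(); calls <- list()
    for (r in 1:4) {
      sim <- simulate_duplex_families(sg$genome, sg$features, mm,
                                      n_molecules = 1200,
                                      seed = 5000 + i * 10 + r)
      cons <- build_consensuses(group_families(sim$reads), sim$devs)
      cc <- call_variants(cons, sg$genome, sg$features)
      cc[, replicate := paste0("rep", r)]
      calls[[r]] <- cc
      depth[[paste0("rep", r)]] <-
        coverage_profile(cons, sg$genome$length)$depth
    }
    rf <- region_frequencies(rbindlist(calls), depth, sg$features,
                             sg$genome$length)
    pvals[i] <- rf$kruskal$p.value
  }
  ## no significant region effect in at least 95% of null cohorts would be
  ## the strict reading; allow the binomial wiggle at this cohort count
  expect_lte(sum(pvals < 0.05), stats::qbinom(0.999, n_cohorts, 0.05) + 1)
})
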