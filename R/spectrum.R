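## Mutation-landscape analyses on pass-filter duplex calls: six-class
## substitution spectra, per-region frequencies, transcriptional strand
## asymmetry, and coverage-normalized trinucleotide profiles. Frequencies are
## always numerator count / duplex coverage of the matching site stratum, so
## they are not inflated for common sequence contexts or composition
## differences between strands.

PYRIMIDINES <- c("C", "T")

#' Classify a substitution into the six pyrimidine-keyed classes
#'
#' Purine-reference changes are reported as the complementary pyrimidine
#' change with the strand flag flipped (G>A is C>T with the pyrimidine on the
#' reference minus strand).
#'
#' @param ref,alt single-base character vectors, `ref != alt`.
#' @return data.table with `class` (e.g. `"C>T"`), `pyr_strand` (`"+"`/`"-"`)
#'   and `transition` (logical).
#' @export
classify_substitution <- function(ref, alt) {
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("non-ACGT base in substitution")
  if (any(ref == alt)) stop("ref == alt is not a substitution")
  on_plus <- ref %in% PYRIMIDINES
  cls <- ifelse(on_plus, paste0(ref, ">", alt),
                paste0(COMPLEMENT[ref], ">", COMPLEMENT[alt]))
  data.table(class = cls, pyr_strand = ifelse(on_plus, "+", "-"),
             transition = cls %in% c("C>T", "T>C"))
}

## per-region duplex coverage from a depth vector and a region map
region_coverage <- function(depth, rmap) {
  vapply(REGION_LEVELS, function(r) sum(as.numeric(depth[rmap$region == r])),
         numeric(1))
}

#' Per-region variant frequencies
#'
#' Frequency of pass calls per region class, normalized by the duplex
#' coverage of that region. With a `replicate` column present, per-replicate
#' frequencies are returned and a Kruskal-Wallis test across regions is run
#' on them.
#'
#' @param calls calls table (pass rows are used); may carry a `replicate`
#'   column and a per-replicate list of depths via `depth`.
#' @param depth per-position duplex depth vector (summed over replicates), or
#'   a named list of per-replicate depth vectors.
#' @param features feature table.
#' @param genome_length genome length.
#' @param class_filter optional substitution class (e.g. `"C>T"`).
#' @param type variant type counted (default `"SNV"`).
#' @return list with `table` (region, count, coverage, frequency[, replicate])
#'   and `kruskal` (htest or NULL).
#' @export
region_frequencies <- function(calls, depth, features, genome_length,
                               class_filter = NULL, type = "SNV") {
  rmap <- region_map(features, genome_length)
  type_ <- type
  use <- calls[status == "pass" & calls$type == type_]
  if (!is.null(class_filter)) use <- use[class == class_filter]
  per_rep <- is.list(depth) && !is.null(names(depth))
  if (!per_rep) depth <- list(all = depth)
  reps <- names(depth)
  tabs <- lapply(reps, function(r) {
    u <- if (per_rep) use[replicate == r] else use
    cov <- region_coverage(depth[[r]], rmap)
    cnt <- table(factor(u$region, levels = REGION_LEVELS))
    data.table(replicate = r, region = REGION_LEVELS,
               count = as.integer(cnt), coverage = cov,
               frequency = ifelse(cov > 0, as.integer(cnt) / cov, NA_real_))
  })
  tab <- rbindlist(tabs)
  kr <- NULL
  if (per_rep && length(reps) >= 2L) {
    ok <- tab[!is.na(frequency)]
    if (length(unique(ok$region)) >= 2L)
      kr <- stats::kruskal.test(frequency ~ factor(region), data = ok)
  }
  list(table = tab, kruskal = kr)
}

## per-position logical masks of genic single-strand sites whose
## NON-TEMPLATE-strand base equals `base`; the non-template (sense) strand is
## the gene's strand, so for a "+" gene the + reference base is read, for a
## "-" gene its complement.
nontemplate_base_mask <- function(b, rmap, base) {
  gs <- rmap$strand
  (gs == "+" & b == base) | (gs == "-" & b == COMPLEMENT[[base]])
}

#' Transcriptional strand asymmetry of a complementary class pair
#'
#' For genic single-strand sites, compares the frequency of a pyrimidine
#' change as it reads on the non-template (sense) strand against the
#' complementary purine change, per region, each normalized by the duplex
#' coverage of the corresponding base on that strand. A change whose
#' pyrimidine strand equals the gene strand reads as `C>T` (etc.) on the
#' non-template strand; otherwise it reads as the purine change `G>A`, i.e.
#' the pyrimidine sat on the template strand.
#'
#' @param calls calls table (with optional `replicate` column).
#' @param depth depth vector or named per-replicate list of depth vectors.
#' @param features feature table.
#' @param g [organelle_genome()].
#' @param class pyrimidine class, default `"C>T"`.
#' @param test `"wilcoxon"` (paired signed-rank), `"t"` (paired t-test) or
#'   `"none"`.
#' @return list with `table` (replicate, region, counts and frequencies on
#'   the non-template and template strand) and `tests` (per-region paired
#'   test results, pairing replicates).
#' @export
strand_asymmetry <- function(calls, depth, features, g, class = "C>T",
                             test = "wilcoxon") {
  b <- genome_bases(g)
  rmap <- region_map(features, g$length)
  pyr <- substr(class, 1, 1)
  genic_regions <- setdiff(REGION_LEVELS, "intergenic")
  per_rep <- is.list(depth) && !is.null(names(depth))
  if (!per_rep) depth <- list(all = depth)
  ## denominators: coverage of the pyrimidine base as read on each strand
  mask_nt <- nontemplate_base_mask(b, rmap, pyr)      # pyrimidine on sense
  mask_t <- nontemplate_base_mask(b, rmap, COMPLEMENT[[pyr]]) # pyr on template
  class_ <- class
  use <- calls[status == "pass" & calls$type == "SNV" & calls$class == class_ &
                 gene_strand %in% c("+", "-")]
  rows <- list()
  for (r in names(depth)) {
    u <- if (per_rep) use[replicate == r] else use
    on_template <- u$pyr_strand != u$gene_strand
    for (reg in genic_regions) {
      sel <- rmap$region == reg
      cov_nt <- sum(as.numeric(depth[[r]][sel & mask_nt]))
      cov_t <- sum(as.numeric(depth[[r]][sel & mask_t]))
      n_nt <- sum(u$region == reg & !on_template)
      n_t <- sum(u$region == reg & on_template)
      rows[[length(rows) + 1L]] <- data.table(
        replicate = r, region = reg,
        count_nontemplate = n_nt, coverage_nontemplate = cov_nt,
        freq_nontemplate = if (cov_nt > 0) n_nt / cov_nt else NA_real_,
        count_template = n_t, coverage_template = cov_t,
        freq_template = if (cov_t > 0) n_t / cov_t else NA_real_)
    }
  }
  tab <- rbindlist(rows)
  tests <- NULL
  if (test != "none" && length(depth) >= 2L) {
    tests <- lapply(setNames(genic_regions, genic_regions), function(reg) {
      d <- tab[region == reg & !is.na(freq_nontemplate) & !is.na(freq_template)]
      if (nrow(d) < 2L) return(NULL)
      if (identical(d$freq_nontemplate, d$freq_template)) return(NULL)
      if (test == "wilcoxon")
        stats::wilcox.test(d$freq_nontemplate, d$freq_template, paired = TRUE,
                           exact = FALSE)
      else stats::t.test(d$freq_nontemplate, d$freq_template, paired = TRUE)
    })
  }
  list(table = tab, tests = tests)
}

#' Coverage-normalized trinucleotide mutation frequencies
#'
#' Frequency of a substitution class per 16 (5', 3') neighbor combinations,
#' with the context read on the strand of the pyrimidine, normalized by the
#' duplex coverage of sites carrying that context so that common contexts are
#' not inflated.
#'
#' @param calls calls table.
#' @param depth per-position duplex depth vector.
#' @param g [organelle_genome()].
#' @param class substitution class, default `"C>T"`.
#' @return data.table with `five`, `three`, `context`, `count`, `coverage`,
#'   `frequency` (NA where the context has no coverage).
#' @export
trinucleotide_frequencies <- function(calls, depth, g, class = "C>T") {
  b <- genome_bases(g)
  L <- g$length
  pyr <- substr(class, 1, 1)
  ## context of every site, read on the strand of its pyrimidine
  on_plus <- b == pyr
  on_minus <- b == COMPLEMENT[[pyr]]
  five <- rep(NA_character_, L); three <- rep(NA_character_, L)
  ip <- which(on_plus); im <- which(on_minus)
  five[ip] <- b[fold_pos(ip - 1L, L)]; three[ip] <- b[fold_pos(ip + 1L, L)]
  five[im] <- COMPLEMENT[b[fold_pos(im + 1L, L)]]
  three[im] <- COMPLEMENT[b[fold_pos(im - 1L, L)]]
  grid <- CJ(five = BASES, three = BASES)
  site_key <- paste0(five, three)
  cov <- vapply(paste0(grid$five, grid$three), function(k)
    sum(as.numeric(depth[!is.na(site_key) & site_key == k])), numeric(1))
  class_ <- class
  use <- calls[status == "pass" & calls$type == "SNV" & calls$class == class_]
  cnt_key <- paste0(substr(use$context, 1, 1), substr(use$context, 3, 3))
  cnt <- vapply(paste0(grid$five, grid$three), function(k) sum(cnt_key == k),
                numeric(1))
  grid[, `:=`(context = paste0(five, pyr, three), count = as.integer(cnt),
              coverage = cov,
              frequency = ifelse(cov > 0, cnt / cov, NA_real_))]
  grid[]
}

#' Fold enrichment between two frequency strata
#'
#' Pools numerators and denominators before dividing (never a mean of
#' per-cell ratios), which is robust to empty cells.
#'
#' @param count_a,coverage_a numerator and denominator of stratum A (vectors
#'   are summed).
#' @param count_b,coverage_b same for stratum B.
#' @return the ratio `(sum(count_a)/sum(coverage_a)) /
#'   (sum(count_b)/sum(coverage_b))`; `NA` if undefined.
#' @export
fold_enrichment <- function(count_a, coverage_a, count_b, coverage_b) {
  fa <- sum(as.numeric(count_a)) / sum(as.numeric(coverage_a))
  fb <- sum(as.numeric(count_b)) / sum(as.numeric(coverage_b))
  if (!is.finite(fb) || fb == 0) return(NA_real_)
  fa / fb
}

#' Group-comparison tests on per-replicate frequencies
#'
#' Thin wrappers over the standard routines: two-tailed t-test, paired
#' Wilcoxon signed-rank, Kruskal-Wallis, and one-way ANOVA with Tukey HSD.
#' Degenerate inputs (fewer than two replicates per group, zero variance
#' everywhere) yield a skipped result with a reason rather than an error.
#'
#' @param freq numeric vector of per-replicate frequencies.
#' @param group factor of group labels (same length); for `method =
#'   "wilcoxon_paired"` or `"t_paired"` supply `freq2` instead.
#' @param freq2 second member of each pair for paired methods.
#' @param method `"t"`, `"t_paired"`, `"wilcoxon_paired"`, `"kruskal"` or
#'   `"anova_tukey"`.
#' @return list with `method`, `p_value`, `statistic`, `fit` (the underlying
#'   test object), or `skipped` + `reason`.
#' @export
group_tests <- function(freq, group = NULL, freq2 = NULL, method = "t") {
  skip <- function(reason) list(method = method, skipped = TRUE, reason = reason)
  result <- function(fit, p, stat) list(method = method, skipped = FALSE,
                                        p_value = p, statistic = stat, fit = fit)
  if (method %in% c("t_paired", "wilcoxon_paired")) {
    if (is.null(freq2) || length(freq2) != length(freq))
      return(skip("paired methods need freq2 of equal length"))
    if (length(freq) < 2L) return(skip("fewer than 2 pairs"))
    if (all(freq == freq2)) return(skip("identical pairs: no signal"))
    fit <- if (method == "t_paired")
      stats::t.test(freq, freq2, paired = TRUE)
    else stats::wilcox.test(freq, freq2, paired = TRUE, exact = FALSE)
    return(result(fit, fit$p.value, unname(fit$statistic)))
  }
  if (is.null(group)) return(skip("group required"))
  group <- factor(group)
  if (nlevels(group) < 2L) return(skip("fewer than 2 groups"))
  if (method == "t") {
    if (nlevels(group) != 2L) return(skip("t-test needs exactly 2 groups"))
    n <- table(group)
    if (any(n < 2L)) return(skip("fewer than 2 replicates in a group"))
    if (all(tapply(freq, group, stats::var) == 0)) {
      ## zero within-group variance: t statistic undefined; call it by the
      ## group means (distinct means are trivially separated)
      m <- tapply(freq, group, mean)
      return(list(method = method, skipped = FALSE,
                  p_value = if (m[1] == m[2]) 1 else 0,
                  statistic = NA_real_, fit = NULL))
    }
    fit <- stats::t.test(freq ~ group)
    return(result(fit, fit$p.value, unname(fit$statistic)))
  }
  if (method == "kruskal") {
    fit <- stats::kruskal.test(freq ~ group)
    return(result(fit, fit$p.value, unname(fit$statistic)))
  }
  if (method == "anova_tukey") {
    fit <- stats::aov(freq ~ group)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)
    out <- result(fit, an[["Pr(>F)"]][1], an[["F value"]][1])
    out$tukey <- tk$group
    return(out)
  }
  skip(paste("unknown method", method))
}
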