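## Duplex consensus calling: collapse tagged read families into double-strand
## consensus molecules, call variants against the reference, filter nuclear
## paralog (NUMT/NUPT) artifacts, and compute coverage-aware frequencies.
##
## A true variant must be supported by the consensus of BOTH strand-families
## of a molecule; positions failing consensus are N, never a guessed base.

#' Group aligned, tagged reads into duplex families
#'
#' Reads sharing a tag form a family; reads carrying one tag at clearly
#' distinct loci (start positions differing by more than `locus_slop`) are
#' split into separate families. Untagged reads are rejected and counted.
#'
#' @param reads data.table with columns `read_id`, `tag`, `strand_fam`
#'   (`"A"`/`"B"`), `start`, `len`.
#' @param locus_slop maximum start-position scatter within one family (bp).
#' @return the reads table with a `family` column; attribute `n_untagged`
#'   counts rejected reads.
#' @export
group_families <- function(reads, locus_slop = 10L) {
  reads <- as.data.table(reads)
  untagged <- is.na(reads$tag) | reads$tag == ""
  out <- reads[!untagged]
  setorder(out, tag, start)
  new_fam <- c(TRUE, out$tag[-1] != out$tag[-nrow(out)] |
                 (out$start[-1] - out$start[-nrow(out)]) > locus_slop)
  out[, family := cumsum(new_fam)]
  attr(out, "n_untagged") <- sum(untagged)
  out[]
}

#' Build duplex consensus molecules for all families
#'
#' Per strand-family a base is called where at least
#' `strand_consensus_threshold` of its reads agree; otherwise N. The duplex
#' base is called only where both strand consensuses agree and neither is N.
#' Families with fewer than `min_reads_per_strand` reads on either strand are
#' rejected (a counted outcome, not an error).
#'
#' @param families reads table from [group_families()].
#' @param devs read-level deviation table (`read_id`, `pos`, `type`, `alt`,
#'   `len`).
#' @param min_reads_per_strand minimum reads per strand-family.
#' @param strand_consensus_threshold fraction of reads that must agree.
#' @return list with `consensus` (one row per family: `family`, `tag`,
#'   `start`, `len`, `n_a`, `n_b`, `status`) and `cdevs` (consensus
#'   deviations; rows with `alt == "N"` mark uncallable positions).
#' @export
build_consensuses <- function(families, devs, min_reads_per_strand = 3L,
                              strand_consensus_threshold = 0.9) {
  fam <- families[, .(n_a = sum(strand_fam == "A"), n_b = sum(strand_fam == "B"),
                      tag = tag[1], start = start[1], len = len[1]),
                  by = family]
  fam[, status := ifelse(n_a >= min_reads_per_strand & n_b >= min_reads_per_strand,
                         "pass", "rejected")]
  pass_fam <- fam[status == "pass"]
  empty_cdevs <- data.table(family = integer(), pos = integer(),
                            type = character(), alt = character(), len = integer())
  if (!nrow(devs) || !nrow(pass_fam))
    return(list(consensus = fam, cdevs = empty_cdevs))

  d <- merge(devs, families[, .(read_id, family, strand_fam)], by = "read_id")
  d <- d[family %in% pass_fam$family]
  if (!nrow(d)) return(list(consensus = fam, cdevs = empty_cdevs))
  ## one consensus site = (family, pos); alleles are (type, alt, len) with the
  ## implicit reference allele on reads carrying no deviation there
  d[is.na(alt), alt := "-"]
  cnt <- d[, .N, by = .(family, pos, strand_fam, type, alt, len)]
  ns <- pass_fam[, .(family, n_a, n_b)]
  cnt <- merge(cnt, ns, by = "family")
  cnt[, n_strand := ifelse(strand_fam == "A", n_a, n_b)]
  thr <- strand_consensus_threshold
  ## per (family, pos, strand): the called allele
  strand_call <- cnt[, {
    n_ref <- n_strand[1] - sum(N)
    if (n_ref < 0L) n_ref <- 0L            # overlapping allele bookkeeping guard
    counts <- c(N, n_ref)
    lab <- c(paste(type, alt, len, sep = "\r"), "ref")
    j <- which.max(counts)
    called <- if (counts[j] / n_strand[1] >= thr) lab[j] else "Ncall"
    .(called = called)
  }, by = .(family, pos, strand_fam)]
  wide <- dcast(strand_call, family + pos ~ strand_fam, value.var = "called",
                fill = "ref")
  if (is.null(wide$A)) wide[, A := "ref"]
  if (is.null(wide$B)) wide[, B := "ref"]
  wide[, duplex := ifelse(A == "Ncall" | B == "Ncall" | A != B, "Ncall",
                          A)]
  res <- wide[duplex != "ref"]
  if (!nrow(res)) return(list(consensus = fam, cdevs = empty_cdevs))
  parts <- tstrsplit(ifelse(res$duplex == "Ncall", "M\rN\r1", res$duplex), "\r")
  cdevs <- data.table(family = res$family, pos = res$pos,
                      type = parts[[1]], alt = parts[[2]],
                      len = as.integer(parts[[3]]))
  cdevs[alt == "-", alt := NA_character_]
  list(consensus = fam, cdevs = cdevs[order(family, pos)])
}

#' Build the consensus of a single duplex family
#'
#' Convenience wrapper around [build_consensuses()] for one family.
#'
#' @inheritParams build_consensuses
#' @param family reads of one family (with a `family` column, or one is
#'   added).
#' @return list with one-row `consensus` and that family's `cdevs`.
#' @export
build_consensus <- function(family, devs, min_reads_per_strand = 3L,
                            strand_consensus_threshold = 0.9) {
  family <- as.data.table(family)
  if (is.null(family$family)) family[, family := 1L]
  build_consensuses(family, devs, min_reads_per_strand,
                    strand_consensus_threshold)
}

## left-align an indel against the reference (VCF-style) so identical
## molecules give identical call keys
left_align_indel <- function(b, pos, type, alt, len, L) {
  if (type == "D") {
    while (pos > 1L && b[pos - 1L] == b[pos + len - 1L]) pos <- pos - 1L
  } else {
    a <- strsplit(alt, "")[[1]]
    while (pos > 1L && a[length(a)] == b[pos]) {
      a <- c(b[pos], a[-length(a)])
      pos <- pos - 1L
    }
    alt <- paste(a, collapse = "")
  }
  list(pos = pos, alt = alt)
}

#' Call variants from duplex consensus molecules
#'
#' Consensus mismatches become SNVs; two adjacent SNVs on one molecule are
#' reported as a single dinucleotide call; runs of three or more adjacent
#' changed bases are reported as `multinucleotide` (excluded from SNV and
#' dinucleotide tallies). Indels are left-aligned. Calls within `end_trim`
#' bases of either molecule end get filter status `end_trimmed`. Every call
#' is annotated with region class, gene strand, substitution class and the
#' trinucleotide context on the strand of the pyrimidine.
#'
#' @param cons output of [build_consensuses()].
#' @param g [organelle_genome()].
#' @param features feature table.
#' @param end_trim bp distrusted at each molecule end.
#' @return data.table of calls with columns `family`, `tag`, `pos`, `type`,
#'   `ref`, `alt`, `class`, `pyr_strand`, `region`, `gene_strand`, `context`,
#'   `status`.
#' @export
call_variants <- function(cons, g, features, end_trim = 10L) {
  b <- genome_bases(g)
  L <- g$length
  rmap <- region_map(features, L)
  cd <- cons$cdevs[!(type == "M" & alt == "N")]
  empty <- data.table(family = integer(), tag = character(), pos = integer(),
                      type = character(), ref = character(), alt = character(),
                      class = character(), pyr_strand = character(),
                      region = character(), gene_strand = character(),
                      context = character(), status = character())
  if (!nrow(cd)) return(empty)
  cd <- merge(cd, cons$consensus[, .(family, tag, start, len = len)],
              by = "family", suffixes = c("", ".mol"))
  setnames(cd, "len.mol", "mol_len")

  calls_list <- list()
  ## SNV / dinucleotide / multinucleotide from M deviations
  m <- cd[type == "M"]
  if (nrow(m)) {
    setorder(m, family, pos)
    run_break <- c(TRUE, !(m$family[-1] == m$family[-nrow(m)] &
                             m$pos[-1] == m$pos[-nrow(m)] + 1L))
    m[, run := cumsum(run_break)]
    m[, run_len := .N, by = run]
    snv <- m[run_len == 1L]
    if (nrow(snv)) {
      cl <- classify_substitution(b[snv$pos], snv$alt)
      calls_list$snv <- data.table(
        family = snv$family, tag = snv$tag, pos = snv$pos, type = "SNV",
        ref = b[snv$pos], alt = snv$alt, class = cl$class,
        pyr_strand = cl$pyr_strand, start = snv$start, mol_len = snv$mol_len)
    }
    multi <- m[run_len >= 2L,
               .(pos = pos[1], ref = paste(b[pos], collapse = ""),
                 alt = paste(alt, collapse = ""), tag = tag[1],
                 start = start[1], mol_len = mol_len[1], n = .N),
               by = .(family, run)]
    if (nrow(multi)) {
      calls_list$multi <- data.table(
        family = multi$family, tag = multi$tag, pos = multi$pos,
        type = ifelse(multi$n == 2L, "dinucleotide", "multinucleotide"),
        ref = multi$ref, alt = multi$alt, class = NA_character_,
        pyr_strand = NA_character_, start = multi$start,
        mol_len = multi$mol_len)
    }
  }
  ind <- cd[type %in% c("I", "D")]
  if (nrow(ind)) {
    la <- lapply(seq_len(nrow(ind)), function(i)
      left_align_indel(b, ind$pos[i], ind$type[i], ind$alt[i], ind$len[i], L))
    la_pos <- vapply(la, `[[`, integer(1), "pos")
    la_alt <- vapply(la, function(x) {
      if (is.null(x$alt) || is.na(x$alt)) "" else x$alt
    }, character(1))
    ref_del <- vapply(seq_len(nrow(ind)), function(i) {
      if (ind$type[i] == "D")
        paste(b[la_pos[i]:(la_pos[i] + ind$len[i] - 1L)], collapse = "")
      else ""
    }, character(1))
    calls_list$indel <- data.table(
      family = ind$family, tag = ind$tag, pos = la_pos,
      type = ifelse(ind$type == "I", "insertion", "deletion"),
      ref = ref_del, alt = ifelse(ind$type == "I", la_alt, ""),
      class = NA_character_, pyr_strand = NA_character_,
      start = ind$start, mol_len = ind$mol_len)
  }
  if (!length(calls_list)) return(empty)
  calls <- rbindlist(calls_list)

  ## end trimming: offset of the call within its molecule
  off <- (calls$pos - calls$start) %% L
  trimmed <- off < end_trim | off >= calls$mol_len - end_trim
  calls[, status := ifelse(trimmed, "end_trimmed", "pass")]
  calls[, `:=`(region = as.character(rmap$region[pos]),
               gene_strand = rmap$strand[pos])]
  ctx <- trinucleotide_context(g, calls$pos,
                               ifelse(is.na(calls$pyr_strand), "+",
                                      calls$pyr_strand))
  calls[, context := ctx$context]
  calls[, c("start", "mol_len") := NULL]
  setorder(calls, family, pos)
  calls[]
}

#' Filter nuclear-paralog (NUMT/NUPT) artifacts
#'
#' For each pass call, the consensus haplotype window of `k_flank` bases on
#' each side of the variant, including the alternate allele and any other
#' consensus deviations of the molecule inside the window, is searched
#' against the nuclear genome and its reverse complement. A match with at
#' most `max_mismatch` mismatches marks the call `numt`. Windows truncated by
#' the molecule end use the available bases with `max_mismatch` scaled
#' proportionally.
#'
#' @param calls output of [call_variants()].
#' @param cons the [build_consensuses()] result the calls came from.
#' @param g organellar [organelle_genome()].
#' @param nuclear a `DNAStringSet`, named character vector of nuclear
#'   sequences, or path to a nuclear FASTA.
#' @param k_flank flank length (bp) on each side of the variant.
#' @param max_mismatch mismatches tolerated in the nuclear match.
#' @return the calls table with `status` updated to `"numt"` where matched.
#' @export
numt_filter <- function(calls, cons, g, nuclear, k_flank = 20L,
                        max_mismatch = 0L) {
  if (!nrow(calls)) return(calls)
  if (is.character(nuclear) && length(nuclear) == 1L && file.exists(nuclear))
    nuclear <- Biostrings::readDNAStringSet(nuclear)
  if (!inherits(nuclear, "DNAStringSet"))
    nuclear <- Biostrings::DNAStringSet(nuclear)
  b <- genome_bases(g)
  L <- g$length
  cd <- cons$cdevs[!(type == "M" & alt == "N")]
  mol <- cons$consensus
  status <- calls$status
  for (i in which(calls$status == "pass")) {
    fam <- calls$family[i]
    mrow <- mol[family == fam]
    mstart <- mrow$start; mlen <- mrow$len
    off <- (calls$pos[i] - mstart) %% L
    alt_len <- if (calls$type[i] %in% c("SNV")) 1L else
      max(1L, nchar(calls$alt[i]), nchar(calls$ref[i]))
    lo <- max(0L, off - k_flank)
    hi <- min(mlen - 1L, off + alt_len - 1L + k_flank)
    win_pos <- fold_pos(mstart + lo:hi, L)
    s <- b[win_pos]
    ## apply this molecule's consensus deviations inside the window
    dd <- cd[family == fam & pos %in% win_pos]
    if (nrow(dd)) {
      o <- match(dd$pos, win_pos)
      for (j in order(o, decreasing = TRUE)) {
        if (dd$type[j] == "M") s[o[j]] <- dd$alt[j]
        else if (dd$type[j] == "D")
          s <- s[-(o[j]:min(length(s), o[j] + dd$len[j] - 1L))]
        else s <- append(s, strsplit(dd$alt[j], "")[[1]], after = o[j])
      }
    }
    pat <- paste(s, collapse = "")
    ## proportional mismatch budget for truncated windows
    full <- 2L * k_flank + alt_len
    mm <- floor(max_mismatch * nchar(pat) / full)
    hit <- sum(Biostrings::vcountPattern(pat, nuclear, max.mismatch = mm)) +
      sum(Biostrings::vcountPattern(revcomp(pat), nuclear, max.mismatch = mm))
    if (hit > 0) status[i] <- "numt"
  }
  calls$status <- status
  calls
}

#' Duplex coverage profile
#'
#' Per-position count of pass-filter consensus molecules whose consensus base
#' at that position is callable: uncallable N positions, deleted bases, and
#' the distrusted `end_trim` bases at each molecule end (where calls are also
#' filtered) are excluded from the depth, so numerator and denominator cover
#' the same territory.
#'
#' @param cons [build_consensuses()] output.
#' @param genome_length genome length in bp.
#' @param end_trim bp excluded at each molecule end (match the value given
#'   to [call_variants()]).
#' @return list with `depth` (integer vector) and `total` (total duplex
#'   consensus bases, the frequency denominator).
#' @export
coverage_profile <- function(cons, genome_length, end_trim = 10L) {
  pass <- cons$consensus[status == "pass"]
  L <- genome_length
  depth <- interval_coverage(fold_pos(pass$start + end_trim, L),
                             pass$len - 2L * end_trim, L)
  cd <- cons$cdevs
  if (nrow(cd)) {
    cd <- merge(cd, cons$consensus[, .(family, mstart = start, mlen = len)],
                by = "family")
    off <- (cd$pos - cd$mstart) %% L
    cd <- cd[off >= end_trim & off < mlen - end_trim]
  }
  sub_n <- cd[type == "M" & alt == "N", pos]
  if (length(sub_n)) depth <- depth - tabulate(sub_n, nbins = L)
  del <- cd[type == "D"]
  if (nrow(del)) {
    delpos <- unlist(lapply(seq_len(nrow(del)), function(i)
      fold_pos(del$pos[i]:(del$pos[i] + del$len[i] - 1L), L)))
    depth <- depth - tabulate(delpos, nbins = L)
  }
  depth[depth < 0L] <- 0L
  list(depth = depth, total = sum(as.numeric(depth)))
}

#' Variant frequency per duplex consensus base
#'
#' The headline frequency: number of pass-filter calls of the requested type
#' divided by total duplex consensus coverage.
#'
#' @param calls calls table.
#' @param coverage a [coverage_profile()] result (or total coverage as a
#'   single number).
#' @param type `"SNV"`, `"indel"` (insertions + deletions) or
#'   `"dinucleotide"`.
#' @return frequency per molecule-base.
#' @export
variant_frequency <- function(calls, coverage, type = "SNV") {
  total <- if (is.list(coverage)) coverage$total else as.numeric(coverage)
  if (total <= 0) stop("undefined frequency: zero duplex coverage")
  n <- if (type == "indel")
    sum(calls$status == "pass" & calls$type %in% c("insertion", "deletion"))
  else sum(calls$status == "pass" & calls$type == type)
  n / total
}
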