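## Synthetic circular organellar genomes with annotated features and planted
## repeat pairs. Everything downstream is validated against the truth these
## generators record.

## default gene lengths per region class, loosely matching organellar gene
## architecture (bp)
GENE_LEN_DEFAULTS <- c(CDS = 900L, intron = 600L, rRNA = 1500L, tRNA = 75L)

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Simulate a circular organellar genome with genes and repeat pairs
#'
#' Generates a random circular sequence, places non-overlapping gene features
#' of the four region classes on random strands, and plants dispersed repeat
#' pairs. The second copy of each repeat differs from the first at exactly
#' `round((1 - identity/100) * length)` positions; inverted pairs carry the
#' reverse complement.
#'
#' @param length genome length in bp.
#' @param n_genes named integer vector, e.g. `c(CDS = 4, intron = 1,
#'   rRNA = 2, tRNA = 6)`.
#' @param repeat_specs list of `list(length =, identity =, orientation =)`
#'   (orientation `"direct"` or `"inverted"`); optional `pos1`/`pos2` pin the
#'   copy start coordinates (e.g. to guarantee spacing), otherwise placement
#'   is random.
#' @param gene_lengths named vector of per-class gene lengths (bp).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param margin bp kept feature/repeat-free at the origin and between
#'   placements.
#' @return list with `genome`, `features`, `repeats`.
#' @export
simulate_genome <- function(length, n_genes = c(CDS = 4, intron = 1, rRNA = 2, tRNA = 6),
                            repeat_specs = list(),
                            gene_lengths = GENE_LEN_DEFAULTS,
                            seed = NULL, margin = 50L) {
  if (!is.null(seed)) set.seed(seed)
  seq_chars <- sample(BASES, length, replace = TRUE)

  ## greedy non-overlapping placement over 1..length, avoiding the origin
  occupied <- rep(FALSE, length)
  occupied[c(seq_len(min(margin, length)),
             seq(max(1L, length - margin + 1L), length))] <- TRUE
  place <- function(w) {
    for (try in 1:2000) {
      s <- sample.int(length - w, 1L)
      idx <- s:(s + w - 1L)
      if (!any(occupied[idx])) {
        occupied[idx] <<- TRUE
        ## margin gap around the placement
        lo <- max(1L, s - margin); hi <- min(length, s + w - 1L + margin)
        occupied[lo:hi] <<- TRUE
        return(s)
      }
    }
    stop("cannot place a ", w, "-bp element without overlap; genome too full")
  }

  ## repeats first (they are the largest constraints): copy1 is part of the
  ## random sequence; copy2 overwrites another placement
  rp_rows <- list()
  for (i in seq_along(repeat_specs)) {
    spec <- repeat_specs[[i]]
    w <- as.integer(spec$length)
    if (!is.null(spec$pos1)) {
      s1 <- as.integer(spec$pos1); s2 <- as.integer(spec$pos2)
      for (s0 in c(s1, s2)) {
        idx <- s0:(s0 + w - 1L)
        if (any(occupied[idx])) stop("pinned repeat copy overlaps a placement")
        occupied[pmax(1L, s0 - margin):pmin(length, s0 + w - 1L + margin)] <- TRUE
      }
    } else {
      s1 <- place(w); s2 <- place(w)
    }
    if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
    copy1 <- seq_chars[s1:(s1 + w - 1L)]
    n_mm <- round((1 - spec$identity / 100) * w)
    copy2 <- copy1
    if (n_mm > 0) {
      at <- sample.int(w, n_mm)
      copy2[at] <- vapply(copy2[at], function(b) sample(setdiff(BASES, b), 1L),
                          character(1))
    }
    if (identical(spec$orientation, "inverted"))
      copy2 <- rev(COMPLEMENT[copy2])
    seq_chars[s2:(s2 + w - 1L)] <- copy2
    rp_rows[[i]] <- data.table(
      name = if (!is.null(spec$name)) spec$name else paste0("R", i),
      start1 = s1, end1 = s1 + w - 1L,
      start2 = if (identical(spec$orientation, "inverted")) s2 + w - 1L else s2,
      end2 = if (identical(spec$orientation, "inverted")) s2 else s2 + w - 1L,
      percent_identity = spec$identity)
  }
  repeats <- if (length(rp_rows)) {
    r <- rbindlist(rp_rows)
    repeat_pairs(r$name, r$start1, r$end1, r$start2, r$end2, r$percent_identity)
  } else {
    repeat_pairs(character(), integer(), integer(), integer(), integer(), numeric())
  }

  ## genes
  feat_rows <- list()
  k <- 0L
  for (cls in names(n_genes)) {
    for (j in seq_len(n_genes[[cls]])) {
      w <- as.integer(gene_lengths[[cls]])
      s <- place(w)
      k <- k + 1L
      feat_rows[[k]] <- data.table(name = sprintf("%s_%d", cls, j),
                                   region_class = cls, start = s,
                                   end = s + w - 1L,
                                   strand = sample(c("+", "-"), 1L))
    }
  }
  features <- if (k) {
    f <- rbindlist(feat_rows)
    gene_features(f$name, f$region_class, f$start, f$end, f$strand)
  } else gene_features(character(), character(), integer(), integer(), character())

  g <- organelle_genome("synthetic_organelle", paste(seq_chars, collapse = ""))
  list(genome = g, features = features, repeats = repeats)
}

#' Build a synthetic nuclear genome carrying an organellar paralog (NUMT)
#'
#' Embeds a copy of an organellar genome segment into random nuclear sequence
#' and plants paralogous variants in the copy. Duplex reads originating from
#' such nuclear insertions mimic low-frequency organellar variants; the
#' variant filter must remove them.
#'
#' @param g organellar [organelle_genome()].
#' @param segment_start,segment_end organellar interval copied into the
#'   nuclear genome (1-based inclusive, non-wrapping).
#' @param n_paralog_variants number of substitutions distinguishing the
#'   nuclear paralog from the organellar original.
#' @param flank_length random nuclear sequence added on each side.
#' @param seed RNG seed.
#' @return list with `nuclear` (named character vector, one sequence, ready
#'   for [write_genome_fasta()]), and `paralog_variants` (data.table with
#'   organellar `pos`, `ref`, `alt`).
#' @export
simulate_numt_fixture <- function(g, segment_start, segment_end,
                                  n_paralog_variants = 5L,
                                  flank_length = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (segment_end > g$length || segment_start < 1L || segment_start > segment_end)
    stop("invalid segment")
  seg <- strsplit(substr(g$sequence, segment_start, segment_end), "")[[1]]
  ## keep paralog variants away from segment edges so haplotype windows of
  ## paralog-derived calls lie inside the insertion
  w <- length(seg)
  eligible <- seq(50L, w - 50L)
  at <- sort(sample(eligible, n_paralog_variants))
  ref <- seg[at]
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
  seg[at] <- alt
  nuclear <- paste0(random_dna(flank_length), paste(seg, collapse = ""),
                    random_dna(flank_length))
  list(nuclear = setNames(nuclear, "nuclear_chr_synthetic"),
       paralog_variants = data.table(pos = segment_start + at - 1L,
                                     ref = ref, alt = alt))
}

#' Simulate duplex families contaminated by a nuclear paralog
#'
#' Generates duplex read families whose molecules derive from the nuclear
#' paralog of [simulate_numt_fixture()] but are (mis)mapped at the
#' homologous organellar coordinates: every read of both strand-families
#' carries the paralogous variants falling inside its molecule, mimicking
#' genuine low-frequency organellar mutations.
#'
#' @param g organellar genome.
#' @param fixture result of [simulate_numt_fixture()].
#' @param segment_start,segment_end organellar interval of the paralog.
#' @param n_molecules contaminant molecules.
#' @param reads_per_strand,insert_length as in [simulate_duplex_families()].
#' @param tag_prefix distinguishes contaminant tags from genuine ones.
#' @param seed RNG seed.
#' @return list with `molecules`, `reads`, `devs` and `truth` (the planted
#'   paralog variants per molecule) in the duplex table layout.
#' @export
simulate_numt_contamination <- function(g, fixture, segment_start, segment_end,
                                        n_molecules, reads_per_strand = 3L,
                                        insert_length = 300L,
                                        tag_prefix = "NUMT", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ## molecules fully inside the paralog segment
  span <- segment_end - segment_start + 1L - insert_length
  if (span < 1L) stop("segment shorter than insert_length")
  starts <- segment_start + sample.int(span, n_molecules, replace = TRUE) - 1L
  mol <- data.table(molecule = seq_len(n_molecules),
                    tag = sprintf("%s%06d", tag_prefix, seq_len(n_molecules)),
                    start = starts,
                    len = rep(as.integer(insert_length), n_molecules))
  pv <- fixture$paralog_variants
  ev <- rbindlist(lapply(seq_len(n_molecules), function(i) {
    inside <- pv[pos >= starts[i] & pos <= starts[i] + insert_length - 1L]
    if (!nrow(inside)) return(NULL)
    data.table(molecule = i, pos = inside$pos, type = "SNV",
               class = NA_character_, ref = inside$ref, alt = inside$alt,
               pyr_strand = NA_character_, len = 1L)
  }))
  n_rpm <- 2L * reads_per_strand
  reads <- data.table(
    read_id = seq_len(n_molecules * n_rpm),
    molecule = rep(mol$molecule, each = n_rpm),
    tag = rep(mol$tag, each = n_rpm),
    strand_fam = rep(rep(c("A", "B"), each = reads_per_strand), n_molecules),
    start = rep(mol$start, each = n_rpm),
    len = rep(mol$len, each = n_rpm))
  devs <- if (nrow(ev)) {
    tmp <- merge(reads[, .(read_id, molecule)],
                 ev[, .(molecule, pos, alt)], by = "molecule",
                 allow.cartesian = TRUE)
    tmp[, .(read_id, pos, type = "M", alt, len = 1L)]
  } else data.table(read_id = integer(), pos = integer(), type = character(),
                    alt = character(), len = integer())
  list(molecules = mol, reads = reads, devs = devs, truth = ev)
}
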