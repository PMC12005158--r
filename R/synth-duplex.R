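## Duplex-sequencing library simulator. Each source molecule yields two
## strand-families (A/B) sharing a molecular tag; planted mutations sit on
## every read of both families, sequencing errors are i.i.d. per read.
##
## Reads are carried in a coordinate-anchored sparse form: an aligned interval
## on the reference plus a table of deviations (type M = mismatch, I =
## insertion after pos, D = deletion starting at pos). This is the package's
## aligned-read container; FASTQ emission/placement converts to and from it.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Mutation model for the duplex simulator
#'
#' Rates are per site per molecule, keyed by the six pyrimidine substitution
#' classes. `context_multiplier` scales a class's rate by the 5' and 3'
#' neighbors read on the strand of the pyrimidine. `template_strand_bias`
#' multiplies the rate when the mutated pyrimidine lies on the template
#' strand of a single-strand genic site (1 = symmetric).
#'
#' @param base_rate_per_class named numeric, names among
#'   `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @param context_multiplier `NULL` or data.frame with columns `class`,
#'   `five`, `three`, `multiplier` (unlisted combinations default to 1).
#' @param template_strand_bias nonnegative factor `b`.
#' @param indel_rate per-site probability of a 1-bp insertion or deletion.
#' @param dinucleotide_rate per-site probability of a simultaneous adjacent
#'   double substitution.
#' @return a `mutation_model` list.
#' @export
mutation_model <- function(base_rate_per_class = setNames(numeric(6), SUB_CLASSES),
                           context_multiplier = NULL,
                           template_strand_bias = 1,
                           indel_rate = 0, dinucleotide_rate = 0) {
  rates <- setNames(numeric(6), SUB_CLASSES)
  rates[names(base_rate_per_class)] <- base_rate_per_class
  if (any(rates < 0 | rates > 1) || indel_rate < 0 || indel_rate > 1 ||
      dinucleotide_rate < 0 || dinucleotide_rate > 1)
    stop("rates must be probabilities in [0, 1]")
  if (template_strand_bias < 0) stop("template_strand_bias must be >= 0")
  structure(list(base_rate_per_class = rates,
                 context_multiplier = context_multiplier,
                 template_strand_bias = template_strand_bias,
                 indel_rate = indel_rate,
                 dinucleotide_rate = dinucleotide_rate),
            class = "mutation_model")
}

## per-base coverage counts of a set of (possibly origin-wrapping) intervals
interval_coverage <- function(start, len, L) {
  depth <- integer(L)
  if (!length(start)) return(depth)
  end <- start + len - 1L
  wraps <- end > L
  d <- integer(L + 1L)
  s1 <- start; e1 <- pmin(end, L)
  add <- function(s, e) {
    t1 <- tabulate(s, nbins = L + 1L)
    t2 <- tabulate(e + 1L, nbins = L + 1L)
    d <<- d + t1 - t2
  }
  add(s1, e1)
  if (any(wraps)) add(rep(1L, sum(wraps)), fold_pos(end[wraps], L))
  cumsum(d)[seq_len(L)]
}

## per-position planting weights for one substitution class.
## Returns numeric(L): 0 at ineligible positions.
class_site_weights <- function(b, cls, model, rmap, L) {
  pyr <- substr(cls, 1, 1)                      # C or T
  on_plus <- b == pyr
  on_minus <- b == COMPLEMENT[[pyr]]
  w <- numeric(L)
  pyr_strand <- rep(NA_character_, L)
  pyr_strand[on_plus] <- "+"; pyr_strand[on_minus] <- "-"
  eligible <- on_plus | on_minus
  w[eligible] <- model$base_rate_per_class[[cls]]
  cm <- model$context_multiplier
  if (!is.null(cm) || model$template_strand_bias != 1) {
    idx <- which(eligible)
    if (!is.null(cm)) {
      five <- ifelse(on_plus[idx], b[fold_pos(idx - 1L, L)],
                     COMPLEMENT[b[fold_pos(idx + 1L, L)]])
      three <- ifelse(on_plus[idx], b[fold_pos(idx + 1L, L)],
                      COMPLEMENT[b[fold_pos(idx - 1L, L)]])
      cm <- as.data.frame(cm)
      key <- paste(cls, five, three)
      mk <- setNames(cm$multiplier, paste(cm$class, cm$five, cm$three))
      mult <- mk[key]
      mult[is.na(mult)] <- 1
      w[idx] <- w[idx] * mult
    }
    if (model$template_strand_bias != 1) {
      gs <- rmap$strand[idx]
      ## template strand is the opposite of the gene's sense strand: the
      ## pyrimidine sits on the template iff its strand differs from the
      ## gene strand. Dual-strand ("*") and intergenic sites get no bias.
      on_template <- !is.na(gs) & gs %in% c("+", "-") & gs != pyr_strand[idx]
      w[idx][on_template] <- w[idx][on_template] * model$template_strand_bias
    }
  }
  w
}

## draw Poisson-thinned per-molecule-site events given per-position weights.
## Returns data.table(molecule, pos). Exact in the sparse-mutation regime.
plant_events <- function(w, mol_start, mol_len, L, max_offset_back = 0L) {
  cw <- c(0, cumsum(w))
  S <- function(p) cw[p + 1L]          # prefix sum over 1..p
  end <- mol_start + mol_len - 1L
  wraps <- end > L
  W <- S(pmin(end, L)) - S(mol_start - 1L)
  if (any(wraps)) W[wraps] <- W[wraps] + S(fold_pos(end[wraps], L))
  lam <- sum(W)
  if (lam <= 0) return(data.table(molecule = integer(), pos = integer()))
  K <- rpois(1L, lam)
  if (K == 0L) return(data.table(molecule = integer(), pos = integer()))
  mols <- sample.int(length(W), K, replace = TRUE, prob = W)
  pos <- integer(K)
  for (i in seq_len(K)) {
    m <- mols[i]
    p_idx <- fold_pos(mol_start[m]:(mol_start[m] + mol_len[m] - 1L -
                                      max_offset_back), L)
    wi <- w[p_idx]
    pos[i] <- p_idx[sample.int(length(p_idx), 1L, prob = wi + 1e-300)]
  }
  unique(data.table(molecule = mols, pos = pos))
}

#' Simulate tagged duplex read families with planted mutations
#'
#' Molecules are drawn uniformly on the circular genome; each produces two
#' strand-families of `reads_per_strand` reads sharing a unique tag. Planted
#' SNVs, 1-bp indels and dinucleotide mutations appear on all reads of both
#' families; sequencing errors are independent substitutions per read.
#'
#' @param g [organelle_genome()].
#' @param features feature table (for the template-strand bias).
#' @param model a [mutation_model()].
#' @param n_molecules number of source molecules.
#' @param reads_per_strand reads per strand-family (>= 1).
#' @param insert_length molecule length in bp (< genome length).
#' @param seq_error per-read-base substitution error probability.
#' @param seed RNG seed.
#' @return list with `molecules`, `reads`, `devs` (read-level deviations) and
#'   `truth` (planted events: molecule, pos, type, class, ref, alt,
#'   pyr_strand).
#' @export
simulate_duplex_families <- function(g, features, model = mutation_model(),
                                     n_molecules, reads_per_strand = 3L,
                                     insert_length = 300L, seq_error = 0,
                                     seed = NULL) {
  if (reads_per_strand < 1L) stop("reads_per_strand must be >= 1")
  if (insert_length >= g$length) stop("insert_length must be < genome length")
  if (!is.null(seed)) set.seed(seed)
  L <- g$length
  b <- genome_bases(g)
  rmap <- region_map(features, L)

  mol <- data.table(molecule = seq_len(n_molecules),
                    tag = sprintf("T%07d", seq_len(n_molecules)),
                    start = sample.int(L, n_molecules, replace = TRUE),
                    len = rep(as.integer(insert_length), n_molecules))

  truth_list <- list()
  ## SNVs per class
  for (cls in SUB_CLASSES) {
    if (model$base_rate_per_class[[cls]] <= 0) next
    w <- class_site_weights(b, cls, model, rmap, L)
    ev <- plant_events(w, mol$start, mol$len, L)
    if (nrow(ev)) {
      ref <- b[ev$pos]
      pyr <- substr(cls, 1, 1); mut <- substr(cls, 3, 3)
      on_plus <- ref == pyr
      alt <- ifelse(on_plus, mut, COMPLEMENT[[mut]])
      truth_list[[cls]] <- data.table(
        molecule = ev$molecule, pos = ev$pos, type = "SNV", class = cls,
        ref = ref, alt = alt, pyr_strand = ifelse(on_plus, "+", "-"),
        len = 1L)
    }
  }
  ## dinucleotide mutations (simultaneous adjacent double substitutions)
  if (model$dinucleotide_rate > 0) {
    w <- rep(model$dinucleotide_rate, L)
    ev <- plant_events(w, mol$start, mol$len, L, max_offset_back = 1L)
    if (nrow(ev)) {
      p2 <- fold_pos(ev$pos + 1L, L)
      ref1 <- b[ev$pos]; ref2 <- b[p2]
      alt1 <- vapply(ref1, function(x) sample(setdiff(BASES, x), 1L), character(1))
      alt2 <- vapply(ref2, function(x) sample(setdiff(BASES, x), 1L), character(1))
      truth_list[["dinuc"]] <- data.table(
        molecule = rep(ev$molecule, 2L), pos = c(ev$pos, p2),
        type = "dinucleotide_part", class = NA_character_,
        ref = c(ref1, ref2), alt = c(alt1, alt2),
        pyr_strand = NA_character_, len = 1L)
    }
  }
  ## 1-bp indels
  if (model$indel_rate > 0) {
    w <- rep(model$indel_rate, L)
    ev <- plant_events(w, mol$start, mol$len, L)
    if (nrow(ev)) {
      is_ins <- runif(nrow(ev)) < 0.5
      truth_list[["indel"]] <- data.table(
        molecule = ev$molecule, pos = ev$pos,
        type = ifelse(is_ins, "insertion", "deletion"),
        class = NA_character_, ref = b[ev$pos],
        alt = ifelse(is_ins, sample(BASES, nrow(ev), replace = TRUE),
                     NA_character_),
        pyr_strand = NA_character_, len = 1L)
    }
  }
  truth <- if (length(truth_list)) rbindlist(truth_list) else
    data.table(molecule = integer(), pos = integer(), type = character(),
               class = character(), ref = character(), alt = character(),
               pyr_strand = character(), len = integer())
  ## drop colliding events at the same molecule-site (vanishingly rare in the
  ## sparse regime)
  truth <- unique(truth, by = c("molecule", "pos"))

  ## reads: 2 strand-families x reads_per_strand per molecule
  n_reads_per_mol <- 2L * reads_per_strand
  reads <- data.table(
    read_id = seq_len(n_molecules * n_reads_per_mol),
    molecule = rep(mol$molecule, each = n_reads_per_mol),
    tag = rep(mol$tag, each = n_reads_per_mol),
    strand_fam = rep(rep(c("A", "B"), each = reads_per_strand), n_molecules),
    start = rep(mol$start, each = n_reads_per_mol),
    len = rep(mol$len, each = n_reads_per_mol))

  ## deviations: planted events on every read of the molecule ...
  devs <- if (nrow(truth)) {
    tmp <- merge(reads[, .(read_id, molecule)],
                 truth[, .(molecule, pos, type, alt, len)],
                 by = "molecule", allow.cartesian = TRUE)
    tmp[, dtype := c(SNV = "M", dinucleotide_part = "M", insertion = "I",
                     deletion = "D")[type]]
    tmp[, .(read_id, pos, type = dtype, alt, len)]
  } else data.table(read_id = integer(), pos = integer(), type = character(),
                    alt = character(), len = integer())
  ## ... plus i.i.d. per-read substitution errors
  if (seq_error > 0) {
    total_bases <- as.numeric(nrow(reads)) * insert_length
    K <- rpois(1L, total_bases * seq_error)
    if (K > 0) {
      rid <- sample.int(nrow(reads), K, replace = TRUE)
      off <- sample.int(insert_length, K, replace = TRUE)
      pos <- fold_pos(reads$start[rid] + off - 1L, L)
      ref <- b[pos]
      alt <- BASES[(match(ref, BASES) - 1L + sample.int(3L, K, replace = TRUE)) %% 4L + 1L]
      err <- data.table(read_id = reads$read_id[rid], pos = pos, type = "M",
                        alt = alt, len = 1L)
      devs <- rbind(devs, err)
    }
  }
  ## a read-level error overrides a planted base on that read only
  devs <- unique(devs[rev(seq_len(nrow(devs)))], by = c("read_id", "pos"))
  truth[, type := sub("dinucleotide_part", "dinucleotide", type)]
  list(molecules = mol, reads = reads, devs = devs, truth = truth)
}

## --------------------------------------------------------------------------
## FASTQ materialization and exact placement (interface plumbing)
## --------------------------------------------------------------------------

## reconstruct one read's sequence from the reference and its deviations
materialize_read <- function(g, start, len, devs_row) {
  s <- strsplit(circ_substr(g, start, len), "")[[1]]
  if (nrow(devs_row)) {
    off <- ((devs_row$pos - start) %% g$length) + 1L
    ins <- list()
    for (i in order(off, decreasing = TRUE)) {
      o <- off[i]
      if (devs_row$type[i] == "M") s[o] <- devs_row$alt[i]
      else if (devs_row$type[i] == "D") s <- s[-(o:min(length(s), o + devs_row$len[i] - 1L))]
      else s <- append(s, strsplit(devs_row$alt[i], "")[[1]], after = o)
    }
  }
  paste(s, collapse = "")
}

#' Write duplex read families as FASTQ
#'
#' Read names carry `tag:strand_family:index` so families can be regrouped
#' after external processing. Constant quality (Q37) is emitted.
#'
#' @param sim output of [simulate_duplex_families()].
#' @param g the genome the reads were simulated from.
#' @param path output FASTQ path.
#' @export
write_duplex_fastq <- function(sim, g, path) {
  reads <- sim$reads
  devs <- split(sim$devs, by = "read_id", keep.by = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  empty <- sim$devs[0]
  for (i in seq_len(nrow(reads))) {
    d <- devs[[as.character(reads$read_id[i])]]
    if (is.null(d)) d <- empty
    sq <- materialize_read(g, reads$start[i], reads$len[i], d)
    writeLines(c(sprintf("@%s:%s:%d", reads$tag[i], reads$strand_fam[i], i),
                 sq, "+", strrep("F", nchar(sq))), con)
  }
  invisible(path)
}

#' Read duplex FASTQ and place reads on the reference by exact match
#'
#' The placer is exact-match only and therefore intended for error-free
#' synthetic data; externally aligned SAM-like records should be converted to
#' the reads/devs tables directly for real data.
#'
#' @param path FASTQ with `tag:strand_family:index` read names.
#' @param g reference [organelle_genome()].
#' @return list with `reads` and `devs` tables as in
#'   [simulate_duplex_families()].
#' @export
read_duplex_fastq <- function(path, g) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ")
  names_ <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  seqs <- lines[seq(2, length(lines), by = 4)]
  parts <- strsplit(names_, ":", fixed = TRUE)
  ## exact placement against the doubled sequence (circular origin)
  subject <- Biostrings::DNAString(paste0(g$sequence, g$sequence))
  starts <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    m <- Biostrings::matchPattern(seqs[i], subject)
    st <- Biostrings::start(m)
    st <- st[st <= g$length]
    if (!length(st)) stop("read ", names_[i], " not exactly placeable")
    starts[i] <- st[1]
  }
  list(reads = data.table(read_id = seq_along(seqs),
                          molecule = NA_integer_,
                          tag = vapply(parts, `[`, character(1), 1),
                          strand_fam = vapply(parts, `[`, character(1), 2),
                          start = starts, len = nchar(seqs)),
       devs = data.table(read_id = integer(), pos = integer(),
                         type = character(), alt = character(),
                         len = integer()))
}

#' Combine two duplex read sets
#'
#' Concatenates the molecules/reads/devs/truth tables of two simulated read
#' sets (e.g. genuine families plus nuclear-paralog contamination), with
#' read and molecule identifiers re-offset so they stay unique. Tags must
#' already be distinct between the sets.
#'
#' @param a,b lists with `molecules`, `reads`, `devs`, `truth`.
#' @return combined list in the same layout.
#' @export
combine_duplex_sets <- function(a, b) {
  off_mol <- max(a$molecules$molecule)
  off_read <- max(a$reads$read_id)
  if (any(b$molecules$tag %in% a$molecules$tag))
    stop("tag collision between the two read sets")
  b$molecules <- copy(b$molecules)[, molecule := molecule + off_mol]
  b$reads <- copy(b$reads)[, `:=`(read_id = read_id + off_read,
                                  molecule = molecule + off_mol)]
  b$devs <- copy(b$devs)[, read_id := read_id + off_read]
  b$truth <- copy(b$truth)
  if (nrow(b$truth)) b$truth[, molecule := molecule + off_mol]
  list(molecules = rbind(a$molecules, b$molecules),
       reads = rbind(a$reads, b$reads),
       devs = rbind(a$devs, b$devs),
       truth = rbind(a$truth, b$truth, fill = TRUE))
}
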