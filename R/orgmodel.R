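#' @import data.table
#' @importFrom stats rpois rbinom runif rlnorm setNames aggregate
#' @importFrom utils head tail read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string vector
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct an organellar genome object
#'
#' A circular (by default) reference sequence against which all mutation and
#' recombination frequencies are computed.
#'
#' @param id genome identifier (e.g. `"mt"` or `"cp"`).
#' @param sequence DNA string restricted to A/C/G/T/N.
#' @param circular logical; organellar genomes map as circles.
#' @return an object of class `organelle_genome` with fields `id`, `sequence`,
#'   `circular` and `length`.
#' @export
organelle_genome <- function(id, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) stop("genome sequence restricted to A/C/G/T/N")
  structure(
    list(id = id, sequence = sequence, circular = circular,
         length = nchar(sequence)),
    class = "organelle_genome"
  )
}

#' @export
print.organelle_genome <- function(x, ...) {
  cat(sprintf("<organelle_genome '%s': %s bp, %s>\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

## 1-based circular position folding: maps any integer onto 1..L
fold_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

## character vector of the genome's bases (cached on the object by callers
## that need repeated access)
genome_bases <- function(g) strsplit(g$sequence, "", fixed = TRUE)[[1]]

## substring with circular wraparound; start may be any integer, len >= 0
circ_substr <- function(g, start, len) {
  L <- g$length
  start <- fold_pos(start, L)
  end <- start + len - 1L
  if (end <= L) return(substr(g$sequence, start, end))
  if (!g$circular) stop("interval exceeds linear genome")
  n_wraps <- (end - 1L) %/% L
  paste0(substr(g$sequence, start, L),
         strrep(g$sequence, max(0L, n_wraps - 1L)),
         substr(g$sequence, 1L, fold_pos(end, L)))
}

#' Build a gene-feature table
#'
#' @param name feature names.
#' @param region_class one of `"CDS"`, `"intron"`, `"rRNA"`, `"tRNA"`.
#' @param start,end 1-based inclusive coordinates (`start <= end`; features
#'   spanning the circular origin are represented as two rows sharing `name`).
#' @param strand `"+"` or `"-"`: the strand carrying the sense (non-template)
#'   sequence of the gene.
#' @return a `data.table` of features.
#' @export
gene_features <- function(name, region_class, start, end, strand) {
  region_class <- as.character(region_class)
  bad <- setdiff(unique(region_class), c("CDS", "intron", "rRNA", "tRNA"))
  if (length(bad)) stop("unknown region_class: ", paste(bad, collapse = ", "))
  if (any(start > end)) stop("feature start > end (split origin-spanning features)")
  if (any(start < 1L)) stop("feature start < 1")
  data.table(name = as.character(name), region_class = region_class,
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand))
}

REGION_LEVELS <- c("intergenic", "CDS", "intron", "rRNA", "tRNA")
## precedence for overlap resolution: higher wins
REGION_PRECEDENCE <- c(intron = 1L, CDS = 2L, rRNA = 3L, tRNA = 4L)

#' Per-position region and strand maps for a genome
#'
#' Assigns every genome position to exactly one region class (overlaps
#' resolved by precedence tRNA > rRNA > CDS > intron; unannotated positions
#' are intergenic) and records the gene strand. Positions covered by features
#' on both strands get strand `"*"` and are excluded from strand-asymmetry
#' denominators.
#'
#' @param features a feature table from [gene_features()].
#' @param genome_length genome length in bp.
#' @return list with `region` (factor vector, length `genome_length`) and
#'   `strand` (character vector: `"+"`, `"-"`, `"*"` or `NA` for intergenic).
#' @export
region_map <- function(features, genome_length) {
  region <- factor(rep("intergenic", genome_length), levels = REGION_LEVELS)
  strand <- rep(NA_character_, genome_length)
  prec <- rep(0L, genome_length)
  plus <- rep(FALSE, genome_length)
  minus <- rep(FALSE, genome_length)
  if (!is.null(features) && nrow(features)) {
    if (any(features$end > genome_length)) stop("feature exceeds genome length")
    for (i in seq_len(nrow(features))) {
      idx <- features$start[i]:features$end[i]
      p <- REGION_PRECEDENCE[[features$region_class[i]]]
      take <- p > prec[idx]
      region[idx[take]] <- features$region_class[i]
      prec[idx[take]] <- p
      if (features$strand[i] == "+") plus[idx] <- TRUE else minus[idx] <- TRUE
    }
    genic <- prec > 0L
    strand[genic & plus & !minus] <- "+"
    strand[genic & minus & !plus] <- "-"
    strand[genic & plus & minus] <- "*"
  }
  list(region = region, strand = strand)
}

#' Region class of individual sites
#'
#' @param features feature table.
#' @param pos integer vector of 1-based positions.
#' @param genome_length genome length in bp.
#' @return data.table with `pos`, `region`, `strand`.
#' @export
site_region <- function(features, pos, genome_length) {
  rm_ <- region_map(features, genome_length)
  data.table(pos = as.integer(pos),
             region = as.character(rm_$region[pos]),
             strand = rm_$strand[pos])
}

#' Build a repeat-pair catalog
#'
#' Each row is one pair of dispersed repeat copies. Inverted pairs are those
#' whose second copy is printed with descending coordinates in the field's
#' tables; internally both copies are stored as ascending intervals plus an
#' orientation flag.
#'
#' @param name repeat names.
#' @param start1,end1 copy 1 interval (1-based inclusive, ascending).
#' @param start2,end2 copy 2 interval as printed (descending for inverted).
#' @param percent_identity percent identity between the copies (0, 100].
#' @return data.table with ascending `start2 <= end2` and an `orientation`
#'   column (`"direct"` / `"inverted"`), plus the derived `length`.
#' @export
repeat_pairs <- function(name, start1, end1, start2, end2, percent_identity) {
  if (any(start1 > end1)) stop("malformed repeat record: copy1 start > end")
  orientation <- ifelse(start2 > end2, "inverted", "direct")
  s2 <- pmin(start2, end2); e2 <- pmax(start2, end2)
  if (any(percent_identity <= 0 | percent_identity > 100))
    stop("percent_identity must be in (0, 100]")
  data.table(name = as.character(name),
             start1 = as.integer(start1), end1 = as.integer(end1),
             start2 = as.integer(s2), end2 = as.integer(e2),
             orientation = orientation,
             percent_identity = as.numeric(percent_identity),
             length = as.integer(end1 - start1 + 1L))
}

#' Repeat length from copy-1 coordinates
#'
#' Validates the 1-based inclusive convention: `end - start + 1`.
#'
#' @param rp a repeat catalog ([repeat_pairs()]) or one row of it.
#' @return integer vector of lengths.
#' @export
repeat_length <- function(rp) {
  if (any(rp$start1 > rp$end1)) stop("malformed repeat record: copy1 start > end")
  as.integer(rp$end1 - rp$start1 + 1L)
}

#' Trinucleotide context at a genome position
#'
#' Returns the three bases centered on `pos`, with circular wraparound, on the
#' requested strand; the minus-strand context is the reverse complement of the
#' plus-strand context at the same position. Contexts containing N are flagged
#' unusable (`usable = FALSE`) and are excluded from frequency denominators.
#'
#' @param g an [organelle_genome()].
#' @param pos integer vector of 1-based positions.
#' @param strand `"+"` or `"-"` (recycled).
#' @return data.table with `pos`, `strand`, `context`, `usable`.
#' @export
trinucleotide_context <- function(g, pos, strand = "+") {
  if (any(pos < 1L | pos > g$length)) stop("position outside genome")
  b <- genome_bases(g)
  L <- g$length
  ctx <- paste0(b[fold_pos(pos - 1L, L)], b[pos], b[fold_pos(pos + 1L, L)])
  strand <- rep_len(strand, length(pos))
  neg <- strand == "-"
  if (any(neg)) ctx[neg] <- revcomp(ctx[neg])
  data.table(pos = as.integer(pos), strand = strand, context = ctx,
             usable = !grepl("N", ctx, fixed = TRUE))
}

## --------------------------------------------------------------------------
## I/O: FASTA, GFF3 subset, repeat-catalog TSV
## --------------------------------------------------------------------------

#' Read a genome from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @param circular logical, stored on the returned genome.
#' @return an [organelle_genome()].
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  organelle_genome(id = sub("\\s.*$", "", names(ss)[1]),
                   sequence = as.character(ss[[1]]), circular = circular)
}

#' Write a genome (or named sequences) to FASTA
#'
#' @param x an `organelle_genome` or a named character vector of sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(x, path) {
  if (inherits(x, "organelle_genome")) x <- setNames(x$sequence, x$id)
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Only feature types CDS, intron, rRNA and tRNA are consumed; other types are
#' ignored (their count is reported via attribute `n_ignored`). The GFF strand
#' is taken as the sense (non-template) strand of the gene.
#'
#' @param path GFF3 file.
#' @return a feature table as from [gene_features()].
#' @export
read_features_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
    df <- data.table(
      name = if (!is.null(gr$ID)) as.character(gr$ID) else as.character(seq_len(nrow(gr))),
      type = as.character(gr$type),
      start = gr$start, end = gr$end,
      strand = as.character(gr$strand))
  } else {
    raw <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    df <- data.table(name = sub("^.*ID=([^;]+).*$", "\\1", raw$V9),
                     type = raw$V3, start = raw$V4, end = raw$V5,
                     strand = raw$V7)
  }
  keep <- df$type %in% c("CDS", "intron", "rRNA", "tRNA")
  out <- gene_features(df$name[keep], df$type[keep], df$start[keep],
                       df$end[keep], df$strand[keep])
  attr(out, "n_ignored") <- sum(!keep)
  out
}

#' Write gene features as GFF3
#'
#' @param features feature table; @param genome_id seqid column value;
#' @param path output path.
#' @export
write_features_gff3 <- function(features, genome_id, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\torgvar\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     genome_id, features$region_class, features$start,
                     features$end, features$strand, features$name))
  writeLines(lines, path)
  invisible(path)
}

## parse one printed coordinate token like "19,682-20,237" (hyphen or en dash)
parse_coord_pair <- function(x) {
  x <- gsub(",", "", x)
  parts <- strsplit(x, "[-–]")[[1]]
  if (length(parts) != 2L) stop("cannot parse coordinate pair: ", x)
  as.integer(parts)
}

#' Read a repeat catalog TSV
#'
#' Tab-separated with columns `name`, `copy1`, `copy2`, `percent_id`,
#' `length`; coordinate columns use the printed `start-end` form (commas and
#' en dashes allowed). Descending `copy2` coordinates denote an inverted pair.
#' The `length` column is validated against copy-1 coordinates.
#'
#' @param path TSV path.
#' @return a repeat catalog as from [repeat_pairs()].
#' @export
read_repeat_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    return(repeat_pairs(character(), integer(), integer(), integer(),
                        integer(), numeric()))
  c1 <- lapply(raw$copy1, parse_coord_pair)
  c2 <- lapply(raw$copy2, parse_coord_pair)
  rp <- repeat_pairs(raw$name,
                     vapply(c1, `[`, integer(1), 1), vapply(c1, `[`, integer(1), 2),
                     vapply(c2, `[`, integer(1), 1), vapply(c2, `[`, integer(1), 2),
                     raw$percent_id)
  if (!is.null(raw$length)) {
    bad <- which(as.integer(raw$length) != rp$length)
    if (length(bad))
      stop("length column inconsistent with copy1 coordinates in row(s): ",
           paste(rp$name[bad], collapse = ", "))
  }
  rp
}

#' Write a repeat catalog TSV
#'
#' Inverse of [read_repeat_table()]: inverted pairs are printed with
#' descending copy-2 coordinates.
#'
#' @param rp repeat catalog; @param path output path.
#' @export
write_repeat_table <- function(rp, path) {
  inv <- rp$orientation == "inverted"
  out <- data.frame(
    name = rp$name,
    copy1 = sprintf("%d-%d", rp$start1, rp$end1),
    copy2 = ifelse(inv, sprintf("%d-%d", rp$end2, rp$start2),
                   sprintf("%d-%d", rp$start2, rp$end2)),
    percent_id = rp$percent_identity,
    length = rp$length)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
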