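## Split-alignment classification of long reads and repeat-mediated
## recombination bookkeeping: per-read structure classes, breakpoint-to-repeat
## matching, per-repeat and genome-wide recombination frequencies, supported
## indel calls, and 1-kb coverage-ratio windows.

READ_CLASSES <- c("single_hit_clean", "single_hit_indel", "two_hit_inverted",
                  "two_hit_direct_deletion", "two_hit_direct_circular",
                  "multi_hit_excluded", "unmapped")

#' Build a local-hit table
#'
#' One row per local alignment of a read: 1-based inclusive intervals on the
#' read and on the genome, and the orientation.
#'
#' @param read_id read identifiers.
#' @param read_len read lengths (bp).
#' @param qstart,qend read interval (1-based inclusive).
#' @param tstart,tend genome interval (1-based inclusive, ascending).
#' @param strand `"+"` or `"-"`.
#' @param cigar optional CIGAR strings (for indel extraction).
#' @return data.table of hits.
#' @export
local_hits <- function(read_id, read_len, qstart, qend, tstart, tend, strand,
                       cigar = NA_character_) {
  if (any(qstart > qend) || any(tstart > tend)) stop("empty hit interval")
  data.table(read_id = as.character(read_id), read_len = as.integer(read_len),
             qstart = as.integer(qstart), qend = as.integer(qend),
             tstart = as.integer(tstart), tend = as.integer(tend),
             strand = as.character(strand), cigar = as.character(cigar))
}

#' Read minimap2 PAF alignments into a hit table
#'
#' Secondary alignments (`tp:A:S`) are dropped; 0-based half-open PAF
#' coordinates are converted to 1-based inclusive. If the reference was a
#' doubled circular genome, pass `fold_length` to map target coordinates back
#' onto the single copy.
#'
#' @param path PAF file (minimap2, ideally with `-c` for CIGARs).
#' @param fold_length genome length used to fold coordinates of an alignment
#'   against a doubled reference; `NULL` for linear references.
#' @return a hit table as from [local_hits()].
#' @export
read_paf <- function(path, fold_length = NULL) {
  lines <- readLines(path)
  if (!length(lines))
    return(local_hits(character(), integer(), integer(), integer(),
                      integer(), integer(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[`, character(1), i)
  tags <- vapply(fields, function(x) paste(x[-(1:12)], collapse = "\t"),
                 character(1))
  tp <- sub(".*tp:A:(.).*", "\\1", tags)
  tp[!grepl("tp:A:", tags)] <- "P"
  cg <- ifelse(grepl("cg:Z:", tags),
               sub(".*cg:Z:([^\t]+).*", "\\1", tags), NA_character_)
  keep <- tp != "S"
  ts <- as.integer(get(8))[keep] + 1L
  te <- as.integer(get(9))[keep]
  if (!is.null(fold_length)) {
    shift <- ifelse(ts > fold_length, fold_length, 0L)
    ts <- ts - shift; te <- te - shift
  }
  local_hits(get(1)[keep], as.integer(get(2))[keep],
             as.integer(get(3))[keep] + 1L, as.integer(get(4))[keep],
             ts, te, get(5)[keep], cg[keep])
}

#' Read BLAST tabular (outfmt 6) alignments into a hit table
#'
#' Expects the default 12 columns plus `qlen` as a 13th column (outfmt
#' `"6 std qlen"`); descending subject coordinates denote minus-strand hits.
#'
#' @param path BLAST outfmt-6 TSV.
#' @return a hit table as from [local_hits()].
#' @export
read_blast_hits <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(raw))
    return(local_hits(character(), integer(), integer(), integer(),
                      integer(), integer(), character()))
  if (ncol(raw) < 13L) stop("need outfmt '6 std qlen' (13 columns)")
  minus <- raw$V9 > raw$V10
  local_hits(raw$V1, raw$V13, raw$V7, raw$V8,
             pmin(raw$V9, raw$V10), pmax(raw$V9, raw$V10),
             ifelse(minus, "-", "+"))
}

#' Align long reads with minimap2 and import the hits
#'
#' Writes the reads as FASTQ, maps them with `minimap2 -x map-ont -c
#' --secondary=no --mask-level 0.95` against the genome (doubled when
#' circular, with target coordinates folded back), splits alignments at
#' large deletions ([split_hits_at_deletions()]) and returns the hit table.
#' The raised mask level keeps junction arms that overlap the primary
#' alignment on the read across a near-identical repeat copy from being
#' demoted to secondary.
#'
#' @param lr [simulate_long_reads()] result or a table with `read_id`,
#'   `sequence`.
#' @param g [organelle_genome()].
#' @param threads minimap2 threads.
#' @return hit table as from [local_hits()].
#' @export
align_long_reads_minimap2 <- function(lr, g, threads = 1L) {
  if (Sys.which("minimap2") == "")
    stop("minimap2 not found on PATH")
  td <- tempfile("mm2")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  ref_fa <- file.path(td, "ref.fa")
  fq <- file.path(td, "reads.fq")
  paf <- file.path(td, "aln.paf")
  refseq <- if (g$circular) paste0(g$sequence, g$sequence) else g$sequence
  write_genome_fasta(setNames(refseq, g$id), ref_fa)
  write_long_read_fastq(lr, fq)
  status <- system2("minimap2",
                    c("-x", "map-ont", "-c", "--secondary=no",
                      "--mask-level", "0.95",
                      "-t", as.character(threads), shQuote(ref_fa), shQuote(fq)),
                    stdout = paf, stderr = FALSE)
  if (status != 0L) stop("minimap2 failed with status ", status)
  h <- read_paf(paf, fold_length = if (g$circular) g$length else NULL)
  split_hits_at_deletions(h)
}

#' Split alignments at large deletions into separate local hits
#'
#' Chained aligners can absorb a long deletion into a single alignment as a
#' `D` CIGAR operation, hiding the junction from split-hit classification;
#' local aligners like BLASTn report two hits instead. This restores the
#' local-hit view by cutting each alignment at deletion operations of at
#' least `min_del` bp.
#'
#' @param hits hit table with `cigar` (rows without a CIGAR pass through).
#' @param min_del minimum deletion length (bp) that splits a hit.
#' @return hit table with split rows.
#' @export
split_hits_at_deletions <- function(hits, min_del = 100L) {
  hits <- as.data.table(hits)
  need <- which(!is.na(hits$cigar) &
                  vapply(hits$cigar, function(cg) {
                    m <- regmatches(cg, gregexpr("\\d+(?=[DN])", cg, perl = TRUE))[[1]]
                    length(m) > 0 && any(as.integer(m) >= min_del)
                  }, logical(1)))
  if (!length(need)) return(hits)
  out <- vector("list", length(need))
  for (k in seq_along(need)) {
    i <- need[k]
    toks <- regmatches(hits$cigar[i], gregexpr("\\d+[MIDNSH=X]", hits$cigar[i]))[[1]]
    len <- as.integer(sub("[MIDNSH=X]", "", toks))
    op <- sub("\\d+", "", toks)
    dq <- ifelse(op %in% c("M", "=", "X", "I", "S"), len, 0L)
    dt <- ifelse(op %in% c("M", "=", "X", "D", "N"), len, 0L)
    cut <- which(op %in% c("D", "N") & len >= min_del)
    bounds <- c(0L, cut, length(op))
    segs <- list()
    for (s in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      idx <- setdiff(idx, cut)                 # the cut op belongs to no segment
      if (!length(idx)) next
      q_before <- sum(dq[seq_len(min(idx) - 1L)])
      t_before <- sum(dt[seq_len(min(idx) - 1L)])
      q_len <- sum(dq[idx]); t_len <- sum(dt[idx])
      if (q_len == 0L || t_len == 0L) next
      if (hits$strand[i] == "+") {
        qs <- hits$qstart[i] + q_before; qe <- qs + q_len - 1L
      } else {
        qe <- hits$qend[i] - q_before; qs <- qe - q_len + 1L
      }
      tss <- hits$tstart[i] + t_before; tee <- tss + t_len - 1L
      segs[[length(segs) + 1L]] <- data.table(
        read_id = hits$read_id[i], read_len = hits$read_len[i],
        qstart = qs, qend = qe, tstart = tss, tend = tee,
        strand = hits$strand[i],
        cigar = paste0(len[idx], op[idx], collapse = ""))
    }
    out[[k]] <- rbindlist(segs)
  }
  rbind(hits[-need], rbindlist(out))
}

## junction target coordinates of a sorted two-hit pair: the genome position
## of hit1 at its read-end side and of hit2 at its read-start side
junction_coords <- function(h) {
  j1 <- if (h$strand[1] == "+") h$tend[1] else h$tstart[1]
  j2 <- if (h$strand[2] == "+") h$tstart[2] else h$tend[2]
  c(j1, j2)
}

classify_one <- function(h, read_len, min_hit_len, max_unexplained_frac,
                         max_unexplained_const) {
  h <- h[(qend - qstart + 1L) >= min_hit_len]
  n <- nrow(h)
  max_unexp <- max_unexplained_const + max_unexplained_frac * read_len
  if (n == 0L)
    return(list(class = "unmapped", j1 = NA_integer_, j2 = NA_integer_))
  if (n >= 3L)
    return(list(class = "multi_hit_excluded", j1 = NA_integer_, j2 = NA_integer_))
  setorder(h, qstart)
  if (n == 1L) {
    unexp <- read_len - (h$qend[1] - h$qstart[1] + 1L)
    cls <- if (unexp <= max_unexp) "single_hit_clean" else "single_hit_indel"
    return(list(class = cls, j1 = NA_integer_, j2 = NA_integer_))
  }
  j <- junction_coords(h)
  if (h$strand[1] != h$strand[2])
    return(list(class = "two_hit_inverted", j1 = j[1], j2 = j[2]))
  sgn <- if (h$strand[1] == "+") 1L else -1L
  cls <- if (sgn * (j[2] - j[1]) > 0L) "two_hit_direct_deletion"
         else "two_hit_direct_circular"
  list(class = cls, j1 = j[1], j2 = j[2])
}

#' Classify reads by their split-alignment geometry
#'
#' Hits shorter than `min_hit_len` on the read are dropped first. Reads with
#' no remaining hit are `unmapped`; three or more hits are always
#' `multi_hit_excluded` (such reads may span several recombined repeats and
#' are disregarded, not reconstructed). A single hit explaining the read up
#' to `max_unexplained` bases is `single_hit_clean`, otherwise
#' `single_hit_indel`. Two hits of opposite orientation are
#' `two_hit_inverted`; two same-orientation hits whose genome order follows
#' the read order are `two_hit_direct_deletion`, and with genome order
#' reversed (the end of the read mapping in front of its start)
#' `two_hit_direct_circular`.
#'
#' @param hits hit table ([local_hits()]); `read_len` must be present.
#' @param min_hit_len minimum hit length on the read (bp).
#' @param max_unexplained_const,max_unexplained_frac a single hit is "clean"
#'   if the unexplained read length is at most `const + frac * read_len`.
#' @param all_read_ids optional vector of every read id submitted to the
#'   aligner; reads without any hit are reported as `unmapped`.
#' @return data.table with one row per read: `read_id`, `read_len`, `n_hits`,
#'   `class`, junction coordinates `j1`, `j2` (two-hit classes only).
#' @export
classify_reads <- function(hits, min_hit_len = 100L,
                           max_unexplained_const = 50L,
                           max_unexplained_frac = 0.05,
                           all_read_ids = NULL) {
  hits <- as.data.table(hits)
  out <- hits[, {
    r <- classify_one(.SD, read_len[1], min_hit_len, max_unexplained_frac,
                      max_unexplained_const)
    .(read_len = read_len[1], n_hits = .N, class = r$class,
      j1 = r$j1, j2 = r$j2)
  }, by = read_id]
  if (!is.null(all_read_ids)) {
    missing_ids <- setdiff(as.character(all_read_ids), out$read_id)
    if (length(missing_ids))
      out <- rbind(out, data.table(read_id = missing_ids, read_len = NA_integer_,
                                   n_hits = 0L, class = "unmapped",
                                   j1 = NA_integer_, j2 = NA_integer_))
  }
  out[]
}

## distance of a point to an interval (0 inside)
interval_dist <- function(p, a, b) pmax(0L, pmax(a - p, p - b))

#' Match recombination breakpoints to catalogued repeats
#'
#' A two-hit read's junction pair matches a repeat when one junction lies
#' within each copy's interval extended by `tolerance`, and the read's
#' geometry is consistent with the repeat's orientation (inverted geometry
#' with inverted repeats, deletion/circular with direct repeats). Among
#' qualifying repeats the one with the smallest total junction-to-copy
#' distance wins; an exact tie is ambiguous and matches nothing.
#'
#' @param structures output of [classify_reads()] (two-hit rows are used).
#' @param repeats repeat catalog.
#' @param tolerance bp of slack around each copy.
#' @return `structures` with columns `repeat_name` (NA if unmatched) and
#'   `geometry`.
#' @export
match_breakpoints <- function(structures, repeats, tolerance = 100L) {
  st <- as.data.table(structures)
  st[, geometry := c(two_hit_inverted = "inverted",
                     two_hit_direct_deletion = "direct_deletion",
                     two_hit_direct_circular = "direct_circular")[class]]
  st[, repeat_name := NA_character_]
  two <- which(!is.na(st$geometry))
  for (i in two) {
    want <- if (st$geometry[i] == "inverted") "inverted" else "direct"
    cand <- repeats[orientation == want]
    if (!nrow(cand)) next
    j1 <- st$j1[i]; j2 <- st$j2[i]
    ## one junction per copy, either assignment
    dA <- interval_dist(j1, cand$start1, cand$end1) +
      interval_dist(j2, cand$start2, cand$end2)
    dB <- interval_dist(j2, cand$start1, cand$end1) +
      interval_dist(j1, cand$start2, cand$end2)
    okA <- interval_dist(j1, cand$start1, cand$end1) <= tolerance &
      interval_dist(j2, cand$start2, cand$end2) <= tolerance
    okB <- interval_dist(j2, cand$start1, cand$end1) <= tolerance &
      interval_dist(j1, cand$start2, cand$end2) <= tolerance
    d <- pmin(ifelse(okA, dA, Inf), ifelse(okB, dB, Inf))
    if (all(!is.finite(d))) next
    best <- min(d)
    hitsn <- cand$name[d == best]
    if (length(hitsn) == 1L) st$repeat_name[i] <- hitsn
    ## equal-distance tie between two repeats: ambiguous, left unmatched
  }
  st[]
}

#' Count repeat-spanning and recombined reads per repeat pair
#'
#' A read spans a repeat pair when one of its hits fully covers either copy
#' plus at least `flank` bases on both sides, or when it is a recombined read
#' matched to that repeat (recombinants enter both numerator and
#' denominator). Both copies are pooled; a read contributes once.
#'
#' @param hits hit table.
#' @param matched output of [match_breakpoints()].
#' @param repeats repeat catalog.
#' @param flank required flank (bp).
#' @param genome_length genome length (to also check the wrapped image of
#'   hits crossing the origin of a circular genome); `NULL` to skip.
#' @return data.table: `name`, `recombined`, `spanning`, `frequency`.
#' @export
count_spanning <- function(hits, matched, repeats, flank = 100L,
                           genome_length = NULL) {
  hits <- as.data.table(hits)
  out <- lapply(seq_len(nrow(repeats)), function(i) {
    rr <- repeats[i]
    covers <- function(a, b) {
      ok <- hits$tstart <= a - flank & hits$tend >= b + flank
      if (!is.null(genome_length))
        ok <- ok | (hits$tstart <= a + genome_length - flank &
                      hits$tend >= b + genome_length + flank)
      ok
    }
    span_reads <- unique(hits$read_id[covers(rr$start1, rr$end1) |
                                        covers(rr$start2, rr$end2)])
    rec_reads <- matched$read_id[!is.na(matched$repeat_name) &
                                   matched$repeat_name == rr$name]
    spanning <- length(union(span_reads, rec_reads))
    data.table(name = rr$name, recombined = length(rec_reads),
               spanning = spanning,
               frequency = if (spanning > 0) length(rec_reads) / spanning
                           else NA_real_)
  })
  rbindlist(out)
}

#' Per-repeat recombination statistics
#'
#' @param recombined,spanning counts (vectors allowed).
#' @param name optional repeat names.
#' @return data.table `name`, `recombined`, `spanning`, `frequency`
#'   (`NA` flagged when no read spans the repeat).
#' @export
repeat_frequency <- function(recombined, spanning, name = NULL) {
  if (any(spanning < recombined)) stop("recombined must be <= spanning")
  data.table(name = if (is.null(name)) as.character(seq_along(recombined))
                    else name,
             recombined = as.integer(recombined),
             spanning = as.integer(spanning),
             frequency = ifelse(spanning > 0, recombined / spanning, NA_real_))
}

#' Genome-wide recombination frequency with read-support thresholds
#'
#' Repeats are included when their recombining reads, summed across all
#' replicates, reach the genome-appropriate threshold (10 for mtDNA, 3 for
#' cpDNA). The pooled frequency is total recombined / total spanning over
#' included repeats, per replicate and overall; the mean of per-replicate
#' frequencies is also reported.
#'
#' @param stats data.table with columns `replicate`, `name`, `recombined`,
#'   `spanning` (a single-replicate table may omit `replicate`).
#' @param genome `"mt"` or `"cp"` (sets the default threshold), or use
#'   `min_recombined` directly.
#' @param min_recombined threshold override.
#' @return list with `included` (repeat names), `per_replicate`, `pooled`
#'   frequency and `mean_of_replicates`; empty `included` gives NA
#'   frequencies.
#' @export
genome_frequency <- function(stats, genome = c("mt", "cp"),
                             min_recombined = NULL) {
  genome <- match.arg(genome)
  if (is.null(min_recombined))
    min_recombined <- if (genome == "mt") 10L else 3L
  stats <- as.data.table(stats)
  if (is.null(stats$replicate)) stats[, replicate := "rep1"]
  totals <- stats[, .(recombined = sum(recombined)), by = name]
  included <- totals$name[totals$recombined >= min_recombined]
  use <- stats[name %in% included]
  if (!nrow(use))
    return(list(included = character(0), per_replicate = NULL,
                pooled = NA_real_, mean_of_replicates = NA_real_,
                threshold = min_recombined))
  per_rep <- use[, .(recombined = sum(recombined), spanning = sum(spanning)),
                 by = replicate]
  per_rep[, frequency := ifelse(spanning > 0, recombined / spanning, NA_real_)]
  list(included = included, per_replicate = per_rep,
       pooled = sum(use$recombined) / sum(use$spanning),
       mean_of_replicates = mean(per_rep$frequency, na.rm = TRUE),
       threshold = min_recombined)
}

## indels >= min_len from a CIGAR string; returns data.table(pos, type, len)
## with pos = last reference base before the event
cigar_indels <- function(cigar, tstart, min_len = 10L) {
  if (is.na(cigar)) return(NULL)
  ops <- gregexpr("\\d+[MIDNSH=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSH=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSH=X]", "", toks))
  op <- sub("\\d+", "", toks)
  tpos <- tstart - 1L
  out <- list()
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "N")) tpos <- tpos + len[i]
    else if (op[i] == "D") {
      if (len[i] >= min_len)
        out[[length(out) + 1L]] <- data.table(pos = tpos + 1L,
                                              type = "deletion", len = len[i])
      tpos <- tpos + len[i]
    } else if (op[i] == "I") {
      if (len[i] >= min_len)
        out[[length(out) + 1L]] <- data.table(pos = tpos, type = "insertion",
                                              len = len[i])
    }
  }
  if (length(out)) rbindlist(out) else NULL
}

#' Gather candidate indels from read structures
#'
#' Candidates come from deletion-type two-hit junctions (position = first
#' deleted base, length = reference bases skipped between the junctions) and
#' from CIGAR indels of at least `min_indel_len` bp in single-hit
#' alignments, under the same position convention.
#'
#' @param hits hit table (with `cigar` where available).
#' @param structures [classify_reads()] output.
#' @param min_indel_len minimum CIGAR indel length considered (bp).
#' @return data.table `read_id`, `pos`, `type`, `len`.
#' @export
candidate_indels <- function(hits, structures, min_indel_len = 10L) {
  out <- list()
  del <- structures[class == "two_hit_direct_deletion"]
  if (nrow(del))
    ## deleted segment starts one past the last aligned base before the
    ## junction; its length is the number of reference bases skipped
    out$junction <- data.table(read_id = del$read_id,
                               pos = pmin(del$j1, del$j2) + 1L,
                               type = "deletion",
                               len = abs(del$j2 - del$j1) - 1L)
  single <- structures[class %in% c("single_hit_clean", "single_hit_indel")]
  h <- as.data.table(hits)[read_id %in% single$read_id & !is.na(cigar)]
  if (nrow(h)) {
    cl <- lapply(seq_len(nrow(h)), function(i) {
      ci <- cigar_indels(h$cigar[i], h$tstart[i], min_indel_len)
      if (is.null(ci)) return(NULL)
      ci[, read_id := h$read_id[i]]
      ci
    })
    cl <- cl[!vapply(cl, is.null, logical(1))]
    if (length(cl)) out$cigar <- rbindlist(cl)[, .(read_id, pos, type, len)]
  }
  if (!length(out))
    return(data.table(read_id = character(), pos = integer(),
                      type = character(), len = integer()))
  rbindlist(out, use.names = TRUE)
}

#' Call indels supported by independent reads
#'
#' Candidates are grouped by identical (type, position, length); groups with
#' at least `min_support` distinct reads are emitted.
#'
#' @param candidates [candidate_indels()] output.
#' @param min_support minimum distinct supporting reads (default 2).
#' @return data.table `type`, `pos`, `len`, `support`.
#' @export
call_supported_indels <- function(candidates, min_support = 2L) {
  if (!nrow(candidates))
    return(data.table(type = character(), pos = integer(), len = integer(),
                      support = integer()))
  grp <- as.data.table(candidates)[, .(support = uniqueN(read_id)),
                                   by = .(type, pos, len)]
  grp[support >= min_support][order(pos)]
}

#' Per-base depth from a hit table
#'
#' @param hits hit table; hits of a doubled circular reference should already
#'   be folded ([read_paf()] does this).
#' @param genome_length genome length.
#' @return integer vector of per-base depth.
#' @export
depth_from_hits <- function(hits, genome_length) {
  if (!nrow(hits)) return(integer(genome_length))
  interval_coverage(hits$tstart, hits$tend - hits$tstart + 1L, genome_length)
}

#' Coverage-ratio windows (mutant vs wild type)
#'
#' Mean depth in windows tiling the genome; the per-window mutant:WT ratio is
#' rescaled so the mean over windows with WT coverage equals exactly 1.
#'
#' @param depth_mut,depth_wt per-base depth vectors of equal length.
#' @param window window size in bp (default 1000); a genome shorter than one
#'   window yields a single whole-genome window.
#' @return data.table `window`, `start`, `end`, `depth_mut`, `depth_wt`,
#'   `ratio`, `ratio_normalized` (`NA` and flagged where WT depth is zero).
#' @export
coverage_ratio_windows <- function(depth_mut, depth_wt, window = 1000L) {
  L <- length(depth_mut)
  if (length(depth_wt) != L) stop("depth vectors differ in length")
  if (L < window) window <- L
  starts <- seq(1L, L, by = window)
  ends <- pmin(starts + window - 1L, L)
  dm <- vapply(seq_along(starts), function(i)
    mean(depth_mut[starts[i]:ends[i]]), numeric(1))
  dw <- vapply(seq_along(starts), function(i)
    mean(depth_wt[starts[i]:ends[i]]), numeric(1))
  ratio <- ifelse(dw > 0, dm / dw, NA_real_)
  norm <- ratio / mean(ratio, na.rm = TRUE)
  data.table(window = seq_along(starts), start = starts, end = ends,
             depth_mut = dm, depth_wt = dw, ratio = ratio,
             ratio_normalized = norm)
}
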