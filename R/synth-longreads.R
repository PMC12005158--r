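## Long-read simulator with planted repeat-mediated recombination. A read
## whose source molecule spans a catalogued repeat copy recombines there with
## the repeat's configured frequency; inverted repeats produce a strand
## switch at a crossover point uniform within the repeat, direct repeats
## produce deletion-type or circular/tandem-type junctions per a configurable
## mix. Nanopore-like error is i.i.d. substitution + 1-bp indel noise.

#' Long-read generative model
#'
#' @param n_reads number of reads.
#' @param per_repeat_recomb_freq named numeric vector, repeat name ->
#'   recombination frequency in `[0, 1]`.
#' @param read_length_meanlog,read_length_sdlog lognormal read-length
#'   parameters; @param min_length,max_length truncation (bp).
#' @param error_rate per-base error probability in `[0, 0.3]` (60%
#'   substitutions, 20% insertions, 20% deletions).
#' @param circular_mix for direct repeats: probability that a recombinant is
#'   a circular/tandem product rather than a deletion product.
#' @param span_flank bp of flank on both sides of a copy a molecule must
#'   cover to be exposed to recombination there.
#' @param seed RNG seed.
#' @return a `long_read_model` list.
#' @export
long_read_model <- function(n_reads, per_repeat_recomb_freq = numeric(),
                            read_length_meanlog = log(4000),
                            read_length_sdlog = 0.35, min_length = 1000L,
                            max_length = NULL, error_rate = 0,
                            circular_mix = 0.5, span_flank = 100L,
                            seed = NULL) {
  if (any(per_repeat_recomb_freq < 0 | per_repeat_recomb_freq > 1))
    stop("recombination frequencies must be in [0, 1]")
  if (error_rate < 0 || error_rate > 0.3)
    stop("error_rate must be in [0, 0.3]")
  structure(list(n_reads = n_reads,
                 per_repeat_recomb_freq = per_repeat_recomb_freq,
                 read_length_meanlog = read_length_meanlog,
                 read_length_sdlog = read_length_sdlog,
                 min_length = as.integer(min_length),
                 max_length = if (is.null(max_length)) NULL else as.integer(max_length),
                 error_rate = error_rate, circular_mix = circular_mix,
                 span_flank = as.integer(span_flank), seed = seed),
            class = "long_read_model")
}

## does a parental read [s, s+l-1] (circular) cover [a-flank, b+flank]?
covers_copy <- function(s, l, a, b, flank, L) {
  o <- (a - flank - s) %% L          # offset of the extended copy start
  o >= 0 & (o + (b - a + 1L) + 2L * flank) <= l
}

#' Simulate long reads with planted recombination at catalogued repeats
#'
#' @param g [organelle_genome()].
#' @param repeats repeat catalog ([repeat_pairs()]); every name in the
#'   model's `per_repeat_recomb_freq` must appear here (and repeats with
#'   nonzero frequency must be at least 2 bp long).
#' @param model a [long_read_model()].
#' @return list with `reads` (read_id, length, sequence), and `truth`
#'   (read_id, recombinant, repeat, geometry, junction1, junction2,
#'   crossover, spanned = comma-joined names of repeats the parental molecule
#'   spanned).
#' @export
simulate_long_reads <- function(g, repeats, model) {
  f <- model$per_repeat_recomb_freq
  missing_rep <- setdiff(names(f), repeats$name)
  if (length(missing_rep))
    stop("unknown repeat(s) in per_repeat_recomb_freq: ",
         paste(missing_rep, collapse = ", "))
  short <- repeats$name[repeats$length < 2L]
  if (any(f[names(f) %in% short] > 0))
    stop("recombination frequency > 0 for a repeat shorter than 2 bp")
  if (!is.null(model$seed)) set.seed(model$seed)
  L <- g$length
  n <- model$n_reads
  flank <- model$span_flank
  starts <- sample.int(L, n, replace = TRUE)
  lens <- pmax(model$min_length,
               as.integer(round(rlnorm(n, model$read_length_meanlog,
                                       model$read_length_sdlog))))
  lens <- pmin(lens, L - 1L)
  if (!is.null(model$max_length)) lens <- pmin(lens, model$max_length)

  seqs <- character(n)
  truth <- vector("list", n)
  rep_rows <- split(repeats, seq_len(nrow(repeats)))
  for (i in seq_len(n)) {
    s <- starts[i]; l <- lens[i]
    ## which repeats does the parental molecule span (either copy)?
    spanned <- character(0); span_copy <- integer(0)
    for (rr in rep_rows) {
      c1 <- covers_copy(s, l, rr$start1, rr$end1, flank, L)
      c2 <- covers_copy(s, l, rr$start2, rr$end2, flank, L)
      if (c1 || c2) {
        spanned <- c(spanned, rr$name)
        span_copy <- c(span_copy, if (c1) 1L else 2L)
      }
    }
    event_rep <- NA_character_; geometry <- NA_character_
    j1 <- NA_integer_; j2 <- NA_integer_; k <- NA_integer_
    if (length(spanned)) {
      ord <- sample.int(length(spanned))
      for (si in ord) {
        nm <- spanned[si]
        if (!is.na(f[nm]) && runif(1) < f[nm]) {
          event_rep <- nm
          break
        }
      }
    }
    if (is.na(event_rep)) {
      seqs[i] <- circ_substr(g, s, l)
    } else {
      rr <- repeats[name == event_rep]
      copy <- span_copy[match(event_rep, spanned)]
      a <- if (copy == 1L) rr$start1 else rr$start2
      rep_len <- rr$length
      k <- sample.int(rep_len, 1L) - 1L            # crossover offset 0..len-1
      o <- (a - s) %% L                            # copy offset within read
      pre_len <- o + k + 1L                        # junction after a+k
      suf_len <- l - pre_len
      if (rr$orientation == "inverted") {
        geometry <- "inverted"
        b_other <- if (copy == 1L) rr$end2 else rr$end1
        j1 <- fold_pos(a + k, L)
        j2 <- fold_pos(b_other - k, L)
        pre <- circ_substr(g, s, pre_len)
        suf <- revcomp(circ_substr(g, j2 - suf_len + 1L, suf_len))
        seqs[i] <- paste0(pre, suf)
      } else {
        circular <- runif(1) < model$circular_mix
        D <- rr$start2 - rr$start1                 # copy-to-copy distance
        if (!circular) {
          geometry <- "direct_deletion"
          j1 <- fold_pos(rr$start1 + k, L)
          j2 <- fold_pos(rr$start2 + k, L)
          pre <- circ_substr(g, j1 - pre_len + 1L, pre_len)
          suf <- circ_substr(g, j2 + 1L, suf_len)
          seqs[i] <- paste0(pre, suf)
        } else {
          geometry <- "direct_circular"
          ## read from the excised circle (size D), crossing its junction:
          ## ... start2+k | start1+k+1 ...
          pre_len2 <- min(pre_len, D - 1L)
          suf_len2 <- min(suf_len, D - 1L)
          j1 <- fold_pos(rr$start2 + k, L)
          j2 <- fold_pos(rr$start1 + k, L)
          pre <- circ_substr(g, j1 - pre_len2 + 1L, pre_len2)
          suf <- circ_substr(g, j2 + 1L, suf_len2)
          seqs[i] <- paste0(pre, suf)
        }
      }
    }
    truth[[i]] <- data.table(
      read_id = sprintf("lr%06d", i), recombinant = !is.na(event_rep),
      repeat_name = event_rep, geometry = geometry,
      junction1 = j1, junction2 = j2, crossover = k,
      spanned = paste(spanned, collapse = ","))
  }
  truth <- rbindlist(truth)
  if (model$error_rate > 0) seqs <- add_read_errors(seqs, model$error_rate)
  list(reads = data.table(read_id = truth$read_id,
                          length = nchar(seqs), sequence = seqs),
       truth = truth)
}

## i.i.d. substitution/indel noise over a character vector of sequences
add_read_errors <- function(seqs, rate) {
  vapply(seqs, function(sq) {
    ch <- strsplit(sq, "")[[1]]
    n <- length(ch)
    K <- rpois(1L, n * rate)
    if (K == 0L) return(sq)
    at <- sample.int(n, min(K, n))
    kind <- sample(c("sub", "ins", "del"), length(at), replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    sub_at <- at[kind == "sub"]
    if (length(sub_at))
      ch[sub_at] <- BASES[(match(ch[sub_at], BASES) - 1L +
                             sample.int(3L, length(sub_at), replace = TRUE)) %% 4L + 1L]
    keep <- rep(TRUE, n)
    keep[at[kind == "del"]] <- FALSE
    ins_at <- at[kind == "ins"]
    ## interleave insertions by fractional positions in one ordered rebuild
    pos_all <- c(which(keep), ins_at + 0.5)
    chr_all <- c(ch[keep], sample(BASES, length(ins_at), replace = TRUE))
    paste(chr_all[order(pos_all)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write long reads as FASTQ
#'
#' @param lr result of [simulate_long_reads()] (or any table with `read_id`
#'   and `sequence`).
#' @param path output path.
#' @export
write_long_read_fastq <- function(lr, path) {
  reads <- if (is.list(lr) && !is.data.frame(lr)) lr$reads else lr
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads)))
    writeLines(c(paste0("@", reads$read_id[i]), reads$sequence[i], "+",
                 strrep("F", nchar(reads$sequence[i]))), con)
  invisible(path)
}
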