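## Packaged example datasets: fixed study conditions used by the package's
## validation runs and documentation. Repeat sizes and identities mirror the
## most recombinationally active Arabidopsis mtDNA repeats; copies of
## different pairs are pinned farther apart than the longest read so each
## read gets an independent recombination trial per spanned repeat.

#' Example recombination benchmark dataset
#'
#' An 80-kb circular genome carrying five dispersed repeat pairs (direct and
#' inverted, 127-556 bp, 99.2-100% identity) with planted per-repeat
#' recombination frequencies 0, 0.1, 0.3, 0.7 and 1, and a long-read library
#' sized so every repeat is spanned by several hundred reads.
#'
#' @param seed RNG seed.
#' @param n_reads number of long reads.
#' @param error_rate per-base read error rate (0 = error-free mode).
#' @return list with `genome`, `features`, `repeats`, `freqs` (the planted
#'   per-repeat frequencies), `model` and the simulated `reads`/`truth`.
#' @export
example_recomb_dataset <- function(seed = 1L, n_reads = 8000L,
                                   error_rate = 0) {
  sg <- simulate_genome(
    80000,
    n_genes = c(CDS = 2, tRNA = 2),
    repeat_specs = list(
      list(name = "RD556", length = 556, identity = 99.82,
           orientation = "direct", pos1 = 5000, pos2 = 20000),
      list(name = "RD249", length = 249, identity = 100,
           orientation = "direct", pos1 = 12500, pos2 = 27500),
      list(name = "RI127", length = 127, identity = 99.21,
           orientation = "inverted", pos1 = 35000, pos2 = 50000),
      list(name = "RI350", length = 350, identity = 100,
           orientation = "inverted", pos1 = 42500, pos2 = 57500),
      list(name = "RD463", length = 463, identity = 99.57,
           orientation = "direct", pos1 = 65000, pos2 = 72500)),
    seed = seed)
  freqs <- c(RD556 = 0.3, RD249 = 0.1, RI127 = 1, RI350 = 0.7, RD463 = 0)
  model <- long_read_model(
    n_reads = n_reads, per_repeat_recomb_freq = freqs,
    read_length_meanlog = log(3500), read_length_sdlog = 0.3,
    min_length = 1500L, max_length = 6500L, error_rate = error_rate,
    circular_mix = 0.5, seed = seed + 1L)
  lr <- simulate_long_reads(sg$genome, sg$repeats, model)
  c(sg, list(freqs = freqs, model = model, reads = lr$reads,
             truth = lr$truth))
}

#' Example duplex mutation-accumulation dataset
#'
#' A 30-kb annotated circular genome and a duplex library with planted
#' mutations under a configurable model; a thin wrapper used by the worked
#' examples and validation runs.
#'
#' @param seed RNG seed.
#' @param n_molecules duplex source molecules.
#' @param model a [mutation_model()].
#' @param seq_error per-read-base sequencing error rate.
#' @return list with `genome`, `features`, `repeats` and the simulation
#'   tables of [simulate_duplex_families()].
#' @export
example_duplex_dataset <- function(seed = 1L, n_molecules = 5000L,
                                   model = mutation_model(
                                     base_rate_per_class = c("C>T" = 2e-5,
                                                             "T>C" = 1e-5)),
                                   seq_error = 1e-3) {
  sg <- simulate_genome(30000, n_genes = c(CDS = 6, intron = 2, rRNA = 2,
                                           tRNA = 8), seed = seed)
  sim <- simulate_duplex_families(sg$genome, sg$features, model,
                                  n_molecules = n_molecules,
                                  seq_error = seq_error, seed = seed + 1L)
  c(sg, sim)
}
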