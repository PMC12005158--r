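## Orchestration: configuration handling and end-to-end runs chaining the
## synthetic generators (or user-supplied inputs) through consensus calling,
## spectrum analysis and structural variant analysis, with a reproducible
## manifest.

## every default that fills a gap the field's protocols leave open is tagged
## "artifact-default" in the manifest so users can tell prescribed from
## package-chosen parameters
DEFAULT_CONFIG <- list(
  seed = 1L,
  duplex = list(
    n_molecules = 2000L, reads_per_strand = 3L, insert_length = 300L,
    seq_error = 0, min_reads_per_strand = 3L, strand_consensus_threshold = 0.9,
    end_trim = 10L, numt_k_flank = 20L, numt_max_mismatch = 0L,
    locus_slop = 10L),
  structvar = list(
    min_hit_len = 100L, max_unexplained_const = 50L, max_unexplained_frac = 0.05,
    breakpoint_tolerance = 100L, span_flank = 100L, min_recomb_mt = 10L,
    min_recomb_cp = 3L, window = 1000L, min_indel_len = 10L,
    min_indel_support = 2L)
)
ARTIFACT_DEFAULTS <- c("duplex.min_reads_per_strand",
                       "duplex.strand_consensus_threshold", "duplex.end_trim",
                       "duplex.numt_k_flank", "duplex.numt_max_mismatch",
                       "duplex.locus_slop", "structvar.min_hit_len",
                       "structvar.max_unexplained_const",
                       "structvar.max_unexplained_frac",
                       "structvar.breakpoint_tolerance", "structvar.span_flank",
                       "structvar.min_indel_len")

#' Default run configuration
#'
#' @return nested list of all pipeline parameters with their defaults.
#' @export
default_config <- function() DEFAULT_CONFIG

merge_config <- function(base, user, prefix = "") {
  for (k in names(user)) {
    key <- if (prefix == "") k else paste0(prefix, ".", k)
    if (!k %in% names(base)) stop("unknown config key: ", key)
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]], key)
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file, or a list already parsed.
#' @return full configuration list.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  merge_config(default_config(), user)
}

run_manifest <- function(config, stage) {
  list(package = "orgvar",
       version = as.character(utils::packageVersion("orgvar")),
       stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       seed = config$seed, parameters = config,
       artifact_defaults = ARTIFACT_DEFAULTS)
}

#' End-to-end duplex run on synthetic data
#'
#' Chains genome simulation (or supplied genome/features), duplex family
#' simulation per replicate, family grouping, consensus building, variant
#' calling, optional NUMT filtering, coverage and frequency computation, and
#' the spectrum tables.
#'
#' @param config configuration from [load_config()] / [default_config()].
#' @param g,features genome and features (required).
#' @param model a [mutation_model()].
#' @param replicates number of replicate libraries.
#' @param nuclear optional nuclear reference (path, sequences, or
#'   DNAStringSet) enabling the NUMT filter; if the filter parameters are set
#'   but `nuclear` is missing the run aborts before computing.
#' @param numt_filter_on logical, apply the NUMT filter.
#' @return list with `calls` (all replicates, `replicate` column), `depth`
#'   (named list of per-replicate depth vectors), `coverage_total`,
#'   `frequencies` (per replicate x type), `truth`, `manifest`.
#' @export
run_duplex <- function(config = default_config(), g, features,
                       model = mutation_model(), replicates = 1L,
                       nuclear = NULL, numt_filter_on = !is.null(nuclear)) {
  if (numt_filter_on && is.null(nuclear))
    stop("config error: NUMT filter enabled but no nuclear reference given")
  dc <- config$duplex
  calls_all <- list(); depth_all <- list(); truth_all <- list()
  cons_all <- list()
  for (r in seq_len(replicates)) {
    rep_name <- paste0("rep", r)
    sim <- simulate_duplex_families(
      g, features, model, n_molecules = dc$n_molecules,
      reads_per_strand = dc$reads_per_strand,
      insert_length = dc$insert_length, seq_error = dc$seq_error,
      seed = config$seed + r)
    fams <- group_families(sim$reads, locus_slop = dc$locus_slop)
    cons <- build_consensuses(fams, sim$devs,
                              min_reads_per_strand = dc$min_reads_per_strand,
                              strand_consensus_threshold = dc$strand_consensus_threshold)
    calls <- call_variants(cons, g, features, end_trim = dc$end_trim)
    if (numt_filter_on)
      calls <- numt_filter(calls, cons, g, nuclear,
                           k_flank = dc$numt_k_flank,
                           max_mismatch = dc$numt_max_mismatch)
    cov <- coverage_profile(cons, g$length, end_trim = dc$end_trim)
    calls[, replicate := rep_name]
    calls_all[[rep_name]] <- calls
    depth_all[[rep_name]] <- cov$depth
    sim$truth[, replicate := rep_name]
    truth_all[[rep_name]] <- sim$truth
    cons_all[[rep_name]] <- cons
  }
  calls <- rbindlist(calls_all)
  total <- sum(vapply(depth_all, function(d) sum(as.numeric(d)), numeric(1)))
  freqs <- rbindlist(lapply(names(depth_all), function(rn) {
    tot <- sum(as.numeric(depth_all[[rn]]))
    cc <- calls[replicate == rn]
    data.table(replicate = rn, coverage = tot,
               snv = variant_frequency(cc, tot, "SNV"),
               indel = variant_frequency(cc, tot, "indel"),
               dinucleotide = variant_frequency(cc, tot, "dinucleotide"))
  }))
  list(calls = calls, depth = depth_all, coverage_total = total,
       frequencies = freqs, truth = rbindlist(truth_all),
       consensus = cons_all, manifest = run_manifest(config, "duplex"))
}

#' End-to-end structural variant run on synthetic long reads
#'
#' Simulates long reads per replicate, aligns them (minimap2) or consumes
#' supplied hit tables, classifies read structures, matches breakpoints to
#' the repeat catalog, and derives per-repeat statistics, genome-wide
#' frequencies and supported indel calls.
#'
#' @param config configuration list.
#' @param g genome; @param repeats repeat catalog.
#' @param lr_model a [long_read_model()] (ignored when `hits` supplied).
#' @param replicates number of replicate libraries.
#' @param hits optional named list of pre-computed hit tables per replicate
#'   (bypasses simulation and alignment).
#' @param genome_kind `"mt"` or `"cp"` (selects the inclusion threshold).
#' @return list with `structures`, `per_repeat` (replicate-stratified
#'   stats), `genome_freq`, `indels`, `truth`, `manifest`.
#' @export
run_structvar <- function(config = default_config(), g, repeats,
                          lr_model = NULL, replicates = 1L, hits = NULL,
                          genome_kind = "mt") {
  sc <- config$structvar
  st_all <- list(); pr_all <- list(); truth_all <- list(); cand_all <- list()
  for (r in seq_len(replicates)) {
    rep_name <- paste0("rep", r)
    if (is.null(hits)) {
      m <- lr_model
      m$seed <- (if (is.null(m$seed)) config$seed else m$seed) + r
      lr <- simulate_long_reads(g, repeats, m)
      h <- align_long_reads_minimap2(lr, g)
      all_ids <- lr$reads$read_id
      lr$truth[, replicate := rep_name]
      truth_all[[rep_name]] <- lr$truth
    } else {
      h <- as.data.table(hits[[r]])
      all_ids <- unique(h$read_id)
    }
    st <- classify_reads(h, min_hit_len = sc$min_hit_len,
                         max_unexplained_const = sc$max_unexplained_const,
                         max_unexplained_frac = sc$max_unexplained_frac,
                         all_read_ids = all_ids)
    st <- match_breakpoints(st, repeats, tolerance = sc$breakpoint_tolerance)
    pr <- count_spanning(h, st, repeats, flank = sc$span_flank,
                         genome_length = g$length)
    st[, replicate := rep_name]; pr[, replicate := rep_name]
    st_all[[rep_name]] <- st; pr_all[[rep_name]] <- pr
    cand_all[[rep_name]] <- candidate_indels(h, st,
                                             min_indel_len = sc$min_indel_len)
  }
  per_repeat <- rbindlist(pr_all)
  thr <- if (genome_kind == "mt") sc$min_recomb_mt else sc$min_recomb_cp
  gf <- genome_frequency(per_repeat, genome = genome_kind,
                         min_recombined = thr)
  indels <- call_supported_indels(rbindlist(cand_all),
                                  min_support = sc$min_indel_support)
  list(structures = rbindlist(st_all), per_repeat = per_repeat,
       genome_freq = gf, indels = indels,
       truth = if (length(truth_all)) rbindlist(truth_all) else NULL,
       manifest = run_manifest(config, "structvar"))
}

#' Human-readable run summary
#'
#' @param duplex_result [run_duplex()] output (or NULL).
#' @param structvar_result [run_structvar()] output (or NULL).
#' @return character vector of report lines (also printed invisibly usable
#'   with `writeLines`).
#' @export
make_report <- function(duplex_result = NULL, structvar_result = NULL) {
  lines <- c("orgvar run report", strrep("=", 40))
  if (!is.null(duplex_result)) {
    f <- duplex_result$frequencies
    lines <- c(lines, "", "Duplex consensus variant frequencies (per base):")
    if (!is.null(f) && nrow(f)) {
      for (i in seq_len(nrow(f)))
        lines <- c(lines, sprintf(
          "  %s: coverage %.3g; SNV %.3g; indel %.3g; dinucleotide %.3g",
          f$replicate[i], f$coverage[i], f$snv[i], f$indel[i],
          f$dinucleotide[i]))
    } else lines <- c(lines, "  (no data)")
    n_numt <- sum(duplex_result$calls$status == "numt")
    lines <- c(lines, sprintf("  calls: %d pass, %d NUMT-filtered, %d end-trimmed",
                              sum(duplex_result$calls$status == "pass"), n_numt,
                              sum(duplex_result$calls$status == "end_trimmed")))
  }
  if (!is.null(structvar_result)) {
    lines <- c(lines, "", "Repeat-mediated recombination:")
    pr <- structvar_result$per_repeat
    if (!is.null(pr) && nrow(pr)) {
      agg <- pr[, .(recombined = sum(recombined), spanning = sum(spanning)),
                by = name]
      for (i in seq_len(nrow(agg)))
        lines <- c(lines, sprintf("  %s: %d/%d recombined/spanning (%.3f)",
                                  agg$name[i], agg$recombined[i], agg$spanning[i],
                                  ifelse(agg$spanning[i] > 0,
                                         agg$recombined[i] / agg$spanning[i], NA)))
      gfp <- structvar_result$genome_freq$pooled
      lines <- c(lines, sprintf("  genome-wide pooled frequency: %s",
                                ifelse(is.na(gfp), "no repeat passed threshold",
                                       sprintf("%.4f", gfp))))
    } else lines <- c(lines, "  (no reads)")
    nind <- if (is.null(structvar_result$indels)) 0L
            else nrow(structvar_result$indels)
    lines <- c(lines, sprintf("  supported indel calls: %d", nind))
  }
  lines
}
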