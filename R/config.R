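#' Pipeline configuration
#'
#' Collects every tunable constant of the annotation pipeline in one list.
#' Defaults reproduce the published analysis settings: exact adapter
#' substring matching of 5 nt or more, pool size windows of 18-22 nt
#' (miRNA), 28-32 nt (piRNA) and 35-42 nt (crasiRNA), all-hits ungapped
#' mapping with at most 1 mismatch, a +/-50 bp folding window with a 75%
#' paired-stem requirement, 1000 bp gene-model flank expansion, a 15 nt
#' minimum exact seed and 95% mature identity for reference comparison,
#' and a +/-50 bp motif window scored against 100 composition-preserving
#' shuffles with a 1/3 match-fraction cohort threshold.
#'
#' @param adapter3 3' adapter sequence (required for clipping).
#' @param adapter5 Optional 5' adapter sequence.
#' @param min_adapter_match Minimum exact terminal adapter match (nt).
#' @param size_ranges Named list `pool -> c(min, max)` insert sizes (nt).
#' @param max_mismatches Maximum mismatches per alignment.
#' @param hairpin_flank Bases of genomic context folded on each side of a hit.
#' @param min_stem_paired_frac Minimum fraction of stem bases that are paired.
#' @param min_loop Minimum unpaired terminal loop length enforced by folding.
#' @param min_loop_validate Minimum loop length required at validation.
#' @param loop_overhang Read bases tolerated inside the terminal loop.
#' @param no_lonely_pairs Forbid isolated base pairs when folding.
#' @param gene_flank Gene-model expansion (bp) applied per missing UTR.
#' @param ref_min_seed Minimum exact shared seed with a reference hairpin (nt).
#' @param ref_min_identity Minimum mature identity against a reference hairpin.
#' @param motif_flank Bases of flanking sequence per side in motif windows.
#' @param motif_min_distinct_3mers Complexity gate: distinct 3-mers required.
#' @param motif_max_n_frac Windows with a higher N fraction are skipped.
#' @param motif_n_shuffles Number of composition-preserving shuffles.
#' @param motif_share_threshold Match fraction defining cohort membership.
#' @param motif_pseudocount Use the (n_ge + 1)/(n + 1) p-value correction.
#' @param peak_min_reads Minimum alignments per retained read peak.
#' @param peak_max_gap Maximum gap (bp) bridged when clustering peaks.
#' @param rng_seed Global random seed for all stochastic steps.
#' @return A list of class `srn_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(adapter3 = "TCGTATGCCG")
#' cfg$size_ranges$mirna
pipeline_config <- function(adapter3 = NULL,
                            adapter5 = NULL,
                            min_adapter_match = 5L,
                            size_ranges = list(mirna = c(18L, 22L),
                                               pirna = c(28L, 32L),
                                               crasirna = c(35L, 42L)),
                            max_mismatches = 1L,
                            hairpin_flank = 50L,
                            min_stem_paired_frac = 0.75,
                            min_loop = 3L,
                            min_loop_validate = 1L,
                            loop_overhang = 0L,
                            no_lonely_pairs = TRUE,
                            gene_flank = 1000L,
                            ref_min_seed = 15L,
                            ref_min_identity = 0.95,
                            motif_flank = 50L,
                            motif_min_distinct_3mers = 5L,
                            motif_max_n_frac = 0.10,
                            motif_n_shuffles = 100L,
                            motif_share_threshold = 1 / 3,
                            motif_pseudocount = FALSE,
                            peak_min_reads = 2L,
                            peak_max_gap = 0L,
                            rng_seed = 1L) {
  cfg <- list(
    adapter3 = adapter3, adapter5 = adapter5,
    min_adapter_match = as.integer(min_adapter_match),
    size_ranges = lapply(size_ranges, as.integer),
    max_mismatches = as.integer(max_mismatches),
    hairpin_flank = as.integer(hairpin_flank),
    min_stem_paired_frac = min_stem_paired_frac,
    min_loop = as.integer(min_loop),
    min_loop_validate = as.integer(min_loop_validate),
    loop_overhang = as.integer(loop_overhang),
    no_lonely_pairs = isTRUE(no_lonely_pairs),
    gene_flank = as.integer(gene_flank),
    ref_min_seed = as.integer(ref_min_seed),
    ref_min_identity = ref_min_identity,
    motif_flank = as.integer(motif_flank),
    motif_min_distinct_3mers = as.integer(motif_min_distinct_3mers),
    motif_max_n_frac = motif_max_n_frac,
    motif_n_shuffles = as.integer(motif_n_shuffles),
    motif_share_threshold = motif_share_threshold,
    motif_pseudocount = isTRUE(motif_pseudocount),
    peak_min_reads = as.integer(peak_min_reads),
    peak_max_gap = as.integer(peak_max_gap),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "srn_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ints <- c("min_adapter_match", "max_mismatches", "hairpin_flank", "min_loop",
            "min_loop_validate", "loop_overhang", "gene_flank", "ref_min_seed",
            "motif_flank", "motif_min_distinct_3mers", "motif_n_shuffles",
            "peak_min_reads", "peak_max_gap")
  for (f in ints) {
    v <- cfg[[f]]
    if (!is.integer(v) || length(v) != 1L || is.na(v) || v < 0L) {
      abort(sprintf("config field '%s' must be a single integer >= 0", f))
    }
  }
  for (f in c("min_stem_paired_frac", "ref_min_identity",
              "motif_share_threshold")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      abort(sprintf("config field '%s' must be a fraction in (0, 1]", f))
    }
  }
  if (length(cfg$size_ranges) == 0L) abort("size_ranges must not be empty")
  for (pool in names(cfg$size_ranges)) {
    r <- cfg$size_ranges[[pool]]
    if (length(r) != 2L || any(is.na(r)) || r[1] < 1L || r[2] < r[1]) {
      abort(sprintf("size range for pool '%s' must be c(min, max) with max >= min >= 1", pool))
    }
  }
  if (!is.null(cfg$adapter3)) {
    if (!is_string(cfg$adapter3)) abort("adapter3 must be a single string")
    if (nchar(cfg$adapter3) < cfg$min_adapter_match) {
      abort("adapter3 must be at least min_adapter_match bases long")
    }
  }
  invisible(cfg)
}

#' @export
print.srn_config <- function(x, ...) {
  cat("<srn_config>\n")
  sr <- vapply(names(x$size_ranges), function(p) {
    sprintf("%s [%d,%d]", p, x$size_ranges[[p]][1], x$size_ranges[[p]][2])
  }, character(1))
  cat("  pools:      ", paste(sr, collapse = "  "), "\n")
  cat("  adapter3:   ", x$adapter3 %||% "<unset>",
      " (min terminal match ", x$min_adapter_match, ")\n", sep = "")
  cat("  mapping:     <=", x$max_mismatches, "mismatch, all hits\n")
  cat("  hairpin:     flank", x$hairpin_flank, "bp, stem frac >=",
      x$min_stem_paired_frac, "\n")
  cat("  motif:       flank", x$motif_flank, "bp,", x$motif_n_shuffles,
      "shuffles, share >=", round(x$motif_share_threshold, 3), "\n")
  cat("  rng_seed:   ", x$rng_seed, "\n")
  invisible(x)
}

# read a flat key: value YAML-ish config file into pipeline_config() arguments
#' Read a pipeline configuration file
#'
#' The file is a flat `key: value` document whose keys mirror the
#' [pipeline_config()] argument names; pool size ranges are written as
#' `size_mirna: 18,22` etc. Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A `srn_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- stringr::str_match(lines, "^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*?)\\s*$")
  if (anyNA(kv[, 1])) abort("malformed config line(s)")
  keys <- kv[, 2]
  vals <- kv[, 3]
  args <- list()
  ranges <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (grepl("^size_", k)) {
      ranges[[sub("^size_", "", k)]] <- as.integer(strsplit(v, ",")[[1]])
    } else if (k %in% c("adapter3", "adapter5")) {
      args[[k]] <- v
    } else if (k %in% c("no_lonely_pairs", "motif_pseudocount")) {
      args[[k]] <- toupper(v) %in% c("TRUE", "YES", "1")
    } else if (k %in% names(formals(pipeline_config))) {
      args[[k]] <- as.numeric(v)
    } else {
      abort(sprintf("unknown config key '%s'", k))
    }
  }
  if (length(ranges)) args$size_ranges <- ranges
  do.call(pipeline_config, args)
}
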