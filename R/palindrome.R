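# Discontiguous-palindrome ("mirror") motif statistic. The score of a
# window is the number of positions at which the window matches its own
# reverse complement, i.e. positions i where base i is the complement of
# base L-1-i. Matches come in symmetric position pairs and no base is
# self-complementary, so the score is always even. Significance is an
# empirical p-value over composition-preserving permutations of the window.

#' Mirror (discontiguous palindrome) score
#'
#' Vectorised over windows. `N` never matches.
#'
#' @param windows Character vector of window sequences.
#' @return Integer vector of scores, one per window (always even, between
#'   0 and the window length).
#' @export
#' @examples
#' mirror_score(c("ACGT", "AAAA", "ACGTT"))
mirror_score <- function(windows) {
  if (any(nchar(windows) == 0L)) abort("empty window")
  rc <- revcomp(windows)
  vapply(seq_along(windows), function(i) {
    a <- strsplit(windows[i], "")[[1]]
    b <- strsplit(rc[i], "")[[1]]
    sum(a == b & a != "N")
  }, integer(1))
}

#' Count distinct overlapping 3-mers
#'
#' 3-mers containing `N` are excluded from the count.
#'
#' @param seq A single sequence of length >= 3.
#' @return Integer count of distinct 3-mers.
#' @export
#' @examples
#' count_distinct_3mers("ACGTACGT")
count_distinct_3mers <- function(seq) {
  if (!is_string(seq) || nchar(seq) < 3L) abort("sequence must have length >= 3")
  km <- seq_kmers(seq, 3L)
  km <- km[!grepl("N", km, fixed = TRUE)]
  length(unique(km))
}

#' Extract motif windows around crasiRNA alignments
#'
#' Each alignment contributes the aligned interval plus `motif_flank` bases
#' up- and downstream, oriented to the strand the read mapped to
#' (minus-strand windows are reverse-complemented). Alignments too close
#' to a contig edge for a full flank are skipped (`"edge"`), as are
#' low-complexity windows (fewer than `motif_min_distinct_3mers` distinct
#' 3-mers, or more than `motif_max_n_frac` ambiguous bases).
#'
#' @param hits Alignment tibble from [map_reads()].
#' @param genome Genome tibble or named character vector.
#' @param config A [pipeline_config()].
#' @return Tibble with one row per alignment: hit coordinates,
#'   `window_seq`, `skipped`, `skip_reason` (`""`, `"edge"`,
#'   `"low_complexity"`).
#' @export
extract_motif_windows <- function(hits, genome, config = pipeline_config()) {
  contigs <- genome_vector(genome)
  flank <- config$motif_flank
  n <- nrow(hits)
  win <- character(n)
  reason <- character(n)
  lens <- nchar(contigs)
  for (i in seq_len(n)) {
    L <- lens[[hits$contig[i]]]
    s <- hits$start[i] - flank
    e <- hits$end[i] + flank
    if (s < 0L || e > L) {
      reason[i] <- "edge"
      next
    }
    w <- substr(contigs[[hits$contig[i]]], s + 1L, e)
    if (hits$strand[i] == "-") w <- revcomp(w)
    n_frac <- stringr::str_count(w, "N") / nchar(w)
    if (count_distinct_3mers(w) < config$motif_min_distinct_3mers ||
        n_frac > config$motif_max_n_frac) {
      reason[i] <- "low_complexity"
      next
    }
    win[i] <- w
  }
  out <- as_tibble(hits[, intersect(hit_cols(), names(hits))])
  out$window_seq <- win
  out$skipped <- reason != ""
  out$skip_reason <- reason
  out
}

#' Empirical p-value of a window's mirror score
#'
#' The window is permuted `n_shuffles` times (Fisher-Yates, preserving
#' base composition); the p-value is the fraction of permutations scoring
#' at least the original. With `motif_pseudocount = TRUE` the
#' `(n_ge + 1) / (n + 1)` correction is applied instead.
#'
#' @param window_seq A single window sequence.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the permutation stream.
#' @return One-row tibble: `score`, `match_frac`, `n_shuffles`, `n_ge`,
#'   `p_value`.
#' @export
empirical_p <- function(window_seq, config = pipeline_config(),
                        seed = config$rng_seed) {
  score <- mirror_score(window_seq)
  chars <- strsplit(window_seq, "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", chars)
  L <- length(chars)
  n_sh <- config$motif_n_shuffles
  n_ge <- withr::with_seed(seed, {
    hits <- 0L
    for (s in seq_len(n_sh)) {
      perm <- sample.int(L)
      x <- chars[perm]
      # score of permuted window without re-materialising the string
      sc <- sum(x == rev(comp[perm]) & x != "N")
      if (sc >= score) hits <- hits + 1L
    }
    hits
  })
  p <- if (config$motif_pseudocount) (n_ge + 1) / (n_sh + 1) else n_ge / n_sh
  tibble(score = score, match_frac = score / L, n_shuffles = n_sh,
         n_ge = n_ge, p_value = p)
}

#' Score motif windows with permutation significance
#'
#' Applies [mirror_score()] and [empirical_p()] to every non-skipped
#' window. Per-window permutation seeds are derived deterministically from
#' the global seed and the locus (contig, start, strand), so results do
#' not depend on processing order.
#'
#' @param windows Output of [extract_motif_windows()].
#' @param config A [pipeline_config()].
#' @return An object of class `srn_cohort`: the per-window tibble with
#'   `score`, `match_frac`, `n_ge`, `p_value`, `share_member` columns
#'   (NA for skipped windows), plus the config used.
#' @export
score_palindromes <- function(windows, config = pipeline_config()) {
  out <- as_tibble(windows)
  n <- nrow(out)
  res <- tibble(score = rep(NA_integer_, n), match_frac = NA_real_,
                n_ge = NA_integer_, p_value = NA_real_)
  for (i in seq_len(n)) {
    if (out$skipped[i]) next
    key <- paste(out$contig[i], out$start[i], out$strand[i], sep = ":")
    r <- empirical_p(out$window_seq[i], config,
                     seed = derive_seed(config$rng_seed, key))
    res$score[i] <- r$score
    res$match_frac[i] <- r$match_frac
    res$n_ge[i] <- r$n_ge
    res$p_value[i] <- r$p_value
  }
  out <- dplyr::bind_cols(out, res)
  out$share_member <- !out$skipped &
    out$match_frac >= config$motif_share_threshold
  structure(list(results = out, config = config), class = "srn_cohort")
}

#' Summarise a scored motif cohort
#'
#' @param cohort A `srn_cohort` from [score_palindromes()] (or its
#'   per-window results tibble).
#' @param config A [pipeline_config()]; taken from the cohort when present.
#' @return List with `share` (fraction of non-skipped loci at or above the
#'   match-fraction threshold), `share_all_loci` (same numerator over all
#'   loci including skipped), `n_scored`, `n_skipped`, and `histogram`
#'   (p-values binned at width 0.01: `bin_lo`, `bin_hi`, `count`).
#' @export
cohort_summary <- function(cohort, config = NULL) {
  if (inherits(cohort, "srn_cohort")) {
    config <- config %||% cohort$config
    res <- cohort$results
  } else {
    config <- config %||% pipeline_config()
    res <- cohort
  }
  scored <- filter(res, !.data$skipped)
  if (nrow(scored) == 0L) abort("empty cohort: no window passed the gates")
  breaks <- seq(0, 1, by = 0.01)
  cuts <- cut(scored$p_value, breaks = breaks, include.lowest = TRUE,
              right = FALSE)
  # right-open bins [lo, hi) except the last, which includes 1
  hist <- tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 count = as.integer(table(cuts)))
  list(share = mean(scored$share_member),
       share_all_loci = sum(scored$share_member) / nrow(res),
       n_scored = nrow(scored),
       n_skipped = sum(res$skipped),
       histogram = hist)
}
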