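# broom-style accessors for the package's result objects.

#' Tidy a motif cohort
#'
#' @param x A `srn_cohort` from [score_palindromes()].
#' @param ... Unused.
#' @return The per-window results tibble (one row per alignment window).
#' @export
tidy.srn_cohort <- function(x, ...) {
  x$results
}

#' One-row summary of a motif cohort
#'
#' @param x A `srn_cohort` from [score_palindromes()].
#' @param ... Unused.
#' @return One-row tibble: `n_windows`, `n_scored`, `n_skipped`, `share`,
#'   `median_p`, `mean_match_frac`.
#' @export
glance.srn_cohort <- function(x, ...) {
  res <- x$results
  scored <- filter(res, !.data$skipped)
  tibble(n_windows = nrow(res),
         n_scored = nrow(scored),
         n_skipped = sum(res$skipped),
         share = mean(scored$share_member),
         median_p = stats::median(scored$p_value),
         mean_match_frac = mean(scored$match_frac))
}

#' @export
print.srn_cohort <- function(x, ...) {
  g <- glance(x)
  cat("<srn_cohort> ", g$n_scored, " scored window(s) (+", g$n_skipped,
      " skipped); share at threshold ", round(x$config$motif_share_threshold, 3),
      ": ", round(g$share, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy miRNA calls
#'
#' @param x A `srn_mirna_calls` from [call_mirna_loci()].
#' @param ... Unused.
#' @return The per-alignment verdict tibble.
#' @export
tidy.srn_mirna_calls <- function(x, ...) {
  x$calls
}

#' One-row summary of miRNA calling
#'
#' @param x A `srn_mirna_calls` from [call_mirna_loci()].
#' @param ... Unused.
#' @return One-row tibble: `n_alignments`, `n_reads`, `n_bona_fide`,
#'   `n_loci`.
#' @export
glance.srn_mirna_calls <- function(x, ...) {
  tibble(n_alignments = nrow(x$calls),
         n_reads = dplyr::n_distinct(x$calls$read_id),
         n_bona_fide = length(x$bona_fide),
         n_loci = nrow(x$loci))
}
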