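# Adapter clipping and size-class selection.
#
# Clipping rule: the longest read suffix of length >= min_adapter_match that
# exactly equals a prefix of the 3' adapter is removed; a read with no such
# suffix is discarded outright. A 5' adapter (when configured) is then
# clipped by the symmetric rule -- longest read prefix equal to an adapter
# suffix -- but its absence does not discard. Matching is exact: no
# mismatches are tolerated in the adapter match.

#' Clip adapters from small RNA reads
#'
#' @param reads Tibble with columns `id`, `seq` (from [read_sequences()]).
#' @param config A [pipeline_config()]; `adapter3` must be set.
#' @return The input tibble with columns `seq` (clipped), `clipped3`,
#'   `clipped5`, and `status` (`"kept"`, `"no_adapter"`, or `"empty"`).
#'   Discarded reads are retained in the table with their original sequence
#'   so that downstream tallies conserve the input count.
#' @export
#' @examples
#' cfg <- pipeline_config(adapter3 = "TCGTATGCCG")
#' reads <- tibble::tibble(id = "r1", seq = "ACGTACGTACGTACGTACTCGTA")
#' clip_adapters(reads, cfg)
clip_adapters <- function(reads, config) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (is.null(config$adapter3)) abort("config$adapter3 is required for clipping")
  a3 <- normalize_seq(config$adapter3, "adapter3")
  mm <- config$min_adapter_match
  seqs <- reads$seq
  lens <- nchar(seqs)

  # longest L in [mm, min(len, nchar(a3))] with suffix(read, L) == prefix(a3, L)
  clip3 <- integer(length(seqs))
  hi3 <- if (length(lens)) min(nchar(a3), max(lens)) else 0L
  for (L in if (hi3 >= mm) seq(hi3, mm) else integer(0)) {
    todo <- clip3 == 0L & lens >= L
    if (!any(todo)) next
    hit <- stringr::str_sub(seqs[todo], -L) == stringr::str_sub(a3, 1, L)
    clip3[todo][hit] <- L
  }
  status <- ifelse(clip3 > 0L, "kept", "no_adapter")
  out_seq <- ifelse(clip3 > 0L, stringr::str_sub(seqs, 1, lens - clip3), seqs)

  clip5 <- integer(length(seqs))
  if (!is.null(config$adapter5)) {
    a5 <- normalize_seq(config$adapter5, "adapter5")
    lens2 <- nchar(out_seq)
    hi5 <- if (length(lens2)) min(nchar(a5), max(lens2)) else 0L
    for (L in if (hi5 >= mm) seq(hi5, mm) else integer(0)) {
      todo <- status == "kept" & clip5 == 0L & lens2 >= L
      if (!any(todo)) next
      hit <- stringr::str_sub(out_seq[todo], 1, L) == stringr::str_sub(a5, -L)
      clip5[todo][hit] <- L
    }
    out_seq <- ifelse(clip5 > 0L, stringr::str_sub(out_seq, clip5 + 1L), out_seq)
  }
  status[status == "kept" & nchar(out_seq) == 0L] <- "empty"

  out <- as_tibble(reads)
  out$seq <- ifelse(status == "kept", out_seq, seqs)
  out$clipped3 <- ifelse(status == "kept", clip3, 0L)
  out$clipped5 <- ifelse(status == "kept", clip5, 0L)
  out$status <- status
  out
}

#' Size-select clipped reads for one small RNA pool
#'
#' Retains reads whose post-clip length falls inclusively within the pool's
#' configured size window and labels every read with its fate.
#'
#' @param reads Output of [clip_adapters()].
#' @param pool One of the configured pool names (e.g. `"mirna"`).
#' @param config A [pipeline_config()].
#' @return The input tibble with a `pool` column and an updated `status`
#'   (`"kept"`, `"too_short"`, `"too_long"`, `"no_adapter"`, `"empty"`).
#' @export
size_filter <- function(reads, pool, config) {
  rng <- config$size_ranges[[pool]]
  if (is.null(rng)) abort(sprintf("no configured size range for pool '%s'", pool))
  out <- as_tibble(reads)
  if (!"status" %in% names(out)) out$status <- "kept"
  kept <- out$status == "kept"
  len <- nchar(out$seq)
  out$status[kept & len < rng[1]] <- "too_short"
  out$status[kept & len > rng[2]] <- "too_long"
  out$pool <- pool
  out
}

#' Tally preprocessing fates
#'
#' @param reads Output of [size_filter()] (or [clip_adapters()]).
#' @return One-row tibble with columns `kept`, `too_short`, `too_long`,
#'   `discarded_no_adapter`, `discarded_empty`, `total`. `total` always
#'   equals the input read count (conservation).
#' @export
preprocess_tally <- function(reads) {
  s <- reads$status
  tibble(kept = sum(s == "kept"),
         too_short = sum(s == "too_short"),
         too_long = sum(s == "too_long"),
         discarded_no_adapter = sum(s == "no_adapter"),
         discarded_empty = sum(s == "empty"),
         total = length(s))
}

#' Preprocess one pool end to end
#'
#' Convenience wrapper: [clip_adapters()] then [size_filter()].
#'
#' @inheritParams clip_adapters
#' @inheritParams size_filter
#' @return A list with `reads` (kept reads only, columns `id`, `seq`,
#'   `pool`, `clipped3`, `clipped5`), `all` (every input read with its
#'   fate), and `tally` (see [preprocess_tally()]).
#' @export
preprocess_reads <- function(reads, pool, config) {
  all <- size_filter(clip_adapters(reads, config), pool, config)
  kept <- dplyr::filter(all, .data$status == "kept")
  list(reads = select(kept, all_of(c("id", "seq", "pool", "clipped3", "clipped5"))),
       all = all,
       tally = preprocess_tally(all))
}
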