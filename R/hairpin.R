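# miRNA gene calling: fold a +/- flank window around every alignment,
# demand an unpaired terminal loop, a stem with >= 75% of its bases paired,
# and the read lying on a stem arm; a read is a bona fide miRNA iff at
# least one of its alignments passes.

#' Extract the folding window around an alignment
#'
#' The window is the hit plus `flank` bases on each side, clamped at contig
#' edges. For minus-strand hits the window is reverse-complemented so the
#' read lies on the folded strand, and the read offset is mirrored.
#'
#' @param hit One alignment: a one-row tibble or list with `contig`,
#'   `start`, `end`, `strand`.
#' @param genome Genome tibble (`id`, `seq`) or named character vector.
#' @param flank Bases of context on each side.
#' @return List with `window_seq`, `window_start`, `window_end` (genomic,
#'   forward strand), `read_start`, `read_end` (0-based window-relative,
#'   on the folded strand), `truncated`.
#' @export
extract_window <- function(hit, genome, flank = 50L) {
  contigs <- genome_vector(genome)
  seq <- contigs[[hit$contig]]
  if (is.null(seq)) abort(sprintf("contig '%s' not in genome", hit$contig))
  L <- nchar(seq)
  ws <- max(0L, hit$start - flank)
  we <- min(L, hit$end + flank)
  win <- substr(seq, ws + 1L, we)
  if (hit$strand == "-") {
    win <- revcomp(win)
    rs <- we - hit$end
    re <- we - hit$start
  } else {
    rs <- hit$start - ws
    re <- hit$end - ws
  }
  list(window_seq = win, window_start = ws, window_end = we,
       read_start = rs, read_end = re,
       truncated = (hit$start - flank < 0L) || (hit$end + flank > L))
}

#' Validate the hairpin criteria for one folded window
#'
#' Selects, among stem-loops whose span overlaps the read, the one with the
#' most pairs (ties to the 5'-most), then checks the three criteria: an
#' unpaired terminal loop, a stem paired fraction at or above
#' `min_stem_paired_frac`, and the read contained in the stem arms (at most
#' `loop_overhang` bases inside the terminal loop, none outside the
#' stem-loop span).
#'
#' @param fold A `srn_fold` from [fold_hairpin()].
#' @param read_start,read_end 0-based half-open read interval in window
#'   coordinates (see [extract_window()]).
#' @param config A [pipeline_config()].
#' @return One-row tibble: `has_loop`, `stem_frac_ok`, `read_in_stem`,
#'   `passed`, plus the selected stem-loop geometry (`outer5`, `inner5`,
#'   `inner3`, `outer3`, `n_pairs`, `loop_len`, `stem_paired_frac`; `NA`
#'   when no stem-loop overlaps the read).
#' @export
validate_hairpin <- function(fold, read_start, read_end, config = pipeline_config()) {
  sl <- parse_stemloops(fold)
  na_row <- tibble(has_loop = FALSE, stem_frac_ok = FALSE,
                   read_in_stem = FALSE, passed = FALSE,
                   outer5 = NA_integer_, inner5 = NA_integer_,
                   inner3 = NA_integer_, outer3 = NA_integer_,
                   n_pairs = NA_integer_, loop_len = NA_integer_,
                   stem_paired_frac = NA_real_)
  if (nrow(sl) == 0L) return(na_row)
  # stem-loops whose span overlaps the read (half-open read vs closed span)
  cand <- filter(sl, .data$outer5 < read_end, .data$outer3 + 1L > read_start)
  if (nrow(cand) == 0L) return(na_row)
  cand <- arrange(cand, dplyr::desc(.data$n_pairs), .data$outer5)
  s <- cand[1, ]
  read_pos <- seq(read_start, read_end - 1L)
  in_arm5 <- read_pos >= s$outer5 & read_pos <= s$inner5
  in_arm3 <- read_pos >= s$inner3 & read_pos <= s$outer3
  in_loop <- read_pos > s$inner5 & read_pos < s$inner3
  outside <- !(in_arm5 | in_arm3 | in_loop)
  has_loop <- s$loop_len >= config$min_loop_validate
  stem_frac_ok <- s$stem_paired_frac >= config$min_stem_paired_frac
  read_in_stem <- !any(outside) && sum(in_loop) <= config$loop_overhang
  tibble(has_loop = has_loop, stem_frac_ok = stem_frac_ok,
         read_in_stem = read_in_stem,
         passed = has_loop && stem_frac_ok && read_in_stem,
         outer5 = s$outer5, inner5 = s$inner5, inner3 = s$inner3,
         outer3 = s$outer3, n_pairs = s$n_pairs, loop_len = s$loop_len,
         stem_paired_frac = s$stem_paired_frac)
}

#' Call miRNA loci from mapped reads
#'
#' Folds the flanked window of every alignment and applies
#' [validate_hairpin()]. A read is bona fide iff at least one alignment
#' passes; passed windows overlapping on the same strand are merged into
#' loci. Reads that are not bona fide are returned for target calling, not
#' discarded.
#'
#' @param hits Alignment tibble from [map_reads()].
#' @param genome Genome tibble or named character vector.
#' @param config A [pipeline_config()].
#' @return A list of class `srn_mirna_calls`: `calls` (per-alignment
#'   verdicts), `bona_fide` (read ids), `non_hairpin` (read ids),
#'   `loci` (merged locus tibble with `n_reads` and `read_ids`).
#' @export
call_mirna_loci <- function(hits, genome, config = pipeline_config()) {
  contigs <- genome_vector(genome)
  fold_cache <- new.env(hash = TRUE, parent = emptyenv())
  rows <- purrr::map(seq_len(nrow(hits)), function(i) {
    hit <- as.list(hits[i, ])
    w <- extract_window(hit, contigs, config$hairpin_flank)
    fold <- get0(w$window_seq, envir = fold_cache)
    if (is.null(fold)) {
      fold <- fold_hairpin(w$window_seq, config)
      assign(w$window_seq, fold, envir = fold_cache)
    }
    v <- validate_hairpin(fold, w$read_start, w$read_end, config)
    dplyr::bind_cols(
      tibble(read_id = hit$read_id, contig = hit$contig,
             hit_start = hit$start, hit_end = hit$end, strand = hit$strand,
             window_start = w$window_start, window_end = w$window_end,
             truncated = w$truncated, dotbracket = fold$dotbracket),
      v)
  })
  calls <- bind_rows(rows)
  if (nrow(calls) == 0L) {
    calls <- tibble(read_id = character(0), contig = character(0),
                    hit_start = integer(0), hit_end = integer(0),
                    strand = character(0), window_start = integer(0),
                    window_end = integer(0), truncated = logical(0),
                    dotbracket = character(0), has_loop = logical(0),
                    stem_frac_ok = logical(0), read_in_stem = logical(0),
                    passed = logical(0))
  }
  bona_fide <- unique(calls$read_id[calls$passed])
  non_hairpin <- setdiff(unique(hits$read_id), bona_fide)
  loci <- merge_locus_windows(filter(calls, .data$passed))
  structure(list(calls = calls, bona_fide = bona_fide,
                 non_hairpin = non_hairpin, loci = loci),
            class = "srn_mirna_calls")
}

# merge passed windows that overlap (>= 1 bp) on the same contig + strand
merge_locus_windows <- function(passed) {
  if (nrow(passed) == 0L) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  strand = character(0), n_reads = integer(0),
                  read_ids = list(), stem_paired_frac = double(0),
                  dotbracket = character(0)))
  }
  passed <- arrange(passed, .data$contig, .data$strand, .data$window_start)
  grp_key <- paste(passed$contig, passed$strand)
  out <- list()
  for (k in unique(grp_key)) {
    g <- passed[grp_key == k, ]
    cur_start <- g$window_start[1]
    cur_end <- g$window_end[1]
    members <- 1L
    flush <- function(members, cur_start, cur_end) {
      m <- g[members, ]
      best <- which.max(m$stem_paired_frac)
      tibble(contig = m$contig[1], start = cur_start, end = cur_end,
             strand = m$strand[1],
             n_reads = dplyr::n_distinct(m$read_id),
             read_ids = list(sort(unique(m$read_id))),
             stem_paired_frac = m$stem_paired_frac[best],
             dotbracket = m$dotbracket[best])
    }
    for (i in seq_len(nrow(g))[-1]) {
      if (g$window_start[i] < cur_end) {
        cur_end <- max(cur_end, g$window_end[i])
        members <- c(members, i)
      } else {
        out[[length(out) + 1L]] <- flush(members, cur_start, cur_end)
        cur_start <- g$window_start[i]
        cur_end <- g$window_end[i]
        members <- i
      }
    }
    out[[length(out) + 1L]] <- flush(members, cur_start, cur_end)
  }
  arrange(bind_rows(out), .data$contig, .data$start, .data$strand)
}

#' @export
print.srn_mirna_calls <- function(x, ...) {
  cat("<srn_mirna_calls> ", nrow(x$calls), " alignment(s) inspected; ",
      length(x$bona_fide), " bona fide read(s); ",
      nrow(x$loci), " locus/loci\n", sep = "")
  invisible(x)
}

#' Compare a candidate hairpin to a reference collection
#'
#' A reference hairpin is considered when it shares at least one exact seed
#' of `ref_min_seed` bases with the candidate hairpin (either strand of the
#' candidate). The candidate's mature sequence is then slid ungapped across
#' the reference hairpin in both orientations; the hit qualifies when the
#' best identity reaches `ref_min_identity`. The best qualifying reference
#' is reported (max identity, ties to the longest shared seed, then the
#' lexicographically smallest id).
#'
#' @param hairpin Candidate hairpin sequence.
#' @param mature Candidate mature (sequenced read) sequence.
#' @param reference Tibble of reference hairpins with columns `id`, `seq`
#'   (e.g. from [read_sequences()]).
#' @param config A [pipeline_config()].
#' @return One-row tibble (`ref_id`, `identity`, `seed_len`) or a zero-row
#'   tibble when no reference qualifies.
#' @export
compare_to_reference <- function(hairpin, mature, reference,
                                 config = pipeline_config()) {
  stopifnot(is_string(hairpin), is_string(mature),
            is.data.frame(reference), all(c("id", "seq") %in% names(reference)))
  hairpin <- normalize_seq(hairpin, "candidate hairpin")
  mature <- normalize_seq(mature, "candidate mature")
  k0 <- config$ref_min_seed
  strands <- c(hairpin, revcomp(hairpin))
  none <- tibble(ref_id = character(0), identity = double(0),
                 seed_len = integer(0))
  rows <- purrr::map(seq_len(nrow(reference)), function(r) {
    ref <- reference$seq[r]
    seed <- max(longest_shared_substring(strands[1], ref, k0),
                longest_shared_substring(strands[2], ref, k0))
    if (seed < k0) return(NULL)
    ident <- max(best_slide_identity(mature, ref),
                 best_slide_identity(revcomp(mature), ref))
    if (ident < config$ref_min_identity) return(NULL)
    tibble(ref_id = reference$id[r], identity = ident, seed_len = seed)
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0L) return(none)
  best <- arrange(bind_rows(rows), dplyr::desc(.data$identity),
                  dplyr::desc(.data$seed_len), .data$ref_id)
  best[1, ]
}

# length of the longest substring shared by a and b, or 0 if below kmin
longest_shared_substring <- function(a, b, kmin) {
  hi <- min(nchar(a), nchar(b))
  if (hi < kmin) return(0L)
  shares_k <- function(k) any(seq_kmers(a, k) %in% seq_kmers(b, k))
  if (!shares_k(kmin)) return(0L)
  lo <- kmin
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (shares_k(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# best ungapped identity of `mature` against all windows of `ref`
best_slide_identity <- function(mature, ref) {
  m <- nchar(mature)
  R <- nchar(ref)
  if (R < m) return(0)
  best <- 0L
  for (s in 0:(R - m)) {
    mm <- hamming_n(mature, substr(ref, s + 1L, s + m))
    if (m - mm > best) best <- m - mm
  }
  best / m
}

#' Classify miRNA loci against gene annotations
#'
#' Classification is by at-least-1-bp overlap with gene annotations, with
#' precedence known miRNA gene > protein-coding overlap > pseudogene
#' overlap > intergenic. Gene biotypes are read from the feature
#' `class_label` (`"miRNA"` and `"pseudogene"` matched case-insensitively;
#' other gene features count as protein coding).
#'
#' @param loci Locus tibble with `contig`, `start`, `end` columns.
#' @param features Feature tibble (see [read_features()]).
#' @return `loci` with an added `classification` column.
#' @export
classify_loci <- function(loci, features) {
  genes <- filter(features, .data$kind %in% c("gene", "exon", "utr3", "utr5"))
  cls <- rep("intergenic", nrow(loci))
  if (nrow(genes) > 0L && nrow(loci) > 0L) {
    ov <- overlap_pairs(loci, genes)
    if (nrow(ov) > 0L) {
      biotype <- dplyr::case_when(
        grepl("mirna", genes$class_label[ov$.idx_b], ignore.case = TRUE) ~
          "known_mirna_gene",
        grepl("pseudogene", genes$class_label[ov$.idx_b], ignore.case = TRUE) ~
          "pseudogene_overlap",
        TRUE ~ "protein_coding_overlap")
      rank <- c(known_mirna_gene = 1L, protein_coding_overlap = 2L,
                pseudogene_overlap = 3L)
      agg <- summarise(group_by(tibble(idx = ov$.idx_a, r = rank[biotype]),
                                .data$idx),
                       r = min(.data$r), .groups = "drop")
      cls[agg$idx] <- names(rank)[agg$r]
    }
  }
  out <- as_tibble(loci)
  out$classification <- cls
  out
}
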