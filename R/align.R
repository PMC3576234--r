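# Exhaustive ungapped all-hits mapping with a bounded mismatch count: the
# "-v 1 -a" regime. map_reads() uses pigeonhole seeding (split the read in
# two halves; any placement with <= 1 mismatch carries at least one exact
# half, hence one exact leading k-mer) with full verification, so the hit
# set is exact, not heuristic. brute_force_map() is an independent
# whole-window scan used as the testing oracle. N on either side always
# counts as a mismatch. Minus-strand hits use forward-genome coordinates;
# the read equals the reverse complement of the genome window.

#' Build a k-mer index over a genome
#'
#' @param genome Tibble with columns `id`, `seq` (multi-contig FASTA as read
#'   by [read_sequences()]), or a named character vector.
#' @param k Seed length. Reads mapped against the index with at most one
#'   mismatch must be at least `2 * k` long for seeded lookup; shorter reads
#'   fall back to a full scan.
#' @return A `srn_index` object.
#' @export
build_index <- function(genome, k = 9L) {
  k <- as.integer(k)
  if (k < 1L) abort("k must be >= 1")
  contigs <- genome_vector(genome)
  if (anyDuplicated(names(contigs))) {
    abort(sprintf("duplicate contig id '%s'",
                  names(contigs)[duplicated(names(contigs))][1]))
  }
  kml <- list(); cil <- list(); posl <- list()
  for (ci in seq_along(contigs)) {
    km <- seq_kmers(contigs[[ci]], k)
    if (length(km) == 0L) next
    kml[[length(kml) + 1L]] <- km
    cil[[length(cil) + 1L]] <- rep.int(ci, length(km))
    posl[[length(posl) + 1L]] <- seq_along(km) - 1L
  }
  km <- unlist(kml) %||% character(0)
  env <- if (length(km)) {
    list2env(split(seq_along(km), km), hash = TRUE, parent = emptyenv())
  } else {
    new.env(hash = TRUE, parent = emptyenv())
  }
  structure(list(k = k, contigs = contigs,
                 ci = unlist(cil) %||% integer(0),
                 pos = unlist(posl) %||% integer(0),
                 table = env),
            class = "srn_index")
}

#' @export
print.srn_index <- function(x, ...) {
  cat("<srn_index> k =", x$k, "|", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp\n")
  invisible(x)
}

# row indices into index$ci / index$pos for one k-mer (integer(0) if absent)
index_lookup <- function(index, kmer) {
  get0(kmer, envir = index$table) %||% integer(0)
}

#' Map reads to a genome (all hits, bounded mismatches)
#'
#' Enumerates every ungapped placement of each read on both strands with at
#' most `config$max_mismatches` mismatches. All valid alignments are
#' reported; there is no per-read cap.
#'
#' @param reads Tibble with columns `id`, `seq`.
#' @param index A `srn_index` from [build_index()].
#' @param config A [pipeline_config()].
#' @return Tibble with columns `read_id`, `contig`, `start`, `end`,
#'   `strand`, `mismatches`, sorted by (read, contig, start, strand).
#' @export
map_reads <- function(reads, index, config = pipeline_config()) {
  stopifnot(inherits(index, "srn_index"),
            is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  max_mm <- config$max_mismatches
  out <- purrr::map(seq_len(nrow(reads)), function(i) {
    hits <- map_one_read(reads$seq[i], index, max_mm)
    if (nrow(hits)) hits$read_id <- reads$id[i]
    hits
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty_hits())
  arrange(select(res, all_of(hit_cols())), .data$read_id, .data$contig,
          .data$start, .data$strand)
}

hit_cols <- function() c("read_id", "contig", "start", "end", "strand", "mismatches")

empty_hits <- function() {
  tibble(read_id = character(0), contig = character(0), start = integer(0),
         end = integer(0), strand = character(0), mismatches = integer(0))
}

map_one_read <- function(seq, index, max_mm) {
  m <- nchar(seq)
  k <- index$k
  if (max_mm > 1L || m < 2L * k) {
    # pigeonhole with two halves is only sound for <= 1 mismatch and
    # reads spanning two seeds; otherwise scan every window directly
    return(scan_read(seq, index$contigs, max_mm))
  }
  rows <- list()
  contig_names <- names(index$contigs)
  contig_lens <- nchar(index$contigs)
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else revcomp(seq)
    f <- m %/% 2L
    # exact half => exact k-mer at half start
    cand_ci <- integer(0)
    cand_start <- integer(0)
    for (off in c(0L, f)) {
      rowsidx <- index_lookup(index, substr(q, off + 1L, off + k))
      if (length(rowsidx)) {
        cand_ci <- c(cand_ci, index$ci[rowsidx])
        cand_start <- c(cand_start, index$pos[rowsidx] - off)
      }
    }
    if (length(cand_ci) == 0L) next
    ok <- cand_start >= 0L & cand_start + m <= contig_lens[cand_ci]
    cand <- unique(cbind(ci = cand_ci[ok], start = cand_start[ok]))
    for (j in seq_len(nrow(cand))) {
      ci <- unname(cand[j, "ci"])
      st <- unname(cand[j, "start"])
      mm <- hamming_n(q, substr(index$contigs[[ci]], st + 1L, st + m))
      if (mm <= max_mm) {
        rows[[length(rows) + 1L]] <- tibble(
          contig = contig_names[ci], start = st, end = st + m,
          strand = strand, mismatches = as.integer(mm))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  bind_rows(rows)
}

# full-window scan of one read against all contigs (fallback path)
scan_read <- function(seq, contigs, max_mm) {
  rows <- list()
  m <- nchar(seq)
  for (cn in names(contigs)) {
    g <- contigs[[cn]]
    L <- nchar(g)
    if (L < m) next
    graw <- charToRaw(g)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else revcomp(seq)
      qraw <- charToRaw(q)
      mmv <- window_mismatches(graw, qraw)
      ok <- which(mmv <= max_mm)
      if (length(ok)) {
        rows[[length(rows) + 1L]] <- tibble(
          contig = cn, start = ok - 1L, end = ok - 1L + m, strand = strand,
          mismatches = as.integer(mmv[ok]))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  bind_rows(rows)
}

# mismatch count of the read (qraw) against every window of graw,
# N always mismatching; vectorised over windows
window_mismatches <- function(graw, qraw) {
  L <- length(graw)
  m <- length(qraw)
  nn <- as.raw(78L)
  nwin <- L - m + 1L
  mmv <- integer(nwin)
  for (j in seq_len(m)) {
    gj <- graw[j:(j + nwin - 1L)]
    mmv <- mmv + as.integer(gj != qraw[j] | gj == nn | qraw[j] == nn)
  }
  mmv
}

#' Brute-force read mapping (testing oracle)
#'
#' Scans every window of every contig on both strands directly, with no
#' index or seeding. Defines the ground-truth hit set for [map_reads()].
#'
#' @inheritParams map_reads
#' @param genome Tibble with columns `id`, `seq`, or named character vector.
#' @return Same schema as [map_reads()].
#' @export
brute_force_map <- function(reads, genome, config = pipeline_config()) {
  contigs <- genome_vector(genome)
  out <- purrr::map(seq_len(nrow(reads)), function(i) {
    hits <- scan_read(reads$seq[i], contigs, config$max_mismatches)
    if (nrow(hits)) hits$read_id <- reads$id[i]
    hits
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty_hits())
  arrange(select(res, all_of(hit_cols())), .data$read_id, .data$contig,
          .data$start, .data$strand)
}
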