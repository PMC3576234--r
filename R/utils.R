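# Internal helpers shared across modules. Sequences are plain uppercase
# character strings over {A,C,G,T,N}; intervals are 0-based half-open.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Vectorised over `x`. `N` is preserved as `N`. Input must already be
#' uppercase DNA (as produced by [read_sequences()]).
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# uppercase + U->T normalization, with alphabet validation
normalize_seq <- function(x, context = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- stringr::str_detect(x, "[^ACGTN]")
  if (any(bad)) {
    sym <- stringr::str_extract(x[bad][1], "[^ACGTN]")
    abort(sprintf("invalid symbol '%s' in %s", sym, context))
  }
  x
}

# Hamming distance where N on either side always counts as a mismatch.
# a and b must be equal-length strings.
hamming_n <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  nn <- as.raw(78L) # "N"
  sum(ra != rb | ra == nn | rb == nn)
}

# split one sequence into its overlapping k-mers (character vector)
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, seq_len(L - k + 1L), seq(k, L))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# deterministic 31-bit hash of a string key, for per-locus child seeds
str_hash31 <- function(key) {
  v <- utf8ToInt(key)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# child seed derived from a global seed and a string key; order-independent
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 7919 + str_hash31(key)) %% 2147483647)
}

# genome tibble (id, seq) -> named character vector
genome_vector <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome character vector must be named by contig")
    return(genome)
  }
  if (is.list(genome) && !is.data.frame(genome)) {
    if (is.null(names(genome))) abort("genome list must be named by contig")
    return(unlist(genome))
  }
  stopifnot(is.data.frame(genome), all(c("id", "seq") %in% names(genome)))
  setNames(genome$seq, genome$id)
}

# overlap join between two 0-based half-open interval tables, per contig
# (and optionally per strand). Returns tibble with .idx_a / .idx_b row indices.
overlap_pairs <- function(a, b, by_strand = FALSE) {
  stopifnot(all(c("contig", "start", "end") %in% names(a)),
            all(c("contig", "start", "end") %in% names(b)))
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(.idx_a = integer(0), .idx_b = integer(0)))
  }
  key_a <- if (by_strand) paste(a$contig, a$strand) else a$contig
  key_b <- if (by_strand) paste(b$contig, b$strand) else b$contig
  out <- vector("list", 0L)
  for (k in intersect(unique(key_a), unique(key_b))) {
    ia <- which(key_a == k)
    ib <- which(key_b == k)
    # IRanges is 1-based closed: [start+1, end]
    ra <- IRanges::IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    rb <- IRanges::IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb, minoverlap = 1L)
    out[[length(out) + 1L]] <- tibble(
      .idx_a = ia[S4Vectors::queryHits(ov)],
      .idx_b = ib[S4Vectors::subjectHits(ov)]
    )
  }
  if (length(out) == 0L) return(tibble(.idx_a = integer(0), .idx_b = integer(0)))
  bind_rows(out)
}
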