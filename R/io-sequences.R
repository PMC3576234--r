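#' Read sequences from FASTA or FASTQ
#'
#' Records are returned in file order as a tibble. Sequences are normalised
#' to uppercase DNA with `U -> T`; the alphabet is restricted to
#' `{A,C,G,T,N}`. FASTQ quality strings must match the sequence length
#' (Sanger encoding is assumed and carried through untouched).
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by file extension).
#' @return A tibble with columns `id`, `seq`, and (FASTQ only) `qual`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgu"), fa)
#' read_sequences(fa)
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  if (format == "fastq") {
    # Biostrings does not validate quality lengths; check the 4-line
    # records up front so malformed files fail with a line number
    lines <- readLines(path, warn = FALSE)
    if (length(lines) %% 4L != 0L) {
      abort(sprintf("truncated FASTQ record at end of %s", path))
    }
    seq_lines <- lines[seq(2L, length(lines), by = 4L)]
    qual_lines <- lines[seq(4L, length(lines), by = 4L)]
    bad <- nchar(qual_lines) != nchar(seq_lines)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "FASTQ quality length != sequence length for record %d, near line %d of %s",
        i, 4L * (i - 1L) + 1L, path))
    }
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) abort(sprintf("malformed %s file '%s': %s",
                                      format, path, conditionMessage(e)))
  )
  ids <- names(set) %||% character(0)
  ids <- sub("\\s.*$", "", ids)
  seqs <- as.character(set)
  n <- length(seqs)
  if (n == 0L) {
    out <- tibble(id = character(0), seq = character(0))
    if (format == "fastq") out$qual <- character(0)
    return(out)
  }
  lens <- nchar(seqs)
  if (any(lens == 0L)) {
    i <- which(lens == 0L)[1]
    abort(sprintf("empty sequence for record %d ('%s') in %s", i, ids[i], path))
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("duplicate record id '%s' in %s", dup, path))
  }
  out <- tibble(id = ids, seq = normalize_seq(unname(seqs), context = path))
  if (format == "fastq") {
    qual <- as.character(S4Vectors::mcols(set)$qualities)
    bad <- nchar(qual) != lens
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "FASTQ quality length != sequence length for record %d ('%s'), near line %d of %s",
        i, ids[i], 4L * (i - 1L) + 1L, path))
    }
    out$qual <- unname(qual)
  }
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Tibble with columns `id`, `seq` and, for FASTQ, `qual`.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", seqs$id), seqs$seq))
  } else {
    if (!"qual" %in% names(seqs)) abort("FASTQ output requires a 'qual' column")
    if (any(nchar(seqs$qual) != nchar(seqs$seq))) {
      abort("quality length != sequence length")
    }
    lines <- as.vector(rbind(paste0("@", seqs$id), seqs$seq, "+", seqs$qual))
  }
  writeLines(lines, path)
  invisible(path)
}
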