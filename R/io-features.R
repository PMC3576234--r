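# Feature annotation I/O. Internal coordinates are 0-based half-open;
# GFF3 (1-based closed) and RepeatMasker .out (1-based closed) are converted
# at this boundary only. BED is kept as-is.

FEATURE_KINDS <- c("gene", "exon", "utr3", "utr5", "repeat", "peak", "other")

# kind <-> GFF3 type column
GFF3_TYPE_OF_KIND <- c(gene = "gene", exon = "exon",
                       utr3 = "three_prime_UTR", utr5 = "five_prime_UTR",
                       "repeat" = "repeat_region", peak = "peak",
                       other = "region")

kind_of_gff3_type <- function(type) {
  map <- setNames(names(GFF3_TYPE_OF_KIND), GFF3_TYPE_OF_KIND)
  out <- unname(map[type])
  out[is.na(out)] <- "other"
  out
}

empty_features <- function() {
  tibble(contig = character(0), start = integer(0), end = integer(0),
         strand = character(0), kind = character(0), name = character(0),
         class_label = character(0))
}

check_feature_coords <- function(start, end, path, one_based = FALSE) {
  bad <- if (one_based) {
    is.na(start) | is.na(end) | start < 1L | end < start
  } else {
    is.na(start) | is.na(end) | start < 0L | end <= start
  }
  if (any(bad)) {
    abort(sprintf("negative or reversed coordinates at row %d of %s",
                  which(bad)[1], path))
  }
}

#' Read genomic features (BED, GFF3 or RepeatMasker .out)
#'
#' All dialects are normalised to a single tibble schema with 0-based
#' half-open coordinates: BED is taken as-is, GFF3 converts `start - 1`,
#' and RepeatMasker `.out` rows become `kind = "repeat"` with the
#' class/family column as `class_label` (strand `C` becomes `-`).
#'
#' @param path Input file.
#' @param dialect One of `"bed"`, `"gff3"`, `"rmout"`.
#' @param kind Feature kind assigned to BED rows (BED carries no type).
#' @return Tibble with columns `contig`, `start`, `end`, `strand`, `kind`,
#'   `name`, `class_label`.
#' @export
read_features <- function(path, dialect = c("bed", "gff3", "rmout"),
                          kind = "other") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  switch(dialect,
         bed = parse_bed(lines, path, kind),
         gff3 = parse_gff3(lines, path),
         rmout = parse_rmout(lines, path))
}

parse_bed <- function(lines, path, kind) {
  lines <- lines[!grepl("^(#|track|browser)|^\\s*$", lines)]
  if (length(lines) == 0L) return(empty_features())
  if (!kind %in% FEATURE_KINDS) abort(sprintf("unknown feature kind '%s'", kind))
  f <- stringr::str_split(lines, "\t")
  ncol <- lengths(f)
  if (any(ncol < 3L)) {
    abort(sprintf("BED row %d of %s has fewer than 3 columns",
                  which(ncol < 3L)[1], path))
  }
  col <- function(i, default = NA_character_) {
    vapply(f, function(x) if (length(x) >= i) x[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  check_feature_coords(start, end, path)
  name <- col(4)
  name[is.na(name) | name == "."] <- ""
  strand <- col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  # class label ride-along: "name::class" in the BED name column
  cls <- ifelse(grepl("::", name), sub("^.*::", "", name), "")
  name <- sub("::.*$", "", name)
  tibble(contig = col(1), start = start, end = end, strand = strand,
         kind = kind, name = name, class_label = cls)
}

parse_gff3 <- function(lines, path) {
  lines <- lines[!grepl("^#|^\\s*$", lines)]
  if (length(lines) == 0L) return(empty_features())
  f <- stringr::str_split(lines, "\t")
  if (any(lengths(f) != 9L)) {
    abort(sprintf("GFF3 row %d of %s does not have 9 columns",
                  which(lengths(f) != 9L)[1], path))
  }
  m <- do.call(rbind, f)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  check_feature_coords(start1, end1, path, one_based = TRUE)
  strand <- m[, 7]
  strand[!strand %in% c("+", "-")] <- "."
  attr_field <- function(attrs, key) {
    v <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    v[is.na(v)] <- ""
    v
  }
  name <- attr_field(m[, 9], "Name")
  id <- attr_field(m[, 9], "ID")
  name <- ifelse(name == "", id, name)
  tibble(contig = m[, 1],
         start = start1 - 1L, end = end1,
         strand = strand,
         kind = kind_of_gff3_type(m[, 3]),
         name = name,
         class_label = attr_field(m[, 9], "class"))
}

parse_rmout <- function(lines, path) {
  # RepeatMasker .out: 3 header lines, then whitespace-separated columns:
  # score div del ins query qbegin qend qleft strand repeat class/family ...
  body <- lines[-seq_len(min(3L, length(lines)))]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) == 0L) return(empty_features())
  f <- stringr::str_split(stringr::str_trim(body), "\\s+")
  if (any(lengths(f) < 11L)) {
    abort(sprintf("RepeatMasker row %d of %s has fewer than 11 columns",
                  which(lengths(f) < 11L)[1], path))
  }
  m <- t(vapply(f, function(x) x[1:11], character(11)))
  start1 <- suppressWarnings(as.integer(m[, 6]))
  end1 <- suppressWarnings(as.integer(m[, 7]))
  check_feature_coords(start1, end1, path, one_based = TRUE)
  tibble(contig = m[, 5],
         start = start1 - 1L, end = end1,
         strand = ifelse(m[, 9] %in% c("C", "-"), "-",
                         ifelse(m[, 9] == "+", "+", ".")),
         kind = "repeat",
         name = m[, 10],
         class_label = m[, 11])
}

#' Write genomic features to BED or GFF3
#'
#' Inverse of [read_features()]: GFF3 output converts back to 1-based
#' closed coordinates; BED output stores `name::class_label` in the name
#' column when a class label is present so that a round trip preserves it.
#'
#' @param features Feature tibble (see [read_features()] for the schema).
#' @param path Output path.
#' @param dialect `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(features))
  f <- features
  if (dialect == "bed") {
    nm <- ifelse(f$class_label == "", f$name,
                 paste0(f$name, "::", f$class_label))
    nm[nm == ""] <- "."
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     f$contig, f$start, f$end, nm, 0L, f$strand)
  } else {
    attrs <- sprintf("ID=%s;Name=%s", f$name, f$name)
    attrs[f$name == ""] <- "."
    has_cls <- f$class_label != ""
    attrs[has_cls] <- paste0(attrs[has_cls], ";class=", f$class_label[has_cls])
    lines <- sprintf("%s\tsrnakit\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     f$contig, GFF3_TYPE_OF_KIND[f$kind],
                     f$start + 1L, f$end, f$strand, attrs)
    lines <- c("##gff-version 3", lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular report
#'
#' Deterministic TSV output: header line, UTF-8, `\n`-terminated, and
#' byte-identical for identical input rows. Accepts a data frame or a list
#' of same-schema named lists (mixed schemas are an error).
#'
#' @param rows A data frame, or a list of named lists sharing one schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) abort("rows must be a data frame or list of rows")
    if (length(rows) == 0L) abort("cannot infer a schema from an empty list; pass a data frame")
    schema <- names(rows[[1]])
    same <- vapply(rows, function(r) identical(names(r), schema), logical(1))
    if (!all(same)) abort("rows do not share one schema")
    rows <- bind_rows(lapply(rows, as_tibble))
  }
  rows <- as_tibble(rows)
  listcols <- vapply(rows, is.list, logical(1))
  for (cn in names(rows)[listcols]) {
    rows[[cn]] <- vapply(rows[[cn]], function(x) paste(x, collapse = ","),
                         character(1))
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(vapply(rows[i, ], format_report_cell, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(names(rows), collapse = "\t"), body), con, sep = "\n")
  invisible(path)
}

format_report_cell <- function(x) {
  x <- x[[1]]
  if (is.double(x)) {
    if (is.na(x)) return("NA")
    if (x == round(x) && abs(x) < 1e15) return(sprintf("%.0f", x))
    return(sprintf("%.6g", x))
  }
  as.character(x)
}
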