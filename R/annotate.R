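# Gene-model expansion, target calling, repeat association, pool
# comparison, read-peak clustering, and ChIP-enrichment overlap. Every
# overlap here is the >= 1 bp rule on 0-based half-open intervals.

#' Expand incomplete gene models to approximate missing UTRs
#'
#' Genes lacking an annotated UTR are extended by `flank` bases on the
#' corresponding transcriptional side (strand-aware: a missing 5' UTR
#' extends the genomic left end for `+` genes and the right end for `-`
#' genes), clamped to the contig.
#'
#' @param genes Tibble with `contig`, `start`, `end`, `strand`, `name`, and
#'   logical columns `has_utr5`, `has_utr3` (absent columns default to
#'   `FALSE`, i.e. expand both sides).
#' @param contig_lengths Named integer vector of contig lengths, or a
#'   genome tibble (`id`, `seq`).
#' @param flank Expansion per missing UTR (bp).
#' @return The input tibble with updated `start`/`end`.
#' @export
expand_gene_models <- function(genes, contig_lengths, flank = 1000L) {
  g <- as_tibble(genes)
  if (is.data.frame(contig_lengths)) {
    contig_lengths <- setNames(nchar(contig_lengths$seq), contig_lengths$id)
  }
  if (!"has_utr5" %in% names(g)) g$has_utr5 <- FALSE
  if (!"has_utr3" %in% names(g)) g$has_utr3 <- FALSE
  if (nrow(g) == 0L) return(g)
  if (any(!g$contig %in% names(contig_lengths))) {
    abort("gene contig missing from contig_lengths")
  }
  minus <- g$strand == "-"
  # transcriptional 5' side is genomic left for "+", right for "-"
  expand_left <- ifelse(minus, !g$has_utr3, !g$has_utr5)
  expand_right <- ifelse(minus, !g$has_utr5, !g$has_utr3)
  g$start <- pmax(0L, g$start - ifelse(expand_left, flank, 0L))
  g$end <- pmin(unname(contig_lengths[g$contig]),
                g$end + ifelse(expand_right, flank, 0L))
  g
}

#' Call small RNA target genes
#'
#' A hit supports a gene when it overlaps the (expanded) gene model by at
#' least one base. Support is counted in unique read sequences: identical
#' sequences collapse to one, so PCR/sequencing duplicates do not inflate
#' target support.
#'
#' @param hits Alignment tibble restricted to non-hairpin reads (see
#'   [call_mirna_loci()]).
#' @param genes Expanded gene models ([expand_gene_models()]).
#' @param reads Read tibble (`id`, `seq`) used to collapse identical
#'   sequences.
#' @param pool Pool label recorded on each target record.
#' @return Tibble with one row per targeted gene: `gene_name`, `pool`,
#'   `unique_read_count`, `read_ids` (list column).
#' @export
call_targets <- function(hits, genes, reads, pool = "mirna") {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  empty <- tibble(gene_name = character(0), pool = character(0),
                  unique_read_count = integer(0), read_ids = list())
  if (nrow(hits) == 0L || nrow(genes) == 0L) return(empty)
  ov <- overlap_pairs(hits, genes)
  if (nrow(ov) == 0L) return(empty)
  sup <- tibble(gene_name = genes$name[ov$.idx_b],
                read_id = hits$read_id[ov$.idx_a])
  sup <- left_join(distinct(sup), select(reads, read_id = "id", "seq"),
                   by = "read_id")
  if (anyNA(sup$seq)) abort("hit read_id missing from reads table")
  out <- summarise(group_by(sup, .data$gene_name),
                   unique_read_count = dplyr::n_distinct(.data$seq),
                   read_ids = list(sort(unique(.data$read_id))),
                   .groups = "drop")
  out$pool <- pool
  arrange(select(out, all_of(c("gene_name", "pool", "unique_read_count",
                               "read_ids"))), .data$gene_name)
}

#' Cross-pool target matrix
#'
#' Genes by pools matrix of unique read counts, with a row-normalised copy
#' (each row divided by its maximum; all-zero rows stay zero).
#'
#' @param records Target records from [call_targets()], one or more pools
#'   bound together.
#' @return List with `counts` and `normalized` tibbles (first column
#'   `gene_name`, one column per pool).
#' @export
target_matrix <- function(records) {
  if (nrow(records) == 0L) abort("no target records")
  wide <- tidyr::pivot_wider(
    select(records, all_of(c("gene_name", "pool", "unique_read_count"))),
    names_from = "pool", values_from = "unique_read_count", values_fill = 0L)
  wide <- arrange(wide, .data$gene_name)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rmax <- apply(m, 1, max)
  norm <- sweep(m, 1, ifelse(rmax == 0, 1, rmax), "/")
  list(counts = wide,
       normalized = dplyr::bind_cols(wide[, 1], as_tibble(norm)))
}

#' Associate pool reads with repeat annotations
#'
#' A read is associated with every repeat class any of its alignments
#' overlaps by at least one base; multi-mapping reads may therefore carry
#' several classes, and each (read, class) assignment contributes once to
#' the class distribution.
#'
#' @param hits Alignment tibble.
#' @param repeats Feature tibble with `kind == "repeat"` rows.
#' @return List with `associations` (per read: `read_id`, `class_labels`
#'   list column) and `distribution` (`class_label`, `n_reads`, `percent`;
#'   percentages over all (read, class) assignments, summing to 100).
#' @export
associate_repeats <- function(hits, repeats) {
  repeats <- filter(repeats, .data$kind == "repeat")
  empty <- list(
    associations = tibble(read_id = character(0), class_labels = list()),
    distribution = tibble(class_label = character(0), n_reads = integer(0),
                          percent = double(0)))
  if (nrow(hits) == 0L || nrow(repeats) == 0L) return(empty)
  ov <- overlap_pairs(hits, repeats)
  if (nrow(ov) == 0L) return(empty)
  asg <- distinct(tibble(read_id = hits$read_id[ov$.idx_a],
                         class_label = repeats$class_label[ov$.idx_b]))
  associations <- summarise(group_by(asg, .data$read_id),
                            class_labels = list(sort(unique(.data$class_label))),
                            .groups = "drop")
  dist <- count(asg, .data$class_label, name = "n_reads")
  dist$percent <- 100 * dist$n_reads / sum(dist$n_reads)
  list(associations = arrange(associations, .data$read_id),
       distribution = arrange(dist, dplyr::desc(.data$n_reads),
                              .data$class_label))
}

#' Compare two mapped small RNA pools by locus overlap
#'
#' Reports every (read A, read B) pair whose alignments share at least one
#' base on the same contig and strand, both pools having been mapped under
#' the same configuration.
#'
#' @param hits_a,hits_b Alignment tibbles for the two pools.
#' @return List with `pairs` (`read_a`, `read_b`) and `summary`
#'   (`n_reads_a`, `n_reads_b`: distinct reads of each pool in >= 1 pair).
#' @export
compare_pools <- function(hits_a, hits_b) {
  ov <- overlap_pairs(hits_a, hits_b, by_strand = TRUE)
  pairs <- distinct(tibble(read_a = hits_a$read_id[ov$.idx_a],
                           read_b = hits_b$read_id[ov$.idx_b]))
  list(pairs = arrange(pairs, .data$read_a, .data$read_b),
       summary = tibble(n_reads_a = dplyr::n_distinct(pairs$read_a),
                        n_reads_b = dplyr::n_distinct(pairs$read_b)))
}

#' Cluster alignments into read peaks
#'
#' Single-linkage merge of alignment intervals on each contig (strands
#' pooled): two alignments join one peak when separated by at most
#' `peak_max_gap` bases; clusters supported by fewer than `peak_min_reads`
#' alignments are dropped. The peak span is the member minimum start to
#' maximum end.
#'
#' @param hits Alignment tibble.
#' @param config A [pipeline_config()].
#' @return Peak tibble: `contig`, `start`, `end`, `n_reads`.
#' @export
cluster_peaks <- function(hits, config = pipeline_config()) {
  empty <- tibble(contig = character(0), start = integer(0), end = integer(0),
                  n_reads = integer(0))
  if (nrow(hits) == 0L) return(empty)
  h <- arrange(as_tibble(hits), .data$contig, .data$start, .data$end)
  out <- list()
  for (cn in unique(h$contig)) {
    g <- h[h$contig == cn, ]
    cur_start <- g$start[1]; cur_end <- g$end[1]; n <- 1L
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] <= cur_end + config$peak_max_gap) {
        cur_end <- max(cur_end, g$end[i])
        n <- n + 1L
      } else {
        out[[length(out) + 1L]] <- tibble(contig = cn, start = cur_start,
                                          end = cur_end, n_reads = n)
        cur_start <- g$start[i]; cur_end <- g$end[i]; n <- 1L
      }
    }
    out[[length(out) + 1L]] <- tibble(contig = cn, start = cur_start,
                                      end = cur_end, n_reads = n)
  }
  peaks <- filter(bind_rows(out), .data$n_reads >= config$peak_min_reads)
  arrange(peaks, .data$contig, .data$start)
}

#' Overlap read peaks with enrichment intervals
#'
#' Flags each peak that overlaps at least one enrichment interval (e.g.
#' CENP-A ChIP peaks consumed as BED) by at least one base.
#'
#' @param peaks Peak tibble from [cluster_peaks()].
#' @param enrichment Feature tibble of enrichment intervals.
#' @return List with `n_overlapping`, `n_total`, and `peaks` (the input
#'   with an added logical `overlaps_enrichment`).
#' @export
overlap_peaks <- function(peaks, enrichment) {
  flags <- rep(FALSE, nrow(peaks))
  if (nrow(peaks) > 0L && nrow(enrichment) > 0L) {
    ov <- overlap_pairs(peaks, enrichment)
    flags[unique(ov$.idx_a)] <- TRUE
  }
  out <- as_tibble(peaks)
  out$overlaps_enrichment <- flags
  list(n_overlapping = sum(flags), n_total = nrow(out), peaks = out)
}
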