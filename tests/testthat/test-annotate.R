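cfg <- pipeline_config(adapter3 = "TCGTATGCCG")

test_that("gene-model expansion is strand-aware and clamps to the contig", {
  cl <- c(c1 = 10000L, c2 = 1000L)
  g <- tibble::tibble(contig = "c1", start = 5000L, end = 8000L,
                      strand = "+", name = "g1",
                      has_utr5 = FALSE, has_utr3 = FALSE)
  expect_equal(unlist(expand_gene_models(g, cl)[, c("start", "end")]),
               c(start = 4000L, end = 9000L))

  # clamped at both contig edges
  g2 <- tibble::tibble(contig = "c2", start = 300L, end = 900L, strand = "+",
                       name = "g2", has_utr5 = FALSE, has_utr3 = FALSE)
  expect_equal(unlist(expand_gene_models(g2, cl)[, c("start", "end")]),
               c(start = 0L, end = 1000L))

  # minus-strand gene missing only its 3' UTR expands on the genomic left
  g3 <- tibble::tibble(contig = "c1", start = 5000L, end = 8000L,
                       strand = "-", name = "g3",
                       has_utr5 = TRUE, has_utr3 = FALSE)
  expect_equal(unlist(expand_gene_models(g3, cl)[, c("start", "end")]),
               c(start = 4000L, end = 8000L))

  # idempotent once UTR flags are updated
  once <- expand_gene_models(g, cl)
  once$has_utr5 <- TRUE
  once$has_utr3 <- TRUE
  expect_equal(expand_gene_models(once, cl)$start, once$start)
  expect_true(all(expand_gene_models(g, cl)$start >= 0L))
})

test_that("target calling collapses identical read sequences", {
  genes <- tibble::tibble(contig = "c", start = c(1000L, 5000L),
                          end = c(3000L, 7000L), strand = "+",
                          name = c("gA", "gB"))
  reads <- tibble::tibble(id = c("r1", "r2", "r3", "r4"),
                          seq = c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                                  "TTTTACGTACGTACGTAC", "GGGGACGTACGTACGTAC"))
  hits <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    contig = "c",
    start = c(1100L, 1500L, 2000L, 8000L),
    end = c(1118L, 1518L, 2018L, 8018L),
    strand = "+", mismatches = 0L)
  tg <- call_targets(hits, genes, reads, pool = "mirna")
  expect_equal(nrow(tg), 1L) # only gA is hit
  expect_equal(tg$gene_name, "gA")
  # r1 and r2 share one sequence -> 2 unique sequences support gA
  expect_equal(tg$unique_read_count, 2L)
  expect_setequal(tg$read_ids[[1]], c("r1", "r2", "r3"))
})

test_that("target matrix row-normalises by the row maximum", {
  recs <- dplyr::bind_rows(
    tibble::tibble(gene_name = "Lrtm1", pool = "tammar",
                   unique_read_count = 69L, read_ids = list("x")),
    tibble::tibble(gene_name = "Lrtm1", pool = "mouse",
                   unique_read_count = 49L, read_ids = list("x")),
    tibble::tibble(gene_name = "Lrtm1", pool = "human",
                   unique_read_count = 3L, read_ids = list("x")),
    tibble::tibble(gene_name = "zero", pool = "tammar",
                   unique_read_count = 0L, read_ids = list("x")))
  tm <- target_matrix(recs)
  row <- dplyr::filter(tm$normalized, gene_name == "Lrtm1")
  expect_equal(row$tammar, 1.0)
  expect_equal(row$mouse, 49 / 69, tolerance = 1e-12)
  expect_equal(row$human, 3 / 69, tolerance = 1e-12)
  zero <- dplyr::filter(tm$normalized, gene_name == "zero")
  expect_true(all(unlist(zero[, -1]) == 0))
})

test_that("repeat association uses the one-base overlap rule and multi-class reads", {
  reps <- tibble::tibble(contig = "c",
                         start = c(110L, 50L, 300L),
                         end = c(200L, 105L, 400L),
                         strand = c("+", "+", "-"), kind = "repeat",
                         name = c("L1", "MIR", "hAT"),
                         class_label = c("LINE/L1", "SINE/MIR", "DNA/hAT"))
  hits <- tibble::tibble(
    read_id = c("r1", "r1", "r2", "r3"),
    contig = "c",
    start = c(100L, 95L, 200L, 395L),
    end = c(120L, 115L, 300L, 430L),
    strand = "+", mismatches = 0L)
  out <- associate_repeats(hits, reps)
  a <- out$associations
  expect_equal(a$class_labels[[match("r1", a$read_id)]],
               c("LINE/L1", "SINE/MIR"))
  # r2 abuts the hAT repeat end-to-start: no shared base, no association
  expect_false("r2" %in% a$read_id)
  expect_true("r3" %in% a$read_id)
  expect_equal(sum(out$distribution$percent), 100)
})

test_that("pool comparison pairs reads by same-strand locus overlap", {
  one_a <- tibble::tibble(read_id = "a", contig = "c", start = 100L,
                          end = 136L, strand = "+", mismatches = 0L)
  one_b <- tibble::tibble(read_id = "b", contig = "c", start = 120L,
                          end = 150L, strand = "+", mismatches = 0L)
  cmp <- compare_pools(one_a, one_b)
  expect_equal(nrow(cmp$pairs), 1L)
  expect_equal(unlist(cmp$summary), c(n_reads_a = 1L, n_reads_b = 1L))

  # disjoint pools and opposite strands give nothing
  far <- dplyr::mutate(one_b, start = 5000L, end = 5030L)
  expect_equal(nrow(compare_pools(one_a, far)$pairs), 0L)
  flip <- dplyr::mutate(one_b, strand = "-")
  expect_equal(nrow(compare_pools(one_a, flip)$pairs), 0L)

  # 3 crasi reads over 2 pi reads at one locus -> counts (3, 2)
  crasi <- tibble::tibble(read_id = c("c1", "c2", "c3"), contig = "c",
                          start = c(100L, 105L, 110L),
                          end = c(140L, 145L, 150L), strand = "+",
                          mismatches = 0L)
  pi <- tibble::tibble(read_id = c("p1", "p2"), contig = "c",
                       start = c(120L, 130L), end = c(150L, 160L),
                       strand = "+", mismatches = 0L)
  s <- compare_pools(crasi, pi)$summary
  expect_equal(unlist(s), c(n_reads_a = 3L, n_reads_b = 2L))
})

test_that("peak clustering merges by gap and applies the read floor", {
  hits <- tibble::tibble(read_id = c("a", "b", "c"), contig = "c",
                         start = c(0L, 10L, 100L), end = c(36L, 46L, 140L),
                         strand = "+", mismatches = 0L)
  p1 <- cluster_peaks(hits, pipeline_config(peak_min_reads = 1L))
  expect_equal(nrow(p1), 2L)
  p2 <- cluster_peaks(hits, cfg) # min_reads 2
  expect_equal(nrow(p2), 1L)
  expect_equal(unlist(p2[, c("start", "end", "n_reads")]),
               c(start = 0L, end = 46L, n_reads = 2L))
})

test_that("peak/enrichment overlap flags by >= 1 shared base and contig", {
  peaks <- tibble::tibble(contig = c("c1", "c1", "c2"),
                          start = c(100L, 500L, 100L),
                          end = c(150L, 550L, 150L), n_reads = 3L)
  enrich <- tibble::tibble(contig = c("c1", "c3"), start = c(90L, 100L),
                           end = c(200L, 150L), strand = ".", kind = "peak",
                           name = "", class_label = "")
  out <- overlap_peaks(peaks, enrich)
  expect_equal(out$n_total, 3L)
  expect_equal(out$n_overlapping, 1L)
  expect_equal(out$peaks$overlaps_enrichment, c(TRUE, FALSE, FALSE))
})

test_that("interval operations agree with quadratic oracles on random fixtures", {
  withr::local_seed(202)
  a <- random_intervals(120)
  b <- random_intervals(150)
  got <- srnakit:::overlap_pairs(a, b)
  want <- oracle_overlap_pairs(a, b)
  expect_equal(sort(paste(got$.idx_a, got$.idx_b)), sort(paste(want$i, want$j)))

  gs <- srnakit:::overlap_pairs(a, b, by_strand = TRUE)
  ws <- oracle_overlap_pairs(a, b, by_strand = TRUE)
  expect_equal(sort(paste(gs$.idx_a, gs$.idx_b)), sort(paste(ws$i, ws$j)))

  # clustering vs the O(n^2) chaining oracle, several gap widths
  hits <- random_intervals(150, max_pos = 2000L, max_len = 40L)
  hits$read_id <- sprintf("r%d", seq_len(nrow(hits)))
  hits$mismatches <- 0L
  for (gap in c(0L, 5L, 50L)) {
    c2 <- pipeline_config(peak_min_reads = 1L,
                          peak_max_gap = gap)
    got <- as.data.frame(cluster_peaks(hits, c2))
    want <- oracle_cluster(as.data.frame(hits), gap)
    expect_equal(got, want)
  }
})
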