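cfg <- pipeline_config(adapter3 = "TCGTATGCCG")

test_that("window extraction is strand-aware and clamps at contig edges", {
  genome <- tibble::tibble(id = "c", seq = rand_dna(1000))
  w <- extract_window(list(contig = "c", start = 100L, end = 122L,
                           strand = "+"), genome, flank = 50L)
  expect_equal(w$window_start, 50L)
  expect_equal(w$window_end, 172L)
  expect_equal(c(w$read_start, w$read_end), c(50L, 72L))
  expect_false(w$truncated)

  e <- extract_window(list(contig = "c", start = 10L, end = 32L,
                           strand = "+"), genome, flank = 50L)
  expect_equal(c(e$window_start, e$window_end), c(0L, 82L))
  expect_true(e$truncated)

  m <- extract_window(list(contig = "c", start = 100L, end = 122L,
                           strand = "-"), genome, flank = 50L)
  expect_equal(m$window_seq, revcomp(w$window_seq))
  expect_equal(m$read_start, 172L - 122L)
  expect_equal(m$read_end, 172L - 100L)
})

test_that("hairpin validation covers the full verdict truth table", {
  # constructed dot-brackets around the 75% stem threshold:
  #  - perfect stem: frac 1.0
  #  - 16-pair chain with a 10-nt bulge: 32/42 = 0.762 (pass)
  #  - 14-pair chain with a 10-nt bulge: 28/38 = 0.737 (fail)
  perfect <- paste0(strrep("(", 14), "....", strrep(")", 14))
  pass_b <- paste0(strrep("(", 8), strrep(".", 10), strrep("(", 8),
                   "....", strrep(")", 16))
  fail_b <- paste0(strrep("(", 7), strrep(".", 10), strrep("(", 7),
                   "....", strrep(")", 14))
  perfect0 <- paste0(strrep("(", 14), strrep(")", 14))
  fail0 <- paste0(strrep("(", 7), strrep(".", 10), strrep("(", 7),
                  strrep(")", 14))

  check <- function(db, rs, re, has_loop, frac_ok, in_stem) {
    v <- validate_hairpin(db, rs, re, cfg)
    expect_equal(unlist(v[, c("has_loop", "stem_frac_ok", "read_in_stem")],
                        use.names = FALSE),
                 c(has_loop, frac_ok, in_stem), info = db)
    expect_equal(v$passed, has_loop && frac_ok && in_stem)
  }
  check(perfect, 0L, 10L, TRUE, TRUE, TRUE)    # read on arm
  check(perfect, 14L, 18L, TRUE, TRUE, FALSE)  # read wholly in the loop
  check(fail_b, 0L, 14L, TRUE, FALSE, TRUE)
  check(fail_b, 24L, 28L, TRUE, FALSE, FALSE)
  check(perfect0, 0L, 10L, FALSE, TRUE, TRUE)
  check(perfect0, 20L, 34L, FALSE, TRUE, FALSE) # read straddles the 3' end
  check(fail0, 0L, 14L, FALSE, FALSE, TRUE)
  check(fail0, 30L, 44L, FALSE, FALSE, FALSE)
})

test_that("validation is monotone in the stem-fraction threshold", {
  withr::local_seed(21)
  for (i in 1:20) {
    f <- fold_hairpin(rand_dna(80), cfg)
    rs <- 30L; re <- 50L
    verdicts <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0), function(th) {
      c2 <- pipeline_config(adapter3 = "TCGTATGCCG",
                            min_stem_paired_frac = th)
      validate_hairpin(f, rs, re, c2)$passed
    }, logical(1))
    # once FALSE at some threshold, never TRUE at a higher one
    expect_true(all(diff(as.integer(verdicts)) <= 0L))
  }
})

test_that("loop overhang tolerance admits reads that dip into the loop", {
  db <- paste0(strrep("(", 14), "....", strrep(")", 14))
  strict <- validate_hairpin(db, 10L, 16L, cfg) # 2 bases in the loop
  expect_false(strict$read_in_stem)
  relaxed <- validate_hairpin(db, 10L, 16L,
                              pipeline_config(adapter3 = "TCGTATGCCG",
                                              loop_overhang = 2L))
  expect_true(relaxed$read_in_stem)
})

test_that("miRNA locus calling recovers a planted hairpin and merges windows", {
  withr::local_seed(33)
  arm <- rand_dna(25, c("A", "C", "G", "C"))
  hp <- paste0(arm, "AATTAA", revcomp(arm))
  # N context never pairs, so the planted stem is the unique structure in
  # every window; the A/C-only second contig cannot pair at all
  genome <- tibble::tibble(
    id = c("c1", "c2"),
    seq = c(paste0(strrep("N", 120), hp, strrep("N", 120)),
            rand_dna(300, c("A", "C"))))
  # two overlapping arm reads (bona fide) and one unstructured read
  reads <- tibble::tibble(
    id = c("a1", "a2", "bg"),
    seq = c(substr(arm, 1, 20), substr(arm, 4, 24),
            substr(genome$seq[2], 100, 119)))
  idx <- build_index(genome)
  hits <- map_reads(reads, idx, cfg)
  res <- call_mirna_loci(hits, genome, cfg)
  expect_true(all(c("a1", "a2") %in% res$bona_fide))
  expect_false("bg" %in% res$bona_fide)
  expect_true("bg" %in% res$non_hairpin)
  # the passing windows overlap on each strand -> one merged locus per
  # strand, each supported by both reads
  plus <- dplyr::filter(res$loci, strand == "+")
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$n_reads, 2L)
  expect_setequal(plus$read_ids[[1]], c("a1", "a2"))
})

test_that("reference comparison applies the seed and identity thresholds", {
  withr::local_seed(44)
  ref_hp <- rand_dna(80)
  mature0 <- substr(ref_hp, 20, 41) # 22-mer inside the reference
  mut <- function(s, k) {
    for (p in sample(nchar(s), k)) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    s
  }
  refs <- tibble::tibble(id = c("mir-x", "mir-other"),
                         seq = c(ref_hp, rand_dna(80)))

  hit0 <- compare_to_reference(ref_hp, mature0, refs, cfg)
  expect_equal(hit0$ref_id, "mir-x")
  expect_equal(hit0$identity, 1.0)

  hit1 <- compare_to_reference(ref_hp, mut(mature0, 1), refs, cfg)
  expect_equal(hit1$identity, 21 / 22, tolerance = 1e-12)

  hit2 <- compare_to_reference(ref_hp, mut(mature0, 2), refs, cfg)
  expect_equal(nrow(hit2), 0L) # 20/22 = 0.909 < 0.95

  # candidate sharing only a 14-mer seed is not considered
  cand14 <- paste0(substr(ref_hp, 1, 14), rand_dna(60))
  expect_equal(nrow(compare_to_reference(cand14, mature0, refs, cfg)), 0L)

  # invariance under reverse-complementing the candidate hairpin
  rc_hit <- compare_to_reference(revcomp(ref_hp), mature0, refs, cfg)
  expect_equal(rc_hit$ref_id, hit0$ref_id)
  expect_equal(rc_hit$identity, hit0$identity)
})

test_that("locus classification follows overlap precedence", {
  feats <- tibble::tibble(
    contig = "c", start = c(100L, 180L, 500L), end = c(200L, 400L, 600L),
    strand = "+", kind = "gene",
    name = c("mir9", "geneA", "pseudo1"),
    class_label = c("miRNA", "protein_coding", "processed_pseudogene"))
  loci <- tibble::tibble(contig = "c",
                         start = c(150L, 300L, 520L, 900L),
                         end = c(250L, 350L, 540L, 950L),
                         strand = "+")
  out <- classify_loci(loci, feats)
  expect_equal(out$classification,
               c("known_mirna_gene",   # overlaps miRNA + coding: precedence
                 "protein_coding_overlap",
                 "pseudogene_overlap",
                 "intergenic"))
})
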