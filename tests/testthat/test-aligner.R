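cfg <- pipeline_config(adapter3 = "TCGTATGCCG")

test_that("index lookups agree with a naive substring scan", {
  withr::local_seed(3)
  genome <- tibble::tibble(id = "g", seq = rand_dna(1000))
  idx <- build_index(genome, k = 9L)
  for (i in 1:100) {
    s <- sample.int(992, 1)
    kmer <- substr(genome$seq, s, s + 8)
    hits <- srnakit:::index_lookup(idx, kmer)
    naive <- which(vapply(1:992, function(p) {
      substr(genome$seq, p, p + 8) == kmer
    }, logical(1))) - 1L
    expect_equal(sort(idx$pos[hits]), sort(naive))
  }
})

test_that("index construction handles edge cases", {
  expect_error(build_index(tibble::tibble(id = c("a", "a"),
                                          seq = c("ACGT", "ACGT"))),
               "duplicate contig")
  tiny <- build_index(tibble::tibble(id = "a", seq = "ACG"), k = 9L)
  expect_equal(length(srnakit:::index_lookup(tiny, "ACGTACGTA")), 0L)
  aa <- build_index(tibble::tibble(id = "a", seq = "AAAA"), k = 2L)
  expect_equal(sort(aa$pos[srnakit:::index_lookup(aa, "AA")]), c(0L, 1L, 2L))
})

test_that("forced compositions give the expected hit sets", {
  idx <- build_index(tibble::tibble(id = "g", seq = "AAAAAAAA"), k = 2L)
  hits <- map_reads(tibble::tibble(id = "r", seq = "AAAA"), idx, cfg)
  expect_equal(nrow(hits), 5L)
  expect_true(all(hits$strand == "+")) # revcomp(AAAA)=TTTT never matches
  expect_true(all(hits$mismatches == 0L))

  pal <- build_index(tibble::tibble(id = "g", seq = "ACGT"), k = 2L)
  hits2 <- map_reads(tibble::tibble(id = "r", seq = "ACGT"), pal, cfg)
  expect_equal(nrow(hits2), 2L)
  expect_setequal(hits2$strand, c("+", "-"))
  expect_true(all(hits2$start == 0L))

  idx3 <- build_index(tibble::tibble(id = "g", seq = "ACGTACGTAC"), k = 2L)
  hits3 <- map_reads(tibble::tibble(id = "r", seq = "ACGA"), idx3, cfg)
  expect_equal(nrow(hits3), 4L)
  expect_true(all(hits3$mismatches == 1L))
  expect_equal(sort(hits3$start[hits3$strand == "+"]), c(0L, 4L))
  expect_equal(sort(hits3$start[hits3$strand == "-"]), c(0L, 4L))
})

test_that("N counts as a mismatch on either side", {
  idx <- build_index(tibble::tibble(id = "g", seq = "CCCACGTACGTACGTACGTACCC"),
                     k = 4L)
  hits <- map_reads(tibble::tibble(id = "r", seq = "ACGTACGTNCGTACGT"), idx, cfg)
  expect_true(nrow(hits) >= 1L)
  expect_true(all(hits$mismatches[hits$strand == "+"] == 1L))
  # genome N never matches a read N
  gn <- tibble::tibble(id = "g", seq = "AANAA")
  bf <- brute_force_map(tibble::tibble(id = "r", seq = "AANAA"), gn, cfg)
  expect_equal(bf$mismatches[bf$strand == "+"], 1L)
})

test_that("map_reads equals the brute-force oracle on random cases", {
  withr::local_seed(101)
  for (case in 1:40) {
    # small alphabet-biased genomes raise the chance of multi-mappers
    genome <- tibble::tibble(
      id = c("c1", "c2"),
      seq = c(rand_dna(sample(200:800, 1), c("A", "C", "G", "T")),
              rand_dna(sample(50:400, 1), c("A", "C", "A", "T"))))
    idx <- build_index(genome)
    rl <- sample(18:42, 1)
    # half the reads are genuine genome extracts (possibly mutated)
    if (runif(1) < 0.5) {
      s <- sample.int(nchar(genome$seq[1]) - rl, 1)
      seq <- substr(genome$seq[1], s, s + rl - 1L)
      pos <- sample.int(rl, 1)
      substr(seq, pos, pos) <- sample(c("A", "C", "G", "T", "N"), 1)
    } else {
      seq <- rand_dna(rl, c("A", "C", "A", "T"))
    }
    reads <- tibble::tibble(id = "r", seq = seq)
    got <- sort_hits(map_reads(reads, idx, cfg))
    want <- sort_hits(oracle_map(seq, "r", genome, cfg$max_mismatches))
    expect_equal(got, want)
  }
})

test_that("strand symmetry: mapping against revcomp(genome) mirrors hits", {
  withr::local_seed(55)
  genome <- tibble::tibble(id = "g", seq = rand_dna(400))
  rc <- tibble::tibble(id = "g", seq = revcomp(genome$seq))
  L <- nchar(genome$seq)
  for (i in 1:10) {
    # reads extracted from the genome (with one planted substitution) so
    # that real hit sets exist on both strands
    s <- sample.int(nchar(genome$seq) - 20L, 1)
    seq <- substr(genome$seq, s, s + 19L)
    p <- sample.int(20L, 1)
    substr(seq, p, p) <- sample(c("A", "C", "G", "T"), 1)
    if (runif(1) < 0.5) seq <- revcomp(seq)
    read <- tibble::tibble(id = "r", seq = seq)
    fw <- brute_force_map(read, genome, cfg)
    expect_gt(nrow(fw), 0L)
    bw <- brute_force_map(read, rc, cfg)
    mirrored <- tibble::tibble(
      read_id = bw$read_id, contig = bw$contig,
      start = L - bw$end, end = L - bw$start,
      strand = as.character(ifelse(bw$strand == "+", "-", "+")),
      mismatches = bw$mismatches)
    expect_equal(sort_hits(fw), sort_hits(mirrored))
  }
})

test_that("every reported hit re-verifies its mismatch count", {
  withr::local_seed(77)
  genome <- tibble::tibble(id = "g", seq = rand_dna(600, c("A", "C", "A", "T")))
  idx <- build_index(genome)
  reads <- tibble::tibble(
    id = sprintf("r%d", 1:20),
    seq = vapply(1:20, function(i) {
      s <- sample.int(nchar(genome$seq) - 18L, 1)
      r <- substr(genome$seq, s, s + 17L)
      p <- sample.int(18L, 1)
      substr(r, p, p) <- sample(c("A", "C", "G", "T", "N"), 1)
      if (runif(1) < 0.5) r else revcomp(r)
    }, character(1)))
  hits <- map_reads(reads, idx, cfg)
  expect_gt(nrow(hits), 0L)
  for (i in seq_len(nrow(hits))) {
    win <- substr(genome$seq, hits$start[i] + 1L, hits$end[i])
    q <- reads$seq[match(hits$read_id[i], reads$id)]
    if (hits$strand[i] == "-") q <- revcomp(q)
    expect_equal(srnakit:::hamming_n(q, win), hits$mismatches[i])
  }
})

test_that("reads too short for seeding fall back to a full scan", {
  genome <- tibble::tibble(id = "g", seq = strrep("ACGT", 30))
  idx <- build_index(genome, k = 9L)
  read <- tibble::tibble(id = "r", seq = "ACGTACGTACGT") # 12 < 2k
  got <- sort_hits(map_reads(read, idx, cfg))
  want <- sort_hits(brute_force_map(read, genome, cfg))
  expect_equal(got, want)
  # empty genome edge
  expect_equal(nrow(brute_force_map(read, tibble::tibble(id = "e", seq = "ACG"),
                                    cfg)), 0L)
})
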