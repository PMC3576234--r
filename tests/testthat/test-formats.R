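test_that("FASTA reading normalises case and U/T and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 some description", "acgu", ">r2", "NNGT"), fa)
  out <- read_sequences(fa)
  expect_equal(out$id, c("r1", "r2"))
  expect_equal(out$seq, c("ACGT", "NNGT"))
})

test_that("malformed sequence input is a hard error", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "II"), fq) # quality shorter than seq
  expect_error(read_sequences(fq), "quality length")

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", ">b", "ACGT"), fa) # empty record
  expect_error(read_sequences(fa), "empty sequence")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_sequences(dup), "duplicate")

  alien <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACXT"), alien)
  expect_error(read_sequences(alien), "invalid symbol")
})

test_that("FASTQ qualities round-trip through read/write", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- tibble::tibble(id = c("r1", "r2"), seq = c("ACGT", "TTAA"),
                          qual = c("IIII", "FFFF"))
  write_sequences(reads, fq, format = "fastq")
  expect_equal(as.data.frame(read_sequences(fq)), as.data.frame(reads))
})

test_that("coordinate conventions per dialect: BED as-is, GFF3 start-1, rmout start-1", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10\tx\t0\t+", bed)
  fb <- read_features(bed, "bed", kind = "peak")
  expect_equal(fb$start, 0L)
  expect_equal(fb$end, 10L)
  expect_equal(fb$kind, "peak")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1;Name=g1;class=protein_coding"),
             gff)
  fg <- read_features(gff, "gff3")
  expect_equal(fg$start, 0L)
  expect_equal(fg$end, 10L)
  expect_equal(fg$kind, "gene")
  expect_equal(fg$class_label, "protein_coding")

  rm <- withr::local_tempfile(fileext = ".out")
  writeLines(c("   SW  perc perc perc  query    position in query    matching       repeat",
               "score  div. del. ins.  sequence begin  end   (left)  repeat         class/family",
               "",
               "  463 12.4  0.0  0.0  chr1     101    200  (4000) + MIR3           SINE/MIR      1  100  (0)  1"),
             rm)
  fr <- read_features(rm, "rmout")
  expect_equal(fr$start, 100L)
  expect_equal(fr$end, 200L)
  expect_equal(fr$kind, "repeat")
  expect_equal(fr$class_label, "SINE/MIR")
  expect_equal(fr$name, "MIR3")
})

test_that("reversed or negative coordinates are rejected", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t10", bed)
  expect_error(read_features(bed, "bed"), "coordinates")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr1\tsrc\tgene\t20\t10\t.\t+\t.\tID=g", gff)
  expect_error(read_features(gff, "gff3"), "coordinates")
})

test_that("BED and GFF3 round-trips reproduce identical feature tables", {
  withr::local_seed(5)
  feats <- tibble::tibble(
    contig = sample(c("c1", "c2"), 20, TRUE),
    start = sample.int(1000, 20) - 1L,
    kind = sample(c("gene", "repeat", "peak"), 20, TRUE),
    name = sprintf("f%02d", 1:20),
    class_label = sample(c("", "LINE/L1", "SINE/MIR"), 20, TRUE),
    strand = sample(c("+", "-", "."), 20, TRUE))
  feats$end <- feats$start + sample.int(200, 20)
  feats <- feats[, c("contig", "start", "end", "strand", "kind", "name",
                     "class_label")]

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_features(feats, gff, "gff3")
  expect_equal(as.data.frame(read_features(gff, "gff3")), as.data.frame(feats))

  # BED carries no kind column; compare on a single-kind table
  reps <- feats[feats$kind == "repeat", ]
  bed <- withr::local_tempfile(fileext = ".bed")
  write_features(reps, bed, "bed")
  back <- read_features(bed, "bed", kind = "repeat")
  expect_equal(as.data.frame(back), as.data.frame(reps), ignore_attr = TRUE)

  # the same genomic features written via GFF3 and BED read back as
  # identical internal intervals
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_features(reps, gff2, "gff3")
  expect_equal(read_features(gff2, "gff3")[, c("contig", "start", "end")],
               back[, c("contig", "start", "end")])
})

test_that("write_report is deterministic, schema-checked, and handles empties", {
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  rows <- tibble::tibble(a = c(1L, 2L), b = c("x", "y"), frac = c(0.5, 1 / 3))
  write_report(rows, p1)
  write_report(rows, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(readLines(p1)[1], "a\tb\tfrac")

  empty <- rows[0, ]
  pe <- withr::local_tempfile()
  write_report(empty, pe)
  expect_equal(readLines(pe), "a\tb\tfrac")

  expect_error(write_report(list(list(a = 1), list(b = 2)), p1), "schema")
})
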