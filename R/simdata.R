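# Deterministic synthetic-data generator. Plants hairpin loci (perfect
# stem + loop + reverse-complement stem), shuffled decoy loci, labelled
# repeat intervals, discontiguous-palindrome loci with an exactly designed
# match fraction, background crasiRNA loci, and gene models with planted
# target read counts. Every emitted read is traceable to one truth-ledger
# entry; the whole construction is reproducible from a single seed.

#' Simulate a genome with planted small RNA signals
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @param n_hairpins Number of planted perfect hairpin loci.
#' @param n_decoys Number of decoy loci (composition-matched shuffles of
#'   hairpin-like sequence, no planted structure).
#' @param stem_len,loop_len Hairpin stem and loop lengths (nt).
#' @param repeat_counts Named integer vector: copies per repeat class.
#' @param repeat_len Repeat copy length (nt).
#' @param repeat_divergence Per-base substitution rate between copies of
#'   one class consensus.
#' @param n_palindrome_loci Planted palindromic crasiRNA loci.
#' @param palindrome_match_frac Designed mirror match fraction of planted
#'   palindromic windows.
#' @param n_crasi_background Background crasiRNA loci (plain genomic
#'   intervals, no palindrome structure).
#' @param n_genes Planted gene models.
#' @param gene_len Gene model length (bp).
#' @param target_read_counts Distinct target read sequences planted per
#'   gene (recycled across genes).
#' @param gc Background GC content.
#' @param motif_flank Flank used when designing palindromic windows (must
#'   match the analysis `motif_flank`).
#' @param crasi_read_len Range of planted crasiRNA read lengths.
#' @param seed Integer seed; the entire construction is a pure function of
#'   the parameters and this seed.
#' @param config A [pipeline_config()] whose hairpin settings are used to
#'   certify planted truths (see Details).
#' @param n_read_candidates Certified read placements stored per hairpin
#'   or decoy locus.
#'
#' @details Planted truths are verified at construction so the ledger's
#' claims are exact: each hairpin locus stores read placements whose
#' folding windows pass [validate_hairpin()] in both orientations, and
#' each decoy locus stores placements that fail in both; loci that cannot
#' be certified (e.g. a shuffle that happens to retain structure, or a
#' perfect stem absorbed by chance context pairing) are re-drawn. Reads
#' are later sampled only from certified placements, so recovery tests
#' measure pipeline correctness, not the chance behaviour of random
#' sequence.
#' @return A list of class `srn_sim`: `genome` (tibble `id`, `seq`),
#'   `features` (gene + repeat annotation tibble), and `ledger` (truth
#'   tables: `hairpins`, `repeats`, `palindromes`, `genes`, plus `params`;
#'   `hairpins$read_candidates` holds the certified placements).
#' @export
simulate_genome <- function(contig_lengths = c(sim1 = 50000L, sim2 = 50000L),
                            n_hairpins = 8L, n_decoys = 8L,
                            stem_len = 25L, loop_len = 6L,
                            repeat_counts = c("LINE/L1" = 12L, "SINE/MIR" = 8L,
                                              "DNA/hAT" = 5L, "LTR/ERVL" = 3L),
                            repeat_len = 400L, repeat_divergence = 0.15,
                            n_palindrome_loci = 12L,
                            palindrome_match_frac = 0.5,
                            n_crasi_background = 8L,
                            n_genes = 5L, gene_len = 2000L,
                            target_read_counts = c(3L, 0L, 7L, 1L, 2L),
                            gc = 0.42, motif_flank = 50L,
                            crasi_read_len = c(35L, 42L),
                            seed = 1L, config = pipeline_config(),
                            n_read_candidates = 6L) {
  withr::with_seed(as.integer(seed), {
    contigs <- lapply(contig_lengths, random_dna, gc = gc)
    placer <- make_placer(contig_lengths, margin = motif_flank + 20L)

    hp <- list(); rp <- list(); pl <- list(); gn <- list()
    hp_len <- 2L * stem_len + loop_len

    for (i in seq_len(n_hairpins + n_decoys)) {
      decoy <- i > n_hairpins
      arm <- random_dna(stem_len, gc = 0.55)
      locus <- paste0(arm, random_dna(loop_len, gc = 0.2), revcomp(arm))
      if (decoy) locus <- shuffle_seq(locus)
      at <- placer(hp_len)
      contigs[[at$contig]] <- splice_seq(contigs[[at$contig]], at$start, locus)
      hp[[i]] <- tibble(name = sprintf("%s%03d", if (decoy) "decoy" else "hp", i),
                        contig = at$contig, start = at$start,
                        end = at$start + hp_len, strand = "+",
                        stem_len = stem_len, loop_len = loop_len,
                        decoy = decoy)
    }

    consensus <- lapply(repeat_counts, function(n) random_dna(repeat_len, gc = gc))
    ri <- 0L
    for (cls in names(repeat_counts)) {
      for (j in seq_len(repeat_counts[[cls]])) {
        ri <- ri + 1L
        copy <- mutate_seq(consensus[[cls]], repeat_divergence)
        at <- placer(repeat_len)
        contigs[[at$contig]] <- splice_seq(contigs[[at$contig]], at$start, copy)
        rp[[ri]] <- tibble(name = sprintf("rep%03d", ri), contig = at$contig,
                           start = at$start, end = at$start + repeat_len,
                           strand = "+", class_label = cls)
      }
    }

    for (i in seq_len(n_palindrome_loci + n_crasi_background)) {
      planted <- i <= n_palindrome_loci
      rl <- sample_range(crasi_read_len[1], crasi_read_len[2])
      wlen <- rl + 2L * motif_flank
      at <- placer(wlen)
      if (planted) {
        win <- design_palindrome(wlen, palindrome_match_frac, gc)
        contigs[[at$contig]] <- splice_seq(contigs[[at$contig]], at$start, win)
        frac <- attr(win, "match_frac")
      } else {
        frac <- NA_real_
      }
      pl[[i]] <- tibble(name = sprintf("%s%03d", if (planted) "pal" else "bg", i),
                        contig = at$contig,
                        start = at$start, end = at$start + wlen,
                        read_start = at$start + motif_flank,
                        read_end = at$start + motif_flank + rl,
                        strand = "+", planted = planted,
                        designed_match_frac = frac)
    }

    counts <- rep_len(target_read_counts, n_genes)
    for (i in seq_len(n_genes)) {
      at <- placer(gene_len)
      gn[[i]] <- tibble(name = sprintf("gene%02d", i), contig = at$contig,
                        start = at$start, end = at$start + gene_len,
                        strand = sample(c("+", "-"), 1L),
                        target_reads = counts[i])
    }

    cert <- certify_hairpin_loci(contigs, bind_rows(hp), config,
                                 n_read_candidates)
    contigs <- cert$contigs
    hairpins <- cert$hairpins
    repeats <- bind_rows(rp)
    palindromes <- bind_rows(pl)
    genes <- bind_rows(gn)
    features <- bind_rows(
      tibble(contig = genes$contig, start = genes$start, end = genes$end,
             strand = genes$strand, kind = "gene", name = genes$name,
             class_label = "protein_coding"),
      tibble(contig = repeats$contig, start = repeats$start, end = repeats$end,
             strand = repeats$strand, kind = "repeat", name = repeats$name,
             class_label = repeats$class_label))
    structure(list(
      genome = tibble(id = names(contigs), seq = unname(unlist(contigs))),
      features = features,
      ledger = list(hairpins = hairpins, repeats = repeats,
                    palindromes = palindromes, genes = genes,
                    params = list(stem_len = stem_len, loop_len = loop_len,
                                  motif_flank = motif_flank,
                                  palindrome_match_frac = palindrome_match_frac,
                                  seed = as.integer(seed)))),
      class = "srn_sim")
  })
}

#' @export
print.srn_sim <- function(x, ...) {
  l <- x$ledger
  cat("<srn_sim> ", nrow(x$genome), " contig(s), ",
      sum(nchar(x$genome$seq)), " bp | ",
      sum(!l$hairpins$decoy), " hairpins + ", sum(l$hairpins$decoy),
      " decoys, ", nrow(l$repeats), " repeats, ",
      sum(l$palindromes$planted), " palindromic + ",
      sum(!l$palindromes$planted), " background crasi loci, ",
      nrow(l$genes), " genes\n", sep = "")
  invisible(x)
}

# sample one integer uniformly from [a, b] (safe for a == b)
sample_range <- function(a, b) {
  if (a >= b) return(as.integer(a))
  sample(seq(a, b), 1L)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
  paste(chars, collapse = "")
}

splice_seq <- function(seq, at, insert) {
  # overwrite (not insert) so coordinates stay fixed
  paste0(substr(seq, 1L, at), insert,
         substr(seq, at + nchar(insert) + 1L, nchar(seq)))
}

# non-overlapping placement with an edge margin, bounded rejection sampling
make_placer <- function(contig_lengths, margin, max_tries = 2000L) {
  taken <- list()
  function(len) {
    for (try in seq_len(max_tries)) {
      cn <- sample(names(contig_lengths), 1L)
      lo <- margin
      hi <- contig_lengths[[cn]] - margin - len
      if (hi <= lo) next
      s <- sample(seq(lo, hi), 1L)
      prev <- taken[[cn]]
      # keep features far enough apart that +/-50 bp analysis windows
      # around one feature never reach into another
      clash <- !is.null(prev) &&
        any(s < prev$end + 120L & s + len + 120L > prev$start)
      if (!clash) {
        taken[[cn]] <<- bind_rows(prev, tibble(start = s, end = s + len))
        return(list(contig = cn, start = s))
      }
    }
    abort("could not place feature without overlap; genome too small")
  }
}

# Certify the ledger's structural claims: planted hairpin read windows
# must pass validation in both orientations, decoy windows must fail in
# both. Loci whose claim cannot be certified are regenerated in place.
certify_hairpin_loci <- function(contigs, hp, cfg, n_cand,
                                 max_locus_tries = 30L) {
  cands <- vector("list", nrow(hp))
  for (i in seq_len(nrow(hp))) {
    h <- hp[i, ]
    ok <- FALSE
    for (attempt in seq_len(max_locus_tries)) {
      got <- draw_certified_candidates(contigs, h, cfg, n_cand)
      if (!is.null(got)) {
        cands[[i]] <- got
        ok <- TRUE
        break
      }
      arm <- random_dna(h$stem_len, gc = 0.55)
      locus <- paste0(arm, random_dna(h$loop_len, gc = 0.2), revcomp(arm))
      if (h$decoy) locus <- shuffle_seq(locus)
      contigs[[h$contig]] <- splice_seq(contigs[[h$contig]], h$start, locus)
    }
    if (!ok) abort(sprintf("could not certify locus '%s'", h$name))
  }
  hp$read_candidates <- cands
  list(contigs = contigs, hairpins = hp)
}

draw_certified_candidates <- function(contigs, h, cfg, n_cand,
                                      per_cand_tries = 20L) {
  rng <- cfg$size_ranges$mirna
  out <- list()
  for (j in seq_len(n_cand)) {
    found <- FALSE
    for (t in seq_len(per_cand_tries)) {
      rl <- sample_range(rng[1], min(rng[2], h$stem_len))
      if (h$decoy) {
        s <- h$start + sample.int(h$end - h$start - rl + 1L, 1L) - 1L
      } else {
        arm <- sample(c("arm5", "arm3"), 1L)
        a0 <- if (arm == "arm5") h$start else h$start + h$stem_len + h$loop_len
        s <- a0 + sample.int(h$stem_len - rl + 1L, 1L) - 1L
      }
      verdict <- window_passes_both(contigs, h$contig, s, s + rl, cfg)
      want <- !h$decoy
      if (identical(verdict, c(want, want))) {
        out[[j]] <- tibble(start = s, end = s + rl)
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL)
  }
  bind_rows(out)
}

# pass/fail of the hairpin criteria for a read window, both orientations
window_passes_both <- function(contigs, contig, s, e, cfg) {
  vapply(c("+", "-"), function(st) {
    w <- extract_window(list(contig = contig, start = s, end = e, strand = st),
                        contigs, cfg$hairpin_flank)
    f <- fold_hairpin(w$window_seq, cfg)
    validate_hairpin(f, w$read_start, w$read_end, cfg)$passed
  }, logical(1), USE.NAMES = FALSE)
}

# window with an exactly designed mirror match fraction
design_palindrome <- function(wlen, frac, gc) {
  half <- wlen %/% 2L
  n_pairs <- round(frac * wlen / 2)
  if (n_pairs > half) abort("match fraction infeasible for window length")
  left <- strsplit(random_dna(half, gc), "")[[1]]
  matched <- sort(sample.int(half, n_pairs))
  comp <- chartr("ACGT", "TGCA", left)
  right_rev <- character(half) # position i pairs with wlen - 1 - i
  for (i in seq_len(half)) {
    right_rev[i] <- if (i %in% matched) comp[i] else
      sample(setdiff(DNA_BASES, comp[i]), 1L)
  }
  center <- if (wlen %% 2L == 1L) sample(DNA_BASES, 1L) else character(0)
  win <- paste(c(left, center, rev(right_rev)), collapse = "")
  structure(win, match_frac = 2 * n_pairs / wlen)
}

#' Simulate adapter-ligated reads from planted loci
#'
#' Reads are drawn from the ledger's planted loci for one pool: hairpin
#' arms (and decoy bodies) for `mirna`, repeat bodies for `pirna`,
#' palindromic/background crasi loci for `crasirna`, and planted gene
#' targets for `mirna_targets` (each distinct target sequence is emitted
#' `depth` times to exercise duplicate collapsing). The 3' adapter is
#' appended in full or truncated to at least `min_adapter_match` bases; a
#' configurable fraction of reads instead receives a sub-threshold adapter
#' remnant to exercise the discard rule. Substitution errors are applied
#' at `error_rate` per base.
#'
#' @param sim A `srn_sim` from [simulate_genome()].
#' @param pool `"mirna"`, `"pirna"`, `"crasirna"`, or `"mirna_targets"`.
#' @param depth Reads per locus (for `mirna_targets`, duplicate copies per
#'   distinct planted sequence).
#' @param config A [pipeline_config()] (size ranges and adapter).
#' @param error_rate Per-base substitution error rate.
#' @param short_adapter_frac Fraction of reads given an adapter remnant
#'   shorter than `min_adapter_match` (these should be discarded).
#' @param truncated_adapter_frac Fraction given a truncated (but
#'   clippable) adapter.
#' @param class_weights For `pirna` repeat reads: sampling weight per
#'   repeat class (named; defaults to uniform over planted classes).
#' @param n_reads Total reads for repeat-derived pools (overrides depth).
#' @param seed Integer seed.
#' @return List: `reads` (tibble `id`, `seq`, `qual`) and `truth` (tibble
#'   with per-read origin, insert, adapter length, errors, and
#'   `expect_discard`).
#' @export
simulate_reads <- function(sim, pool, depth = 3L,
                           config = pipeline_config(adapter3 = "TCGTATGCCG"),
                           error_rate = 0, short_adapter_frac = 0,
                           truncated_adapter_frac = 0.3,
                           class_weights = NULL, n_reads = NULL,
                           seed = 1L) {
  stopifnot(inherits(sim, "srn_sim"))
  adapter <- normalize_seq(config$adapter3, "adapter3")
  mm <- config$min_adapter_match
  contigs <- genome_vector(sim$genome)
  led <- sim$ledger
  size_pool <- if (pool == "mirna_targets") "mirna" else pool
  rng <- config$size_ranges[[size_pool]]
  if (is.null(rng)) abort(sprintf("no size range for pool '%s'", size_pool))

  withr::with_seed(as.integer(seed), {
    origins <- switch(
      pool,
      mirna = mirna_origins(led, contigs, depth, rng, adapter, mm),
      mirna_targets = target_origins(led, contigs, depth, rng, adapter, mm),
      pirna = repeat_origins(led, contigs,
                             n_reads %||% (depth * nrow(led$repeats)),
                             rng, class_weights, adapter, mm),
      crasirna = crasi_origins(led, contigs, depth, adapter, mm),
      abort(sprintf("unknown pool '%s'", pool)))
    n <- nrow(origins)
    if (n == 0L) abort("no origins planted for this pool")

    rows <- purrr::map(seq_len(n), function(i) {
      build_read(origins[i, ], contigs, adapter, mm, error_rate,
                 short_adapter_frac, truncated_adapter_frac)
    })
    truth <- bind_rows(rows)
    truth$id <- sprintf("%s_r%05d", pool, seq_len(n))
    truth$pool <- pool
    reads <- tibble(id = truth$id, seq = truth$read_seq,
                    qual = strrep("I", nchar(truth$read_seq)))
    list(reads = reads,
         truth = select(truth, all_of(c(
           "id", "pool", "origin", "contig", "start", "end", "strand",
           "insert_seq", "adapter_len", "n_errors", "expect_discard"))))
  })
}

# error-free insert for a candidate origin interval
origin_insert <- function(contigs, contig, start, end, strand) {
  x <- substr(contigs[[contig]], start + 1L, end)
  if (strand == "-") revcomp(x) else x
}

# accept an interval only when its insert cannot be confused with adapter
# sequence (no clippable adapter-prefix suffix); ledger fates stay exact
guarded_origin <- function(contigs, adapter, mm, origin, contig, draw_fn,
                           max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    d <- draw_fn()
    ins <- origin_insert(contigs, contig, d$start, d$end, d$strand)
    if (!ends_with_prefix(ins, adapter, mm)) {
      return(tibble(origin = origin, contig = contig, start = d$start,
                    end = d$end, strand = d$strand))
    }
  }
  abort(sprintf("could not draw an unambiguous read for locus '%s'", origin))
}

mirna_origins <- function(led, contigs, depth, rng, adapter, mm) {
  hp <- led$hairpins
  out <- list()
  for (i in seq_len(nrow(hp))) {
    h <- hp[i, ]
    for (d in seq_len(depth)) {
      cand <- h$read_candidates[[1]]
      out[[length(out) + 1L]] <- guarded_origin(
        contigs, adapter, mm, h$name, h$contig, function() {
          # only certified read placements are planted (see simulate_genome)
          r <- cand[sample.int(nrow(cand), 1L), ]
          list(start = r$start, end = r$end,
               strand = sample(c("+", "-"), 1L))
        })
    }
  }
  bind_rows(out)
}

target_origins <- function(led, contigs, depth, rng, adapter, mm) {
  gn <- led$genes
  out <- list()
  for (i in seq_len(nrow(gn))) {
    g <- gn[i, ]
    if (g$target_reads == 0L) next
    for (t in seq_len(g$target_reads)) {
      # one distinct sequence: position and strand fixed across duplicates
      o <- guarded_origin(contigs, adapter, mm, g$name, g$contig, function() {
        rl <- sample_range(rng[1], rng[2])
        s <- g$start + sample.int(g$end - g$start - rl + 1L, 1L) - 1L
        list(start = s, end = s + rl, strand = sample(c("+", "-"), 1L))
      })
      for (d in seq_len(depth)) out[[length(out) + 1L]] <- o
    }
  }
  bind_rows(out)
}

repeat_origins <- function(led, contigs, n_reads, rng, class_weights,
                           adapter, mm) {
  rp <- led$repeats
  classes <- unique(rp$class_label)
  w <- if (is.null(class_weights)) setNames(rep(1, length(classes)), classes)
       else class_weights
  if (!all(names(w) %in% classes)) abort("class_weights names not planted")
  cls_draw <- sample(names(w), n_reads, replace = TRUE, prob = unname(w))
  out <- list()
  for (i in seq_len(n_reads)) {
    cand <- rp[rp$class_label == cls_draw[i], ]
    r <- cand[sample.int(nrow(cand), 1L), ]
    out[[i]] <- guarded_origin(contigs, adapter, mm, r$name, r$contig,
                               function() {
      rl <- sample_range(rng[1], rng[2])
      s <- r$start + sample.int(r$end - r$start - rl + 1L, 1L) - 1L
      list(start = s, end = s + rl, strand = sample(c("+", "-"), 1L))
    })
  }
  bind_rows(out)
}

crasi_origins <- function(led, contigs, depth, adapter, mm) {
  pal <- led$palindromes
  out <- list()
  for (i in seq_len(nrow(pal))) {
    p <- pal[i, ]
    for (d in seq_len(depth)) {
      # the read interval is fixed by the planted window; only the strand
      # can vary, so try both before giving up
      strands <- sample(c("+", "-"))
      picked <- NULL
      for (st in strands) {
        ins <- origin_insert(contigs, p$contig, p$read_start, p$read_end, st)
        if (!ends_with_prefix(ins, adapter, mm)) {
          picked <- st
          break
        }
      }
      if (is.null(picked)) {
        abort(sprintf("could not draw an unambiguous read for locus '%s'",
                      p$name))
      }
      out[[length(out) + 1L]] <- tibble(origin = p$name, contig = p$contig,
                                        start = p$read_start,
                                        end = p$read_end, strand = picked)
    }
  }
  bind_rows(out)
}

build_read <- function(o, contigs, adapter, mm, error_rate,
                       short_adapter_frac, truncated_adapter_frac) {
  alen_full <- nchar(adapter)
  base_insert <- origin_insert(contigs, o$contig, o$start, o$end, o$strand)
  for (try in seq_len(100L)) {
    insert <- base_insert
    n_err <- 0L
    if (error_rate > 0) {
      chars <- strsplit(insert, "")[[1]]
      hit <- which(runif(length(chars)) < error_rate)
      for (p in hit) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      n_err <- length(hit)
      insert <- paste(chars, collapse = "")
    }
    u <- runif(1)
    if (u < short_adapter_frac) {
      alen <- sample(0:(mm - 1L), 1L)
    } else if (u < short_adapter_frac + truncated_adapter_frac) {
      alen <- sample(mm:(alen_full - 1L), 1L)
    } else {
      alen <- alen_full
    }
    # sequencing errors can recreate a confusable adapter-prefix ending;
    # redraw the error/adapter realisation in that (rare) case
    if (!ends_with_prefix(insert, adapter, mm)) {
      return(tibble(origin = o$origin, contig = o$contig, start = o$start,
                    end = o$end, strand = o$strand, insert_seq = insert,
                    adapter_len = alen, n_errors = n_err,
                    expect_discard = alen < mm,
                    read_seq = paste0(insert, substr(adapter, 1L, alen))))
    }
  }
  abort("could not draw an unambiguous read; adapter clashes with locus")
}

ends_with_prefix <- function(x, adapter, mm) {
  nx <- nchar(x)
  if (nx < mm) return(FALSE)
  any(vapply(mm:min(nx, nchar(adapter)), function(L) {
    substr(x, nx - L + 1L, nx) == substr(adapter, 1L, L)
  }, logical(1)))
}

#' Write a simulated data set to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `repeats.bed`, one FASTQ per supplied
#' read set, and `truth.json` (the serialised ledger).
#'
#' @param sim A `srn_sim`.
#' @param dir Output directory (created if needed).
#' @param read_sets Named list of [simulate_reads()] outputs; names become
#'   `reads_<name>.fastq`.
#' @return `dir`, invisibly.
#' @export
write_simdata <- function(sim, dir, read_sets = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sequences(sim$genome, file.path(dir, "genome.fa"))
  write_features(filter(sim$features, .data$kind == "gene"),
                 file.path(dir, "genes.gff3"), dialect = "gff3")
  write_features(filter(sim$features, .data$kind == "repeat"),
                 file.path(dir, "repeats.bed"), dialect = "bed")
  truth <- c(lapply(sim$ledger[c("hairpins", "repeats", "palindromes", "genes")],
                    as.data.frame),
             list(params = sim$ledger$params),
             list(reads = lapply(read_sets, function(r) as.data.frame(r$truth))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(read_sets)) {
    write_sequences(read_sets[[nm]]$reads,
                    file.path(dir, sprintf("reads_%s.fastq", nm)),
                    format = "fastq")
  }
  invisible(dir)
}
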