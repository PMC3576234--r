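# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

base_config <- function(...) {
  pipeline_config(adapter3 = "TCGTATGCCG", ...)
}

# --- alignment oracle -------------------------------------------------------
# direct position-by-position scan, written independently of the package's
# vectorised window scan: character vectors, one window at a time
oracle_map <- function(read_seq, read_id, genome_tbl, max_mm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  for (g in seq_len(nrow(genome_tbl))) {
    gseq <- strsplit(genome_tbl$seq[g], "")[[1]]
    for (strand in c("+", "-")) {
      q <- strsplit(read_seq, "")[[1]]
      if (strand == "-") q <- rev(unname(comp[q]))
      m <- length(q)
      if (length(gseq) < m) next
      for (s in 0:(length(gseq) - m)) {
        w <- gseq[(s + 1):(s + m)]
        mm <- sum(w != q | w == "N" | q == "N")
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(
            read_id = read_id, contig = genome_tbl$id[g], start = s,
            end = s + m, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, out)
}

sort_hits <- function(h) {
  h <- as.data.frame(h)
  h <- h[order(h$read_id, h$contig, h$start, h$strand, h$mismatches), ]
  rownames(h) <- NULL
  h
}

# --- folding oracle ---------------------------------------------------------
# exhaustive enumeration of all nested structures over allowed pairs with
# the minimum-loop and (optionally) no-lonely-pairs constraints; returns
# the maximum pair count. Recursive structure generation, not a DP.
oracle_fold_max <- function(seq, min_loop = 3L, no_lp = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  ok_pair <- function(i, j) {
    p <- paste0(chars[i], chars[j])
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  best <- 0L
  # state: position, stack of open indices, list of pairs so far
  rec <- function(pos, stack, pairs) {
    # infeasible: not enough positions left to close every open bracket
    if (length(stack) > n - pos + 1L) return(invisible())
    if (pos > n) {
      if (length(stack) == 0L && valid_nolp(pairs)) {
        best <<- max(best, length(pairs))
      }
      return(invisible())
    }
    # unpaired
    rec(pos + 1L, stack, pairs)
    # open
    rec(pos + 1L, c(stack, pos), pairs)
    # close against top of stack
    if (length(stack) > 0L) {
      top <- stack[length(stack)]
      if (pos - top - 1L >= min_loop && ok_pair(top, pos)) {
        rec(pos + 1L, stack[-length(stack)],
            c(pairs, list(c(top, pos))))
      }
    }
    invisible()
  }
  valid_nolp <- function(pairs) {
    if (!no_lp || length(pairs) == 0L) return(TRUE)
    mat <- do.call(rbind, pairs)
    key <- paste(mat[, 1], mat[, 2])
    # a pair is lonely if neither (i+1, j-1) nor (i-1, j+1) is present
    all(paste(mat[, 1] + 1L, mat[, 2] - 1L) %in% key |
          paste(mat[, 1] - 1L, mat[, 2] + 1L) %in% key)
  }
  rec(1L, integer(0), list())
  best
}

# --- mirror-score oracle ----------------------------------------------------
# explicit per-position loop over complement lookups
oracle_mirror <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  s <- 0L
  for (i in seq_len(L)) {
    if (chars[i] != "N" && comp[[chars[L - i + 1L]]] == chars[i]) s <- s + 1L
  }
  s
}

# --- quadratic interval oracles ---------------------------------------------
oracle_overlap_pairs <- function(a, b, by_strand = FALSE) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$contig[i] != b$contig[j]) next
      if (by_strand && a$strand[i] != b$strand[j]) next
      if (a$start[i] < b$end[j] && a$end[i] > b$start[j]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

# single-linkage clustering by pairwise chaining, O(n^2)
oracle_cluster <- function(hits, gap) {
  n <- nrow(hits)
  if (n == 0L) return(data.frame())
  comp_id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp_id[i] == comp_id[j]) next
        same <- hits$contig[i] == hits$contig[j] &&
          hits$start[i] <= hits$end[j] + gap &&
          hits$start[j] <= hits$end[i] + gap
        if (same) {
          comp_id[comp_id == comp_id[j]] <- comp_id[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  agg <- lapply(unique(comp_id), function(cid) {
    m <- hits[comp_id == cid, ]
    data.frame(contig = m$contig[1], start = min(m$start), end = max(m$end),
               n_reads = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$contig, out$start), ]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, contigs = c("c1", "c2"), max_pos = 5000L,
                             max_len = 60L, stranded = TRUE) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    contig = sample(contigs, n, replace = TRUE),
    start = start, end = start + len,
    strand = if (stranded) sample(c("+", "-"), n, replace = TRUE)
             else rep(".", n))
}
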