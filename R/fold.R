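# Folding backend. The built-in folder maximises the number of nested base
# pairs over {A.T, G.C, G.T} subject to a minimum terminal loop length and
# (by default) a no-lonely-pairs constraint, with deterministic traceback.
# It is a pluggable stand-in for a thermodynamic folder: the stem-loop
# validation criteria downstream operate on any dot-bracket structure.

#' Fold a sequence into its maximum-base-pair nested structure
#'
#' @param seq A single DNA sequence (`A/C/G/T/N`; `N` never pairs).
#' @param config A [pipeline_config()] supplying `min_loop` and
#'   `no_lonely_pairs`.
#' @return A list of class `srn_fold`: `window_seq`, `dotbracket`, `pairs`
#'   (two-column 0-based index matrix, 5' < 3'), and `score` (pair count).
#' @export
#' @examples
#' fold_hairpin("GGGGAAAACCCC")$dotbracket
fold_hairpin <- function(seq, config = pipeline_config()) {
  if (!is_string(seq)) abort("seq must be a single string")
  seq <- normalize_seq(seq, "fold input")
  if (nchar(seq) == 0L) abort("empty sequence")
  res <- .fold_maxpairs(seq, config$min_loop, config$no_lonely_pairs)
  structure(list(window_seq = seq,
                 dotbracket = res$dotbracket,
                 pairs = cbind(i = res$pair_i, j = res$pair_j),
                 score = res$score),
            class = "srn_fold")
}

#' @export
print.srn_fold <- function(x, ...) {
  cat(x$window_seq, "\n", x$dotbracket, "  (", x$score, " pairs)\n", sep = "")
  invisible(x)
}

# dot-bracket -> two-column 0-based pair matrix
dotbracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pi <- integer(0); pj <- integer(0)
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") {
      stack <- c(stack, pos)
    } else if (chars[pos] == ")") {
      if (length(stack) == 0L) abort("unbalanced dot-bracket")
      pi <- c(pi, stack[length(stack)] - 1L)
      pj <- c(pj, pos - 1L)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket")
  ord <- order(pi)
  cbind(i = pi[ord], j = pj[ord])
}

#' Extract stem-loops from a folded structure
#'
#' One stem-loop per hairpin loop (innermost pair): each is extended
#' outward through its enclosing pairs up to, and excluding, the first
#' multiloop branch point. The stem paired fraction is `2 * n_pairs`
#' divided by the total length of the two arms, so bulged and interior-loop
#' bases count against it while the terminal loop is excluded.
#'
#' @param fold A `srn_fold` (or any list with a `pairs` matrix), or a
#'   dot-bracket string.
#' @return Tibble with one row per stem-loop: `outer5`, `inner5`, `inner3`,
#'   `outer3` (0-based window indices of the outermost/innermost paired
#'   bases), `n_pairs`, `loop_len`, `arm5_len`, `arm3_len`,
#'   `stem_paired_frac`.
#' @export
#' @examples
#' parse_stemloops("((..((....))..))")
parse_stemloops <- function(fold) {
  pairs <- if (is.character(fold)) dotbracket_pairs(fold) else fold$pairs
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_stemloops())
  np <- nrow(pairs)
  # parent = smallest enclosing pair; children counts identify branch points
  ord <- order(pairs[, "i"])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- rep(NA_integer_, np)
  stack <- integer(0)
  for (p in seq_len(np)) {
    while (length(stack) && pairs[stack[length(stack)], "j"] < pairs[p, "i"]) {
      stack <- stack[-length(stack)]
    }
    if (length(stack)) parent[p] <- stack[length(stack)]
    stack <- c(stack, p)
  }
  n_children <- tabulate(parent[!is.na(parent)], nbins = np)
  leaves <- which(n_children == 0L)
  rows <- purrr::map(leaves, function(leaf) {
    chain <- leaf
    p <- parent[leaf]
    while (!is.na(p) && n_children[p] == 1L) {
      chain <- c(chain, p)
      p <- parent[p]
    }
    outer <- chain[length(chain)]
    tibble(outer5 = unname(pairs[outer, "i"]),
           inner5 = unname(pairs[leaf, "i"]),
           inner3 = unname(pairs[leaf, "j"]),
           outer3 = unname(pairs[outer, "j"]),
           n_pairs = length(chain))
  })
  out <- bind_rows(rows)
  out <- mutate(out,
                loop_len = .data$inner3 - .data$inner5 - 1L,
                arm5_len = .data$inner5 - .data$outer5 + 1L,
                arm3_len = .data$outer3 - .data$inner3 + 1L,
                stem_paired_frac = 2 * .data$n_pairs /
                  (.data$arm5_len + .data$arm3_len))
  arrange(out, .data$outer5)
}

empty_stemloops <- function() {
  tibble(outer5 = integer(0), inner5 = integer(0), inner3 = integer(0),
         outer3 = integer(0), n_pairs = integer(0), loop_len = integer(0),
         arm5_len = integer(0), arm3_len = integer(0),
         stem_paired_frac = double(0))
}
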