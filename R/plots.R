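# ggplot2 views of the main result types.

#' Histogram of motif permutation p-values
#'
#' The empirical p-value distribution across a cohort of alignment
#' windows; under the null it is close to uniform, while palindromic
#' cohorts pile up near zero.
#'
#' @param cohort A `srn_cohort` from [score_palindromes()].
#' @param binwidth Bin width on the p-value axis.
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(cohort, binwidth = 0.01) {
  res <- filter(tidy(cohort), !.data$skipped)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = "empirical p-value", y = "windows",
                  title = "Mirror-motif significance across loci") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pvalue_histogram
#' @param object,... Passed from the `autoplot` generic.
#' @export
autoplot.srn_cohort <- function(object, ...) plot_pvalue_histogram(object, ...)

#' Heat map of the row-normalised target matrix
#'
#' @param tm Output of [target_matrix()].
#' @return A ggplot object.
#' @export
plot_target_matrix <- function(tm) {
  long <- tidyr::pivot_longer(tm$normalized, -"gene_name",
                              names_to = "pool", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pool, y = .data$gene_name,
                                     fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "darkgreen", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "row-normalised\nsupport") +
    ggplot2::theme_minimal()
}

#' Bar chart of repeat class association
#'
#' @param distribution The `distribution` tibble from [associate_repeats()].
#' @return A ggplot object.
#' @export
plot_repeat_classes <- function(distribution) {
  d <- mutate(distribution,
              class_label = stats::reorder(.data$class_label, -.data$percent))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class_label, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "repeat class", y = "% of read-class assignments") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dot-bracket rendering of a hairpin call
#'
#' @param fold A `srn_fold` from [fold_hairpin()].
#' @return A ggplot object showing per-position pairing state.
#' @export
plot_fold <- function(fold) {
  chars <- strsplit(fold$dotbracket, "")[[1]]
  df <- tibble(pos = seq_along(chars),
               state = factor(chars, levels = c("(", ".", ")")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = 0,
                                   fill = .data$state)) +
    ggplot2::geom_tile(height = 0.5) +
    ggplot2::scale_fill_manual(values = c("(" = "firebrick", "." = "grey85",
                                          ")" = "navy")) +
    ggplot2::labs(x = "window position", y = NULL, fill = "pairing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
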