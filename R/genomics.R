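#' Exact binomial test of a mutation frequency
#'
#' Tests whether `k` mutated cell lines out of `n` is compatible with the
#' tumour mutation frequency `p0`. The two-sided p-value uses the
#' minimum-likelihood rule: all outcomes whose probability under
#' Binomial(n, p0) does not exceed that of the observed `k` are summed.
#'
#' @param k Number of mutated cell lines (0..n).
#' @param n Number of cell lines.
#' @param p0 Tumour mutation frequency, strictly inside (0, 1).
#' @return Two-sided exact p-value.
#' @export
binomial_frequency_test <- function(k, n, p0) {
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) {
    stop("degenerate tumour frequency p0 (must be strictly inside (0, 1))",
         call. = FALSE)
  }
  stats::binom.test(k, n, p = p0)$p.value
}

#' Fraction of the genome altered
#'
#' The fraction of total segment length whose absolute log2 copy-number
#' ratio strictly exceeds the threshold (segments exactly at the threshold
#' do not count).
#'
#' @param segments Data frame with columns `length` (positive integer base
#'   pairs) and `log2_ratio`.
#' @param threshold Default 0.2.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_genome_altered <- function(segments, threshold = 0.2) {
  if (!nrow(segments)) stop("empty segment table", call. = FALSE)
  if (!all(c("length", "log2_ratio") %in% names(segments))) {
    stop("segments need columns `length` and `log2_ratio`", call. = FALSE)
  }
  if (any(segments$length <= 0)) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  total <- sum(segments$length)
  if (total <= 0) stop("zero total genome length", call. = FALSE)
  altered <- abs(segments$log2_ratio) > threshold
  sum(segments$length[altered]) / total
}

#' Read a segment table
#'
#' Accepts either a plain table with `length` and `log2_ratio` columns or a
#' BED-like table (`chrom`, `start`, `end`, `log2_ratio`; half-open 0-based
#' coordinates, so `length = end - start`).
#'
#' @param path Tab-separated file with a header row.
#' @return Data frame with `length` and `log2_ratio`.
#' @export
read_segment_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("chrom", "start", "end") %in% names(tab))) {
    tab$length <- tab$end - tab$start
  }
  if (!all(c("length", "log2_ratio") %in% names(tab))) {
    stop("segment table needs `length`+`log2_ratio` or `chrom`+`start`+`end`+`log2_ratio`",
         call. = FALSE)
  }
  tab[, c("length", "log2_ratio")]
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test for association in a 2x2 contingency table
#' (e.g., ER status by sample source), two-tailed by the minimum-likelihood
#' rule: all tables with the observed margins whose probability does not
#' exceed the observed table's are summed.
#'
#' @param x 2x2 matrix of nonnegative integer counts with positive margins.
#' @return Two-tailed exact p-value.
#' @export
composition_fisher_test <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) stop("x must be a 2x2 table", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  stats::fisher.test(x, alternative = "two.sided")$p.value
}

#' Summarise mutation frequencies against tumour baselines
#'
#' Convenience wrapper running [binomial_frequency_test()] over a table of
#' genes.
#'
#' @param summary Data frame with columns `gene`, `mutated_cell_lines`,
#'   `n_cell_lines`, `tumour_frequency`.
#' @return The input with `cell_line_frequency` and `p_value` columns
#'   added.
#' @export
mutation_frequency_tests <- function(summary) {
  need <- c("gene", "mutated_cell_lines", "n_cell_lines", "tumour_frequency")
  if (!all(need %in% names(summary))) {
    stop("summary needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  summary$cell_line_frequency <-
    summary$mutated_cell_lines / summary$n_cell_lines
  summary$p_value <- mapply(binomial_frequency_test,
                            summary$mutated_cell_lines,
                            summary$n_cell_lines,
                            summary$tumour_frequency)
  summary
}
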