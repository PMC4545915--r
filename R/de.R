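#' Per-gene Welch t-tests between cell lines and tumours
#'
#' For every gene, a two-sample Welch t-test of cell lines versus tumours
#' on the log scale, with Welch-Satterthwaite degrees of freedom and
#' two-sided p-values. The statistic is oriented cell line minus tumour, so
#' positive t means higher expression in culture. Genes with zero variance
#' in both groups get t = 0, p = 1 when the means agree, and an infinite
#' statistic with p = 0 when they do not. BH-adjusted q-values are attached.
#'
#' @param mat An `expr_matrix` (log scale) whose annotations label each
#'   sample `cell_line` or `tumour`, or a plain matrix plus `group`.
#' @param group Optional character vector of `"cell_line"` / `"tumour"`
#'   labels per column (required for plain matrices).
#' @return A `data.frame` of class `de_table`: `gene`, `t_statistic`, `df`,
#'   `p_value`, `q_value`, `mean_cell_line`, `mean_tumour`, `direction`.
#' @export
welch_t_per_gene <- function(mat, group = NULL) {
  if (inherits(mat, "expr_matrix")) {
    group <- mat$samples$source
    v <- mat$values
  } else {
    v <- mat
    if (is.null(group)) stop("`group` required for plain matrices", call. = FALSE)
  }
  i1 <- which(group == "cell_line")
  i2 <- which(group == "tumour")
  if (length(i1) < 2 || length(i2) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  n1 <- length(i1); n2 <- length(i2)
  x1 <- v[, i1, drop = FALSE]; x2 <- v[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  s2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- s1 / n1 + s2 / n2
  diff <- m1 - m2
  t <- ifelse(se2 > 0, diff / sqrt(se2),
              ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df),
              ifelse(t == 0, 1, 0))
  p[t == 0] <- 1
  out <- data.frame(gene = rownames(v), t_statistic = unname(t),
                    df = unname(df), p_value = unname(p),
                    q_value = bh_adjust(unname(p)),
                    mean_cell_line = unname(m1), mean_tumour = unname(m2),
                    direction = unname(sign(diff)),
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_i` is the minimum over `j` with
#' `p_(j) >= p_(i)` of `p_(j) * n / rank(j)`, capped at 1; input order is
#' preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Attach gene-purity correlations and flags to a DE table
#'
#' Joins the stromal/immune/purity correlations onto the DE table and sets
#' two flags: `purity_filtered` marks genes whose absolute stromal or
#' immune correlation exceeds the filter threshold `tau`, and
#' `highly_stromal` marks genes whose stromal or immune correlation exceeds
#' the (separate) reporting threshold. Genes with undefined correlations are
#' never flagged.
#'
#' @param de A `de_table`.
#' @param purcor Output of [gene_purity_correlation()] covering the genes.
#' @param tau Filter threshold on `|r|`, default 0.2.
#' @param report_r Reporting threshold, default 0.5.
#' @return The `de_table` with columns `stromal_r`, `immune_r`, `purity_r`,
#'   `undefined_r`, `purity_filtered`, `highly_stromal` added.
#' @export
annotate_purity <- function(de, purcor, tau = 0.2, report_r = 0.5) {
  stopifnot(inherits(de, "de_table"))
  ix <- match(de$gene, purcor$gene)
  if (anyNA(ix)) stop("purity correlations missing for some genes", call. = FALSE)
  de$stromal_r <- purcor$stromal_r[ix]
  de$immune_r <- purcor$immune_r[ix]
  de$purity_r <- purcor$purity_r[ix]
  de$undefined_r <- purcor$undefined[ix]
  over <- function(r, thr) !is.na(r) & r > thr
  de$purity_filtered <- over(abs(de$stromal_r), tau) |
    over(abs(de$immune_r), tau)
  de$highly_stromal <- over(de$stromal_r, report_r) |
    over(de$immune_r, report_r)
  de
}

#' Select the top fraction of differentially expressed genes
#'
#' Takes the `ceiling(fraction * n)` genes with smallest adjusted p-value;
#' ties are broken by smaller raw p, then larger `|t|`, then gene id. With
#' the conventional 1% fraction, a 16,282-gene table yields 163 genes.
#'
#' @param de A `de_table`.
#' @param fraction Fraction in `(0, 1]`, default 0.01.
#' @return Character vector of gene ids ordered by significance.
#' @export
top_fraction <- function(de, fraction = 0.01) {
  stopifnot(inherits(de, "de_table"))
  if (!nrow(de)) stop("empty DE table", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * nrow(de))
  ord <- order(de$q_value, de$p_value, -abs(de$t_statistic), de$gene)
  de$gene[ord[seq_len(k)]]
}

#' Filter differentially expressed genes by purity correlation
#'
#' Removes genes whose absolute stromal or immune correlation exceeds
#' `tau`, so the surviving ranking reflects culture-intrinsic rather than
#' compartment-loss differences. Genes with undefined correlations are
#' retained (and stay flagged via `undefined_r`). Survivors keep their
#' relative order: the filtered ranking is a subsequence of the unfiltered
#' one.
#'
#' @param de A `de_table` with purity columns (see [annotate_purity()]).
#' @param tau Threshold on `|r|` in `[0, 1]`, default 0.2.
#' @return List with `filtered` (the surviving `de_table`) and `removed`
#'   (character vector of removed gene ids).
#' @export
purity_filter <- function(de, tau = 0.2) {
  stopifnot(inherits(de, "de_table"))
  if (is.null(de$stromal_r)) {
    stop("DE table lacks purity correlations; run annotate_purity() first",
         call. = FALSE)
  }
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]", call. = FALSE)
  drop <- (!is.na(de$stromal_r) & abs(de$stromal_r) > tau) |
    (!is.na(de$immune_r) & abs(de$immune_r) > tau)
  filtered <- de[!drop, , drop = FALSE]
  rownames(filtered) <- NULL
  class(filtered) <- class(de)
  list(filtered = filtered, removed = de$gene[drop])
}

#' Write a DE table
#'
#' @param de A `de_table`.
#' @param path Output path (tab-separated).
#' @return The path, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
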