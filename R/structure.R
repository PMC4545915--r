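#' Select the most variable genes
#'
#' Genes are ranked by sample variance computed across all samples of the
#' (log-scale) matrix — cell lines and tumours combined. Ties are broken
#' lexicographically by gene id; the result is in variance-descending order.
#'
#' @param mat An `expr_matrix` or plain gene x sample matrix.
#' @param k Number of genes to keep (<= number of genes).
#' @return Character vector of `k` gene ids, most variable first.
#' @export
select_top_variance_genes <- function(mat, k) {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  if (k > nrow(v)) {
    stop("k (", k, ") exceeds the number of genes (", nrow(v), ")",
         call. = FALSE)
  }
  n <- ncol(v)
  if (n < 2) stop("need at least 2 samples to compute variance", call. = FALSE)
  vars <- rowSums((v - rowMeans(v))^2) / (n - 1)
  ord <- order(-vars, rownames(v))
  rownames(v)[ord[seq_len(k)]]
}

#' Principal component analysis of samples
#'
#' Samples are the observations, genes the features. Features are centred
#' but not scaled to unit variance (the usual expression-PCA default, which
#' keeps high-variance purity and subtype axes interpretable). Components
#' are ordered by variance explained, and each component's sign is fixed so
#' that its largest-magnitude gene loading is positive.
#'
#' @param mat An `expr_matrix` or plain gene x sample matrix, usually
#'   restricted to the top-variance genes.
#' @return A list of class `pca_result` with `sample_scores`
#'   (sample x component), `loadings` (gene x component, orthonormal) and
#'   `variance_explained` (per-component fraction).
#' @export
run_pca <- function(mat) {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  if (ncol(v) < 2 || nrow(v) < 2) {
    stop("PCA needs at least 2 samples and 2 genes", call. = FALSE)
  }
  if (all(abs(v - mean(v)) < 1e-12)) {
    stop("degenerate input: matrix is constant", call. = FALSE)
  }
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(sample_scores = scores, loadings = loadings,
                 variance_explained = ve[seq_len(ncol(scores))]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$sample_scores), "samples,",
      ncol(x$sample_scores), "components\n")
  cat("  PC1/PC2 variance explained:",
      sprintf("%.1f%% / %.1f%%", 100 * x$variance_explained[1],
              100 * x$variance_explained[2]), "\n")
  invisible(x)
}

#' Correlate a principal component with purity scores
#'
#' Pearson correlation between the chosen component's tumour sample scores
#' and each of the stromal and immune scores. A high correlation of PC1
#' with the stromal score indicates that the dominant axis of variation
#' separates samples by non-malignant content.
#'
#' @param pca A `pca_result`.
#' @param tumour_ids Sample ids (rows of `sample_scores`) to use.
#' @param scores Output of [estimate_scores()] covering those ids.
#' @param component Component index, default 1.
#' @return List with `r_stromal`, `r_immune`, and `undefined` (`TRUE` when
#'   the component is constant across the tumours).
#' @export
correlate_pc_with_scores <- function(pca, tumour_ids, scores, component = 1) {
  stopifnot(inherits(pca, "pca_result"))
  if (!all(tumour_ids %in% rownames(pca$sample_scores))) {
    stop("tumour ids missing from PCA scores", call. = FALSE)
  }
  if (!all(tumour_ids %in% scores$sample_id)) {
    stop("tumour ids missing from purity scores", call. = FALSE)
  }
  if (length(tumour_ids) < 3) {
    stop("need at least 3 tumours", call. = FALSE)
  }
  x <- pca$sample_scores[tumour_ids, component]
  sc <- scores[match(tumour_ids, scores$sample_id), ]
  if (stats::sd(x) == 0) {
    return(list(r_stromal = NA_real_, r_immune = NA_real_, undefined = TRUE))
  }
  safe_cor <- function(y) if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  list(r_stromal = safe_cor(sc$stromal_score),
       r_immune = safe_cor(sc$immune_score),
       undefined = FALSE)
}

#' Hierarchical clustering on correlation distance
#'
#' Pairwise sample distance is `1 - r` (Pearson correlation over the
#' selected genes), agglomerated with the Ward variant that squares
#' dissimilarities before the update (`ward.D2`). Distances lie in `[0, 2]`;
#' identical samples merge at height 0.
#'
#' @param mat An `expr_matrix` or plain gene x sample matrix (selected
#'   genes).
#' @return An object of class `hclust`.
#' @export
correlation_cluster <- function(mat) {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  if (ncol(v) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = "ward.D2")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are differences of consecutive merge heights, so the root
#' to leaf path length reproduces the merge height of the root.
#'
#' @param hc An `hclust` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Rank cell lines by mean correlation with their subtype's tumours
#'
#' Each cell line is compared with all tumours of its comparison subtype
#' (claudin-low lines are compared with basal tumours, as that subtype is
#' poorly represented among tumours); the ranking statistic is the mean
#' Pearson correlation over the selected genes, and lines are ranked in
#' decreasing order within each comparison group.
#'
#' @param mat An `expr_matrix` (log scale) with `source` and `subtype`
#'   annotations; restrict to the top-variance genes first via
#'   [subset_expr()].
#' @return A `data.frame` with `cell_line_id`, `subtype`,
#'   `comparison_subtype`, `mean_correlation`, `rank` (within comparison
#'   group), ordered by group and rank.
#' @export
rank_cell_lines <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  ann <- mat$samples
  cl <- ann[ann$source == "cell_line", , drop = FALSE]
  tum <- ann[ann$source == "tumour", , drop = FALSE]
  if (!nrow(cl) || !nrow(tum)) {
    stop("need both cell lines and tumours", call. = FALSE)
  }
  comparison <- ifelse(cl$subtype == "claudin_low", "basal", cl$subtype)
  missing <- setdiff(unique(comparison), unique(tum$subtype))
  if (length(missing)) {
    stop("no tumours for comparison subtype(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cc <- stats::cor(mat$values[, cl$sample_id, drop = FALSE],
                   mat$values[, tum$sample_id, drop = FALSE])
  mean_r <- vapply(seq_len(nrow(cl)), function(i) {
    mean(cc[i, tum$subtype == comparison[i]])
  }, numeric(1))
  out <- data.frame(cell_line_id = cl$sample_id, subtype = cl$subtype,
                    comparison_subtype = comparison,
                    mean_correlation = mean_r, stringsAsFactors = FALSE)
  parts <- lapply(split(out, out$comparison_subtype), function(p) {
    p <- p[order(-p$mean_correlation, p$cell_line_id), , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    p
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' The fictional average cell line
#'
#' Averages the log-scale expression of all cell lines of one subtype into
#' a single synthetic profile and computes its mean correlation with the
#' matched tumours, exactly as [rank_cell_lines()] does for real lines.
#' Averaging cancels line-specific noise, so this profile typically
#' outranks every individual line.
#'
#' @param mat An `expr_matrix` (log scale, selected genes) with
#'   annotations.
#' @param subtype Cell-line subtype to average (claudin-low maps to basal
#'   tumours for the comparison).
#' @return List with `profile` (named numeric vector) and
#'   `mean_correlation`.
#' @export
average_cell_line <- function(mat, subtype) {
  stopifnot(inherits(mat, "expr_matrix"))
  ann <- mat$samples
  cl_ids <- ann$sample_id[ann$source == "cell_line" & ann$subtype == subtype]
  if (length(cl_ids) < 2) {
    stop("need at least 2 cell lines of subtype '", subtype, "'",
         call. = FALSE)
  }
  comparison <- if (subtype == "claudin_low") "basal" else subtype
  tum_ids <- ann$sample_id[ann$source == "tumour" & ann$subtype == comparison]
  if (!length(tum_ids)) {
    stop("no tumours of comparison subtype '", comparison, "'", call. = FALSE)
  }
  profile <- rowMeans(mat$values[, cl_ids, drop = FALSE])
  r <- mean(stats::cor(profile, mat$values[, tum_ids, drop = FALSE]))
  list(profile = profile, mean_correlation = r)
}

#' Matched-versus-mismatched subtype separation (AUC)
#'
#' For every cell line, the mean correlation with tumours of its comparison
#' subtype (matched) and with tumours of the other subtypes (mismatched) is
#' computed; the AUC is the probability that a matched mean correlation
#' exceeds a mismatched one (Mann-Whitney statistic over all
#' matched/mismatched pairs). An AUC of 1 means subtype identity is fully
#' recoverable from transcriptome correlation.
#'
#' @param mat An `expr_matrix` (log scale, selected genes) with
#'   annotations.
#' @return A single number in `[0, 1]`.
#' @export
subtype_separation_auc <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  ann <- mat$samples
  cl <- ann[ann$source == "cell_line", , drop = FALSE]
  tum <- ann[ann$source == "tumour", , drop = FALSE]
  comparison <- ifelse(cl$subtype == "claudin_low", "basal", cl$subtype)
  cc <- stats::cor(mat$values[, cl$sample_id, drop = FALSE],
                   mat$values[, tum$sample_id, drop = FALSE])
  matched <- mismatched <- numeric(0)
  for (i in seq_len(nrow(cl))) {
    is_match <- tum$subtype == comparison[i]
    if (any(is_match)) matched <- c(matched, mean(cc[i, is_match]))
    if (any(!is_match)) mismatched <- c(mismatched, mean(cc[i, !is_match]))
  }
  if (!length(matched) || !length(mismatched)) {
    stop("need both matched and mismatched tumour groups", call. = FALSE)
  }
  cmp <- outer(matched, mismatched, ">") + 0.5 * outer(matched, mismatched, "==")
  mean(cmp)
}
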