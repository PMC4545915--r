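#' Mean-t gene-set enrichment
#'
#' Tests whether a gene set's per-gene Welch t statistics (cell line vs
#' tumour) are shifted relative to all other tested genes. The set-level
#' statistic reported is the arithmetic mean of member t statistics;
#' significance comes from a two-sided two-sample Welch t-test of member
#' statistics against non-member statistics, and direction is the sign of
#' the member mean minus the background mean. Sets with fewer than 2 or
#' with `max_size` or more members present in the table are excluded
#' (strictly "fewer than `max_size`"). q-values are BH-adjusted across the
#' tested sets.
#'
#' @param de A `de_table` (see [welch_t_per_gene()]).
#' @param sets A list of [gene_signature()]s.
#' @param max_size Exclusive upper bound on present-member count, default
#'   200.
#' @return A `data.frame` of class `geneset_result`: `set_id`, `set_size`,
#'   `mean_t`, `p_value`, `q_value`, `direction`, plus a `members`
#'   list-column of the present member genes. Empty (with a warning) when
#'   no set survives the size filter.
#' @export
gage_test <- function(de, sets, max_size = 200) {
  stopifnot(inherits(de, "de_table"))
  if (inherits(sets, "gene_signature")) sets <- list(sets)
  tstat <- stats::setNames(de$t_statistic, de$gene)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$genes, names(tstat))
    if (length(members) < 2 || length(members) >= max_size) return(NULL)
    # a set needs a real background to be tested against
    if (length(tstat) - length(members) < 2) return(NULL)
    mt <- tstat[members]
    bg <- tstat[setdiff(names(tstat), members)]
    tt <- welch_two_sample(mt, bg)
    data.frame(set_id = s$name, set_size = length(members),
               mean_t = mean(mt), p_value = tt$p,
               direction = if (mean(mt) >= mean(bg)) "up" else "down",
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    warning("no gene sets survive the size filter", call. = FALSE)
    out <- data.frame(set_id = character(0), set_size = integer(0),
                      mean_t = numeric(0), p_value = numeric(0),
                      direction = character(0), q_value = numeric(0))
    out$members <- list()
    class(out) <- c("geneset_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows[keep])
  out$q_value <- bh_adjust(out$p_value)
  out$members <- lapply(sets[keep], function(s) {
    intersect(s$genes, names(tstat))
  })
  rownames(out) <- NULL
  class(out) <- c("geneset_result", "data.frame")
  out
}

# Welch two-sample t with the same degenerate-variance rules as
# welch_t_per_gene: both groups constant -> t = 0 or +/-Inf.
welch_two_sample <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  diff <- mean(x) - mean(y)
  if (se2 > 0) {
    t <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- n1 + n2 - 2
    p <- if (diff == 0) 1 else 0
  }
  list(t = t, df = df, p = p)
}

#' Essential genes of each enriched set
#'
#' The members that drive a set's call: genes that are individually
#' significant (q-value below `member_alpha`) and whose t statistic agrees
#' in sign with the set's direction.
#'
#' @param result A `geneset_result` from [gage_test()].
#' @param de The `de_table` the result was computed from.
#' @param member_alpha Per-gene q-value cutoff, default 0.05.
#' @return The `geneset_result` with an `essential_genes` list-column
#'   added (possibly empty character vectors).
#' @export
essential_genes <- function(result, de, member_alpha = 0.05) {
  stopifnot(inherits(result, "geneset_result"), inherits(de, "de_table"))
  q <- stats::setNames(de$q_value, de$gene)
  t <- stats::setNames(de$t_statistic, de$gene)
  result$essential_genes <- lapply(seq_len(nrow(result)), function(i) {
    m <- result$members[[i]]
    want_sign <- if (result$direction[i] == "up") 1 else -1
    m[q[m] < member_alpha & sign(t[m]) == want_sign]
  })
  result
}

#' Purity attribution of enriched sets
#'
#' Averages the stromal, immune and purity-proxy correlations of each
#' set's essential genes, estimating how much of the set's perturbation is
#' explained by the loss of stromal/immune compartments in culture rather
#' than by the malignant cells themselves. Sets with no essential genes get
#' `NA` means.
#'
#' @param result A `geneset_result` with `essential_genes` (see
#'   [essential_genes()]).
#' @param purcor Output of [gene_purity_correlation()].
#' @return The `geneset_result` with `mean_stromal_r`, `mean_immune_r`,
#'   `mean_purity_r` columns added.
#' @export
attribute_purity <- function(result, purcor) {
  stopifnot(inherits(result, "geneset_result"))
  if (is.null(result$essential_genes)) {
    stop("run essential_genes() first", call. = FALSE)
  }
  col <- function(what) {
    vals <- stats::setNames(purcor[[what]], purcor$gene)
    vapply(result$essential_genes, function(g) {
      if (!length(g)) NA_real_ else mean(vals[g], na.rm = TRUE)
    }, numeric(1))
  }
  result$mean_stromal_r <- col("stromal_r")
  result$mean_immune_r <- col("immune_r")
  result$mean_purity_r <- col("purity_r")
  result
}

#' Write gene-set results
#'
#' Flat tab-separated table in the style of a top-pathways report: set id,
#' mean t statistic, set size, significance, direction, essential-gene
#' count and the purity attributions.
#'
#' @param result A `geneset_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_geneset_results <- function(result, path) {
  stopifnot(inherits(result, "geneset_result"))
  flat <- result
  flat$members <- NULL
  if (!is.null(flat$essential_genes)) {
    flat$n_essential <- vapply(result$essential_genes, length, integer(1))
    flat$essential_genes <- vapply(result$essential_genes, paste,
                                   "", collapse = ",")
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
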