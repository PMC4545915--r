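#' Pipeline configuration
#'
#' One object holding every tunable parameter of the analysis, with the
#' standard defaults: top 5000 variance genes, top 1% differential
#' expression, purity filter at |r| > 0.2, reporting threshold r > 0.5,
#' gene sets with fewer than 200 members, set-level q cutoff 1e-4, and
#' ssGSEA exponent 0.25.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read
#'   tables).
#' @param cohort A [cohort_config()] (synthetic mode); its seed is
#'   overridden by `seed`.
#' @param files Named list for files mode: `expression` (path),
#'   `scale` (scale tag of that table), `annotations` (path),
#'   `signatures` (GMT path; first set stromal, second immune), optional
#'   `gene_sets` (GMT), optional `mutations` (TSV with columns `gene`,
#'   `mutated_cell_lines`, `n_cell_lines`, `tumour_frequency`), optional
#'   `segments` (TSV, see [read_segment_table()]).
#' @param top_k_genes,de_fraction,purity_tau,report_r,set_max_size,set_q_cutoff,ssgsea_exponent
#'   Analysis parameters (see Description).
#' @param seed Integer seed governing all randomness of the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_config(),
                            files = list(),
                            top_k_genes = 5000,
                            de_fraction = 0.01,
                            purity_tau = 0.2,
                            report_r = 0.5,
                            set_max_size = 200,
                            set_q_cutoff = 1e-4,
                            ssgsea_exponent = 0.25,
                            seed = 1) {
  mode <- match.arg(mode)
  if (top_k_genes < 2) stop("top_k_genes must be >= 2", call. = FALSE)
  if (de_fraction <= 0 || de_fraction > 1) {
    stop("de_fraction must be in (0, 1]", call. = FALSE)
  }
  if (purity_tau < 0 || purity_tau > 1) {
    stop("purity_tau must be in [0, 1]", call. = FALSE)
  }
  if (set_max_size < 3) stop("set_max_size must be >= 3", call. = FALSE)
  if (set_q_cutoff <= 0 || set_q_cutoff > 1) {
    stop("set_q_cutoff must be in (0, 1]", call. = FALSE)
  }
  if (ssgsea_exponent < 0) stop("ssgsea_exponent must be >= 0", call. = FALSE)
  if (mode == "files") {
    need <- c("expression", "scale", "annotations", "signatures")
    missing <- setdiff(need, names(files))
    if (length(missing)) {
      stop("files mode needs: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(mode = mode, cohort = cohort, files = files,
                 top_k_genes = top_k_genes, de_fraction = de_fraction,
                 purity_tau = purity_tau, report_r = report_r,
                 set_max_size = set_max_size, set_q_cutoff = set_q_cutoff,
                 ssgsea_exponent = ssgsea_exponent, seed = seed),
            class = "pipeline_config")
}

#' Run the full purity-aware comparison pipeline
#'
#' Executes, in order: data acquisition (synthetic cohort or files),
#' log2(TPM+1) harmonisation, stromal/immune scoring of tumours and
#' gene-score correlation, top-variance gene selection with PCA and
#' correlation clustering, subtype-specific cell-line ranking (plus the
#' fictional average line), per-gene Welch differential expression with BH
#' correction, top-fraction selection before and after the purity filter,
#' mean-t gene-set enrichment with purity attribution, and (files mode,
#' when inputs are present) the genomic frequency tests. Every stage's
#' output is written as a plain-text table under `out_dir` together with a
#' JSON manifest recording the configuration, seed and stage-by-stage
#' counts. Identical configuration and seed give byte-identical output
#' bundles; on error the stage name is reported and partial outputs are
#' removed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    created[[length(created) + 1]] <<- path
    path
  }
  stage <- "setup"
  res <- list()
  counts <- list()

  run <- function() {
    if (config$mode == "synthetic") {
      stage <<- "synthetic_data"
      cc <- config$cohort
      cc$seed <- config$seed
      cohort <- generate_cohort(cc)
      mat <- cohort$matrix
      truth <- cohort$truth
      sigs <- builtin_signatures(truth)
      stromal_sig <- sigs$stromal
      immune_sig <- sigs$immune
      sets <- truth_gene_sets(truth, seed = config$seed)
      write_expression_matrix(mat, emit("expression_tpm.tsv"))
      write_sample_annotations(mat$samples, emit("sample_annotations.tsv"))
      tp <- write_truth(truth, file.path(out_dir, "truth"))
      created <<- c(created, tp)
      write_gmt(list(stromal_sig, immune_sig), emit("signatures.gmt"))
      write_gmt(sets, emit("gene_sets.gmt"))
      res$truth <<- truth
    } else {
      stage <<- "ingest"
      mat <- read_expression_matrix(config$files$expression,
                                    scale = config$files$scale,
                                    annotations = config$files$annotations)
      if (mat$scale != "log2_tpm_plus1") mat <- to_tpm(mat)
      sigs <- read_gmt(config$files$signatures)
      if (length(sigs) < 2) {
        stop("signature GMT must contain a stromal and an immune set")
      }
      stromal_sig <- sigs[[1]]
      immune_sig <- sigs[[2]]
      sets <- if (!is.null(config$files$gene_sets)) {
        read_gmt(config$files$gene_sets)
      }
    }
    counts$n_genes <<- nrow(mat$values)
    counts$n_samples <<- ncol(mat$values)
    message("input: ", nrow(mat$values), " genes x ", ncol(mat$values),
            " samples")

    stage <<- "log_transform"
    logmat <- if (mat$scale == "log2_tpm_plus1") mat else log_transform(mat)

    stage <<- "purity"
    tum <- subset_expr(logmat, source = "tumour")
    scores <- estimate_scores(tum, stromal_sig, immune_sig,
                              exponent = config$ssgsea_exponent)
    purcor <- gene_purity_correlation(tum, scores)
    utils::write.table(scores, emit("purity_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(purcor, emit("gene_purity_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$scores <<- scores
    res$purity_correlation <<- purcor

    stage <<- "structure"
    k <- min(config$top_k_genes, nrow(logmat$values))
    sel <- select_top_variance_genes(logmat, k)
    counts$n_selected_genes <<- k
    writeLines(sel, emit("selected_genes.txt"))
    selmat <- subset_expr(logmat, genes = sel)
    pca <- run_pca(selmat)
    utils::write.table(
      data.frame(sample_id = rownames(pca$sample_scores),
                 pca$sample_scores[, 1:min(10, ncol(pca$sample_scores))],
                 check.names = FALSE),
      emit("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
    )
    utils::write.table(
      data.frame(component = seq_along(pca$variance_explained),
                 variance_explained = pca$variance_explained),
      emit("pca_variance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
    )
    pc1_cor <- correlate_pc_with_scores(pca, tum$samples$sample_id, scores)
    hc <- correlation_cluster(selmat)
    write_dendrogram_newick(hc, emit("dendrogram.nwk"))
    ranking <- rank_cell_lines(selmat)
    utils::write.table(ranking, emit("cell_line_ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    avg <- lapply(
      stats::setNames(nm = unique(ranking$subtype)),
      function(s) {
        n <- sum(ranking$subtype == s)
        if (n >= 2) average_cell_line(selmat, s)$mean_correlation
        else NA_real_
      }
    )
    utils::write.table(
      data.frame(subtype = names(avg),
                 average_line_mean_correlation = unlist(avg)),
      emit("average_cell_line.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    res$pca <<- pca
    res$pc1_score_correlation <<- pc1_cor
    res$dendrogram <<- hc
    res$ranking <<- ranking
    res$average_cell_line <<- avg
    message("structure: ", k, " genes selected; PC1 explains ",
            sprintf("%.1f%%", 100 * pca$variance_explained[1]),
            " of variance")

    stage <<- "de"
    de <- welch_t_per_gene(logmat)
    de <- annotate_purity(de, purcor, tau = config$purity_tau,
                          report_r = config$report_r)
    top <- top_fraction(de, config$de_fraction)
    flt <- purity_filter(de, tau = config$purity_tau)
    top_filtered <- top_fraction(flt$filtered, config$de_fraction)
    write_de_table(de, emit("de_table.tsv"))
    writeLines(top, emit("top_de_genes.txt"))
    writeLines(flt$removed, emit("removed_genes.txt"))
    writeLines(top_filtered, emit("filtered_top_de_genes.txt"))
    counts$n_top_de <<- length(top)
    counts$n_removed_by_purity_filter <<- length(flt$removed)
    counts$n_genes_after_filter <<- nrow(flt$filtered)
    counts$n_top_de_filtered <<- length(top_filtered)
    res$de <<- de
    res$top_de <<- top
    res$purity_filter <<- flt
    res$top_de_filtered <<- top_filtered
    message("de: ", nrow(de), " genes tested -> top ", length(top),
            "; purity filter removed ", length(flt$removed),
            " -> top ", length(top_filtered), " after filtering")

    stage <<- "gsea"
    if (!is.null(sets) && length(sets)) {
      gs <- gage_test(de, sets, max_size = config$set_max_size)
      if (nrow(gs)) {
        gs <- essential_genes(gs, de)
        gs <- attribute_purity(gs, purcor)
      }
      write_geneset_results(gs, emit("gene_set_results.tsv"))
      counts$n_sets_tested <<- nrow(gs)
      counts$n_sets_significant <<- sum(gs$q_value < config$set_q_cutoff)
      res$gene_sets <<- gs
      message("gsea: ", nrow(gs), " sets tested, ",
              counts$n_sets_significant, " below q < ", config$set_q_cutoff)
    }

    stage <<- "genomics"
    if (config$mode == "files" && !is.null(config$files$mutations)) {
      mut <- utils::read.delim(config$files$mutations,
                               stringsAsFactors = FALSE)
      mut <- mutation_frequency_tests(mut)
      utils::write.table(mut, emit("mutation_tests.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      res$mutation_tests <<- mut
    }
    if (config$mode == "files" && !is.null(config$files$segments)) {
      seg <- read_segment_table(config$files$segments)
      fga <- fraction_genome_altered(seg)
      utils::write.table(
        data.frame(fraction_genome_altered = fga),
        emit("fraction_genome_altered.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE
      )
      res$fraction_genome_altered <<- fga
    }

    stage <<- "manifest"
    manifest <- list(
      config = unclass_deep(config),
      counts = counts,
      pc1_score_correlation = pc1_cor[c("r_stromal", "r_immune")],
      outputs = basename(created)
    )
    jsonlite::write_json(manifest, emit("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <<- manifest
  }

  tryCatch(run(), error = function(e) {
    file.remove(created[file.exists(created)])
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}
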