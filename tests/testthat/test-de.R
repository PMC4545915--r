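test_that("per-gene Welch t matches the closed form and t.test", {
  # stated toy: cell lines {1,2,3} vs tumours {2,3,4}
  v <- rbind(g1 = c(1, 2, 3, 2, 3, 4))
  colnames(v) <- paste0("s", 1:6)
  grp <- rep(c("cell_line", "tumour"), each = 3)
  de <- welch_t_per_gene(v, grp)
  expect_equal(de$t_statistic, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(de$t_statistic, -1.2247, tolerance = 1e-4)
  expect_equal(de$df, 4)
  expect_equal(de$p_value, 0.2879, tolerance = 1e-3)

  # label swap negates t, keeps p
  de_sw <- welch_t_per_gene(v, rev(grp))
  expect_equal(de_sw$t_statistic, -de$t_statistic)
  expect_equal(de_sw$p_value, de$p_value)

  # equal means -> t = 0, p = 1 regardless of variances
  v2 <- rbind(gA = c(1, 3, 2, 0, 4, 2))
  colnames(v2) <- paste0("s", 1:6)
  de2 <- welch_t_per_gene(v2, grp)
  expect_equal(de2$t_statistic, 0)
  expect_equal(de2$p_value, 1)

  # oracle equivalence on random matrices against both the direct formula
  # and stats::t.test
  set.seed(4)
  vr <- matrix(rnorm(30 * 12), 30,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  grp_r <- rep(c("cell_line", "tumour"), c(5, 7))
  der <- welch_t_per_gene(vr, grp_r)
  for (i in c(1, 10, 30)) {
    a <- vr[i, 1:5]; b <- vr[i, 6:12]
    orc <- oracle_welch(a, b)
    tt <- t.test(a, b)
    expect_equal(der$t_statistic[i], orc$t, tolerance = 1e-10)
    expect_equal(der$df[i], orc$df, tolerance = 1e-10)
    expect_equal(der$p_value[i], orc$p, tolerance = 1e-10)
    expect_equal(der$t_statistic[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(der$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(der$q_value, p.adjust(der$p_value, "BH"))
  expect_true(all(der$q_value >= der$p_value))
  expect_error(welch_t_per_gene(vr, rep(c("cell_line", "tumour"), c(1, 11))),
               "at least 2")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(8)
  grid <- runif(12)
  for (i in 1:15) {
    p <- sample(grid, sample(1:8, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # q is nondecreasing in p
  p <- sort(runif(20))
  expect_true(all(diff(bh_adjust(p)) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("top-fraction selection uses the ceiling with stable tie-breaks", {
  mk_de <- function(n, seed = 1) {
    set.seed(seed)
    v <- matrix(rnorm(4 * n), n, dimnames = list(sprintf("g%06d", seq_len(n)),
                                                 paste0("s", 1:4)))
    welch_t_per_gene(cbind(v, v + rnorm(n)),
                     rep(c("cell_line", "tumour"), c(4, 4)))
  }
  de <- mk_de(1000)
  expect_length(top_fraction(de, 0.01), 10)
  expect_length(top_fraction(de, 1), 1000)
  # the headline count: 1% of 16,282 genes is 163
  expect_identical(ceiling(0.01 * 16282), 163)
  # ordered by significance
  top <- top_fraction(de, 0.05)
  qs <- de$q_value[match(top, de$gene)]
  expect_true(all(diff(qs) >= 0))
  expect_error(top_fraction(de, 0))
})

test_that("the purity filter removes correlated genes and preserves order", {
  v <- matrix(rnorm(5 * 8), 5, dimnames = list(paste0("g", 1:5),
                                               paste0("s", 1:8)))
  de <- welch_t_per_gene(v, rep(c("cell_line", "tumour"), each = 4))
  purcor <- data.frame(gene = de$gene,
                       stromal_r = c(0.5, 0.1, -0.3, NA, 0.05),
                       immune_r = c(0, 0, 0, NA, 0.6),
                       purity_r = 0, undefined = c(F, F, F, T, F))
  de <- annotate_purity(de, purcor, tau = 0.2, report_r = 0.5)
  flt <- purity_filter(de, tau = 0.2)
  expect_setequal(flt$removed, c("g1", "g3", "g5"))
  # undefined correlations are retained and flagged
  expect_true("g4" %in% flt$filtered$gene)
  expect_true(flt$filtered$undefined_r[flt$filtered$gene == "g4"])
  # flags consistent with thresholds
  expect_identical(de$purity_filtered, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(de$highly_stromal, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # tau = 1 removes nothing; the survivors keep their relative order
  expect_length(purity_filter(de, tau = 1)$removed, 0)
  expect_identical(flt$filtered$gene,
                   de$gene[de$gene %in% flt$filtered$gene])
  # tau = 0 removes every gene with a defined nonzero correlation
  flt0 <- purity_filter(de, tau = 0)
  expect_setequal(flt0$filtered$gene, "g4")
  expect_error(purity_filter(de, tau = 2), "\\[0, 1\\]")
})

test_that("on synthetic cohorts the filter swaps compartment genes for culture genes", {
  co <- small_cohort()
  lg <- log_transform(co$matrix)
  tum <- subset_expr(lg, source = "tumour")
  sigs <- builtin_signatures(co$truth)
  sc <- estimate_scores(tum, sigs$stromal, sigs$immune)
  pc <- gene_purity_correlation(tum, sc)
  de <- annotate_purity(welch_t_per_gene(lg), pc)
  mech <- co$truth$gene_mechanism
  top <- top_fraction(de, 0.01)
  expect_gt(mean(mech[top] %in% c("stromal", "immune")), 0.5)
  flt <- purity_filter(de, 0.2)
  topf <- top_fraction(flt$filtered, 0.01)
  expect_gt(mean(mech[topf] %in% c("culture_up", "culture_down")), 0.5)
})
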