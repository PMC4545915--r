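# Small deterministic DE table builder: t statistics set directly.
fake_de <- function(tstats) {
  de <- data.frame(gene = names(tstats), t_statistic = unname(tstats),
                   df = 10, p_value = 2 * pt(-abs(unname(tstats)), 10),
                   stringsAsFactors = FALSE)
  de$q_value <- p.adjust(de$p_value, "BH")
  de$mean_cell_line <- 0
  de$mean_tumour <- 0
  de$direction <- sign(de$t_statistic)
  class(de) <- c("de_table", "data.frame")
  de
}

test_that("set-level mean t is the arithmetic member mean with a strict size cap", {
  ts <- setNames(c(2, 4, rep(0, 8)), paste0("g", 1:10))
  de <- fake_de(ts)
  res <- gage_test(de, list(gene_signature("up2", c("g1", "g2"))),
                   max_size = 200)
  expect_equal(res$mean_t, 3)
  expect_identical(res$direction, "up")

  # a set with exactly max_size present members is excluded
  ts20 <- setNames(c(rnorm(10, 2), rep(0, 10)), paste0("h", 1:20))
  de20 <- fake_de(ts20)
  big <- gene_signature("big", paste0("h", 1:10))
  expect_warning(out <- gage_test(de20, list(big), max_size = 10),
                 "size filter")
  expect_equal(nrow(out), 0)
  ok <- gage_test(de20, list(big), max_size = 11)
  expect_equal(ok$set_size, 10)

  # duplicate sets with identical member statistics score identically
  dup <- gage_test(de, list(gene_signature("a", c("g1", "g2")),
                            gene_signature("b", c("g1", "g2"))))
  expect_equal(dup$p_value[1], dup$p_value[2])
  expect_equal(dup$mean_t[1], dup$mean_t[2])
  expect_true(all(dup$q_value >= dup$p_value))
})

test_that("set significance equals a two-sample Welch test of member stats", {
  set.seed(6)
  ts <- setNames(rnorm(40), paste0("g", 1:40))
  de <- fake_de(ts)
  members <- paste0("g", 1:6)
  res <- gage_test(de, list(gene_signature("s", members)))
  tt <- t.test(ts[members], ts[setdiff(names(ts), members)])
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_identical(res$direction,
                   if (mean(ts[members]) >=
                       mean(ts[setdiff(names(ts), members)])) "up" else "down")

  # degenerate: both member and background statistics constant
  ts2 <- setNames(c(3, 3, 3, rep(0, 7)), paste0("g", 1:10))
  res2 <- gage_test(fake_de(ts2), list(gene_signature("c", paste0("g", 1:3))))
  expect_equal(res2$mean_t, 3)
  expect_equal(res2$p_value, 0)
  expect_identical(res2$direction, "up")
})

test_that("essential genes are significant, direction-concordant members", {
  # two significant concordant, one significant discordant, one null member
  ts <- setNames(c(6, 5, -6, 0.1, rep(0, 16)), paste0("g", 1:20))
  de <- fake_de(ts)
  res <- gage_test(de, list(gene_signature("s", paste0("g", 1:4))))
  res <- essential_genes(res, de, member_alpha = 0.05)
  expect_setequal(res$essential_genes[[1]], c("g1", "g2"))

  # no member significant -> empty
  ts_ns <- setNames(c(0.2, -0.1, rep(0, 8)), paste0("g", 1:10))
  de_ns <- fake_de(ts_ns)
  res_ns <- essential_genes(gage_test(de_ns,
                                      list(gene_signature("s", c("g1", "g2")))),
                            de_ns)
  expect_length(res_ns$essential_genes[[1]], 0)

  # all members significant with matching sign -> all members
  ts_all <- setNames(c(8, 9, 10, rep(0, 17)), paste0("g", 1:20))
  de_all <- fake_de(ts_all)
  res_all <- essential_genes(gage_test(de_all,
                                       list(gene_signature("s", paste0("g", 1:3)))),
                             de_all)
  expect_setequal(res_all$essential_genes[[1]], paste0("g", 1:3))
})

test_that("purity attribution averages essential-gene correlations", {
  ts <- setNames(c(6, 5, rep(0, 8)), paste0("g", 1:10))
  de <- fake_de(ts)
  purcor <- data.frame(gene = names(ts),
                       stromal_r = c(0.4, 0.6, rep(0, 8)),
                       immune_r = c(0.2, 0.4, rep(0, 8)),
                       purity_r = c(-0.5, -0.7, rep(0, 8)),
                       undefined = FALSE)
  res <- attribute_purity(essential_genes(gage_test(
    de, list(gene_signature("s", c("g1", "g2")))), de), purcor)
  expect_equal(res$mean_stromal_r, 0.5)
  expect_equal(res$mean_immune_r, 0.3)
  expect_equal(res$mean_purity_r, -0.6)

  # empty essential set -> NA attribution
  ts_ns <- setNames(c(0.1, -0.1, rep(0, 8)), paste0("g", 1:10))
  de_ns <- fake_de(ts_ns)
  res_ns <- attribute_purity(essential_genes(gage_test(
    de_ns, list(gene_signature("s", c("g1", "g2")))), de_ns), purcor)
  expect_true(is.na(res_ns$mean_stromal_r))
})

test_that("culture-up sets are called up with strong significance at effect 4", {
  cfg <- cohort_config(n_tumours = 60, n_cell_lines = 50, n_genes = 500,
                       culture_effect = 4, seed = 31)
  co <- generate_cohort(cfg)
  lg <- log_transform(co$matrix)
  de <- welch_t_per_gene(lg)
  sets <- truth_gene_sets(co$truth)
  res <- gage_test(de, sets)
  up <- res[res$set_id == "culture_up_program", ]
  expect_identical(up$direction, "up")
  expect_lt(up$q_value, 1e-4)
})
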