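test_that("search reports one row per TFR-evidenced pair with pathway summary", {
  fx <- gln3_fixture()
  res <- search_trps(fx$tfb, fx$tfr, tf_list = "GLN3", gene_list = "GZF3",
                     condition = fx$condition)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_trps, 2)
  expect_setequal(res$trp_lengths[[1]], c(2L, 3L))
  expect_equal(res$n_tfr_evidence, 1)
  expect_equal(res$n_tfb_evidence, 0)
})

test_that("search honors the deposit rule: no TFR evidence, no row", {
  tfb <- mk_pairs("A", "B", "TFB")
  tfr <- mk_pairs(c("A", "X"), c("B", "Y"), "TFR")
  # TFB-only pair never surfaces
  res <- search_trps(tfb, tfr, tf_list = c("A", "X"), gene_list = "ALL")
  expect_setequal(paste(res$tf, res$gene), c("A B", "X Y"))
  # TFR pair without any pathway still gets a row, with n_trps = 0
  expect_equal(res$n_trps[res$tf == "X"], 0)
  expect_error(search_trps(tfb, tfr, tf_list = character()),
               class = "trp_query_error")
})

test_that("search on the binding network uses the shortest-pathway miner", {
  fx <- gln3_fixture()
  res <- search_trps(fx$tfb, fx$tfr, tf_list = "GLN3", gene_list = "GZF3",
                     condition = fx$condition, network_kind = "binding")
  expect_equal(res$n_trps, 1)              # only GLN3->GAT1->GZF3
  expect_equal(res$trp_lengths[[1]], 2L)
})

test_that("browse lists targets of TFs and regulators of genes", {
  fx <- gln3_fixture()
  by_tf <- browse_trps(fx$tfb, fx$tfr, "GLN3", axis = "by_tf",
                       condition = fx$condition)
  expect_setequal(by_tf$gene, c("GAT1", "DAL80", "GZF3"))
  by_gene <- browse_trps(fx$tfb, fx$tfr, "GZF3", axis = "by_gene",
                         condition = fx$condition)
  expect_true("GLN3" %in% by_gene$tf)
})

test_that("browse filters counterparts by functional category", {
  fx <- gln3_fixture()
  cats <- tibble::tibble(
    symbol = c("GAT1", "DAL80", "GZF3"),
    category = c("nitrogen metabolism", "nitrogen metabolism",
                 "transcription"))
  kept <- browse_trps(fx$tfb, fx$tfr, "GLN3", axis = "by_tf",
                      condition = fx$condition, categories = cats,
                      category = "nitrogen metabolism")
  expect_setequal(kept$gene, c("GAT1", "DAL80"))
  expect_warning(
    none <- browse_trps(fx$tfb, fx$tfr, "GLN3", axis = "by_tf",
                        condition = fx$condition, categories = cats,
                        category = "no such category"),
    class = "trp_category_warning")
  expect_equal(nrow(none), 0)
})

test_that("the detail report carries the four parts of the worked example", {
  fx <- gln3_fixture()
  rep <- build_detail_report(fx$tfb, fx$tfr, "GLN3", "GZF3",
                             condition = fx$condition, corpus = fx$corpus)
  expect_equal(rep$part1$n_tfr_evidence, 1)
  expect_equal(rep$part1$n_tfb_evidence, 0)
  expect_equal(nrow(rep$part2), 2)
  expect_equal(rep$part2$confidence, c(1, 1))
  expect_equal(nrow(rep$part3), 3 + 6)
  # part3 label law: direct pairs have both kinds, indirect pairs lack TFB
  direct <- rep$part3[rep$part3$label == "direct regulatory pair", ]
  expect_true(all(direct$has_tfr & direct$has_tfb))
  indirect <- rep$part3[rep$part3$label == "indirect regulatory target pair", ]
  expect_true(all(!indirect$has_tfb))
  g <- glance(rep)
  expect_equal(g$n_trps, 2)
  expect_equal(g$n_known, 1)
  expect_equal(nrow(tidy(rep)), 2)
})

test_that("detail queries enforce the TFR-evidence precondition", {
  tfb <- mk_pairs("A", "B", "TFB")
  tfr <- mk_pairs("A", "B", "TFR")
  expect_error(build_detail_report(tfb, tfr, "B", "A"),
               regexp = "TFR evidence", class = "trp_query_error")
  # a pair with only the direct edge yields a single length-1 pathway
  rep <- build_detail_report(tfb, tfr, "A", "B")
  expect_equal(rep$part2$nodes, list(c("A", "B")))
  expect_equal(rep$part2$length, 1L)
})

test_that("per-condition statistics count evidence and explainable pairs", {
  fx <- gln3_fixture()
  st <- condition_stats(fx$tfb, fx$tfr, explainable = TRUE)
  row <- st[st$condition == fx$condition, ]
  expect_equal(row$n_tfr_pairs, 6)
  expect_equal(row$n_tfb_pairs, 4)
  expect_equal(row$n_direct_pairs, 4)
  # all six TFR pairs lie on direct-network paths
  expect_equal(row$n_explainable, 6)
  expect_equal(row$pct_explainable, 100)
  expect_equal(st$n_tfr_pairs[st$condition == "stress"], 0)
})

test_that("network and pathway autoplots build without error", {
  fx <- gln3_fixture()
  net <- build_direct_regulatory_network(fx$tfb, fx$tfr, fx$condition)
  p1 <- autoplot(net)
  expect_s3_class(p1, "ggplot")
  paths <- enumerate_all_trps(net, "GLN3", "GZF3")
  p2 <- autoplot(paths, network = net)
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
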