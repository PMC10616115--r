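test_that("build_overlap keeps exactly the KB edges into DE genes", {
  net <- build_overlap(toy_kb(), toy_de_genes())
  # g3, g4 are not DE; g5 is DE but absent from the KB
  expect_equal(nrow(net), 3L)
  expect_setequal(unique(net$cdt_id), c("c1", "c2"))
  expect_false("g3" %in% net$gene_id)
  expect_false("g5" %in% net$gene_id)

  no_overlap <- toy_de_genes()[toy_de_genes()$gene_id == "g5", ]
  expect_message(empty <- build_overlap(toy_kb(), no_overlap), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("edges are labelled by sign agreement and the labels partition E", {
  net <- label_edges(build_overlap(toy_kb(), toy_de_genes()))
  # activation edge onto up-regulated g1 supports H1
  expect_true(net$h1_support[net$cdt_id == "c1" & net$gene_id == "g1"])
  # inhibition edge onto down-regulated g2 supports H1 (signs agree)
  expect_true(net$h1_support[net$cdt_id == "c1" & net$gene_id == "g2"])
  # inhibition edge onto up-regulated g1 supports H2
  expect_false(net$h1_support[net$cdt_id == "c2" & net$gene_id == "g1"])
  expect_equal(sum(net$h1_support) + sum(!net$h1_support), nrow(net))
})

test_that("contingency tables count focal and non-focal support", {
  net <- label_edges(build_overlap(toy_kb(), toy_de_genes()))
  expect_equal(contingency_for(net, "c1"),
               tibble::tibble(l = 2L, k = 0L, m = 0L, n = 1L))
  expect_equal(contingency_for(net, "c2"),
               tibble::tibble(l = 0L, k = 1L, m = 2L, n = 0L))
  expect_error(contingency_for(net, "nope"), "no edge")

  # single CDT owning all edges
  solo <- tibble::tibble(cdt_id = "c", gene_id = paste0("g", 1:4),
                         sign = c(1L, 1L, 1L, -1L),
                         de_sign = c(1L, 1L, 1L, 1L))
  tab <- contingency_for(label_edges(solo), "c")
  expect_equal(unlist(tab), c(l = 3L, k = 1L, m = 0L, n = 0L))
})

test_that("summing l over CDTs recovers the H1 edge total", {
  cfg <- sim_config(seed = 5, agreement_noise = 0.3,
                    background_de_rate = 0.1)
  kb <- generate_kb(cfg)
  de <- generate_profile(kb, "CDT10", cfg)
  net <- label_edges(build_overlap(kb, select_de_genes(de)))
  res <- test_all(net)
  expect_equal(sum(res$l), sum(net$h1_support))
  expect_equal(sum(res$l + res$k + res$m + res$n),
               nrow(res) * nrow(net))
})

test_that("the one-sided Fisher tail matches hand-derived values", {
  expect_equal(fisher_one_sided(0, 5, 0, 5), 1.0)
  expect_equal(fisher_one_sided(2, 0, 0, 3), 0.1)
  expect_equal(fisher_one_sided(3, 1, 1, 5), 25 / 210)
  expect_equal(p_value_h2(0, 2, 3, 0), 0.1)
  expect_error(fisher_one_sided(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_one_sided(0, 0, 0, 0), "at least one")
})

test_that("the Fisher tail agrees with enumeration and stats::fisher.test", {
  set.seed(31)
  for (i in 1:60) {
    cells <- as.integer(stats::rmultinom(1, sample(4:40, 1), rep(1, 4)))
    l <- cells[1]; k <- cells[2]; m <- cells[3]; n <- cells[4]
    expect_equal(fisher_one_sided(l, k, m, n),
                 enum_fisher_upper(l, k, m, n), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(l, m, k, n), 2),
                             alternative = "greater")
    expect_equal(fisher_one_sided(l, k, m, n), ft$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the strict tail is the inclusive tail minus the observed table", {
  expect_equal(fisher_one_sided(2, 0, 0, 3, tail = "strict"), 0)
  p_inc <- fisher_one_sided(3, 1, 1, 5)
  p_str <- fisher_one_sided(3, 1, 1, 5, tail = "strict")
  expect_equal(p_inc - p_str, choose(4, 3) * choose(6, 1) / choose(10, 4))
})

test_that("column-swap duality and involution hold exactly", {
  set.seed(17)
  for (i in 1:40) {
    cells <- as.integer(stats::rmultinom(1, sample(2:50, 1), rep(1, 4)))
    l <- cells[1]; k <- cells[2]; m <- cells[3]; n <- cells[4]
    expect_identical(p_value_h2(l, k, m, n),
                     fisher_one_sided(k, l, n, m))
    # swapping twice returns the H1 p-value
    expect_identical(p_value_h2(k, l, n, m),
                     fisher_one_sided(l, k, m, n))
  }
  # symmetric tables have equal tails
  expect_equal(fisher_one_sided(3, 3, 5, 5), p_value_h2(3, 3, 5, 5))
})

test_that("negating every DE sign swaps the two hypothesis p-values", {
  cfg <- sim_config(seed = 23, agreement_noise = 0.2,
                    background_de_rate = 0.1)
  kb <- generate_kb(cfg)
  de <- select_de_genes(generate_profile(kb, "CDT05", cfg))
  flipped <- dplyr::mutate(de, sign = -sign, log_fc = -log_fc)

  res <- tibble::as_tibble(pure_test(kb, de))
  res_f <- tibble::as_tibble(pure_test(kb, flipped))
  res_f <- res_f[match(res$cdt_id, res_f$cdt_id), ]
  expect_equal(res$p_h1, res_f$p_h2)
  expect_equal(res$p_h2, res_f$p_h1)
})

test_that("the H1 tail shrinks as focal support grows at fixed margins", {
  # grow l along the diagonal shift that preserves all margins
  ps <- fisher_one_sided(l = 2:6, k = 6:2, m = 8 - (0:4), n = 4 + (0:4))
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment matches the hand-computed step-up and its contracts", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(7)
  p <- stats::runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(50)
  expect_equal(fdr_adjust(p[perm]), adj[perm])  # permutation equivariance
})

test_that("average ranks follow the tie convention and conserve rank sums", {
  expect_equal(rank_results(c(0.1, 0.1, 0.1, 0.1, 0.5)),
               c(2.5, 2.5, 2.5, 2.5, 5))
  expect_equal(rank_results(c(0.1, 0.1, 0.5)), c(1.5, 1.5, 3))
  expect_equal(rank_results(1:7), as.numeric(1:7))
  set.seed(13)
  for (i in 1:20) {
    x <- sample(stats::rpois(sample(3:30, 1), 3))
    n <- length(x)
    expect_equal(sum(rank_results(x)), n * (n + 1) / 2)
  }
})

test_that("test_all returns one row per CDT and orders deterministically", {
  cfg <- sim_config(seed = 2)
  kb <- generate_kb(cfg)
  de <- select_de_genes(generate_profile(kb, "CDT01", cfg))
  net <- label_edges(build_overlap(kb, de))
  res <- test_all(net)
  expect_equal(nrow(res), length(unique(net$cdt_id)))
  expect_identical(tibble::as_tibble(res), tibble::as_tibble(test_all(net)))

  empty <- test_all(net[0, ])
  expect_s3_class(empty, "pure_result")
  expect_equal(nrow(empty), 0L)
})

test_that("a CDT whose edges dominate the H1 support attains the minimum p", {
  # 3 CDTs: "a" owns 6 agreeing edges, "b" and "c" own mixed edges
  net <- tibble::tibble(
    cdt_id = c(rep("a", 6), rep("b", 4), rep("c", 4)),
    gene_id = paste0("g", 1:14),
    sign = 1L,
    de_sign = c(rep(1L, 6), 1L, -1L, -1L, -1L, 1L, 1L, -1L, -1L)
  )
  res <- test_all(label_edges(net))
  expect_equal(res$cdt_id[which.min(res$p_h1)], "a")
  expect_equal(res$rank_h1[res$cdt_id == "a"], 1)
})

test_that("significance calls honour the inclusive alpha and both-calls", {
  res <- tibble::tibble(
    cdt_id = c("a", "b", "c"),
    fdr_h1 = c(0.05, 0.2, 0.01),
    fdr_h2 = c(0.9, 0.9, 0.02)
  )
  sig <- significant_set(res, alpha = 0.05)
  expect_equal(sig$call[sig$cdt_id == "a"], "present")  # boundary inclusive
  expect_false("b" %in% sig$cdt_id)
  expect_equal(sig$call[sig$cdt_id == "c"], "both")
})

test_that("FDR families can be pooled across hypotheses", {
  cfg <- sim_config(seed = 19)
  kb <- generate_kb(cfg)
  de <- select_de_genes(generate_profile(kb, "CDT03", cfg))
  by_h <- pure_test(kb, de, fdr = "by_hypothesis")
  pooled <- pure_test(kb, de, fdr = "pooled")
  expect_equal(sort(by_h$p_h1), sort(pooled$p_h1))  # raw p unchanged
  m <- nrow(by_h)
  # pooling doubles the family size, so no adjusted value can shrink
  merged <- dplyr::inner_join(tibble::as_tibble(by_h),
                              tibble::as_tibble(pooled),
                              by = "cdt_id", suffix = c("_f", "_p"))
  expect_true(all(merged$fdr_h1_p >= merged$fdr_h1_f - 1e-12))
})
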