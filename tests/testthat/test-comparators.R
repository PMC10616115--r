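test_that("ORA p-values match hand-derived values and degenerate cases", {
  expect_equal(ora_pvalue(100, 10, 5, 0), 1.0)
  expect_equal(ora_pvalue(10, 4, 4, 3), 25 / 210)
  # every background gene targeted: the overlap is forced
  expect_equal(ora_pvalue(20, 20, 7, 7), 1.0)
  expect_error(ora_pvalue(10, 12, 4, 3), "Impossible")
  expect_error(ora_pvalue(10, 4, 4, 5), "Impossible")
})

test_that("ORA agrees with full hypergeometric enumeration", {
  for (N in c(5, 12, 25)) {
    for (M in 0:N) {
      for (n in c(0, 3, N %/% 2, N)) {
        if (n > N) next
        for (x in 0:min(M, n)) {
          mass <- vapply(0:min(M, n), function(i) {
            choose(M, i) * choose(N - M, n - i) / choose(N, n)
          }, numeric(1))
          expect_equal(ora_pvalue(N, M, n, x), sum(mass[(0:min(M, n)) >= x]),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("KS enrichment matches the two-sample sup-difference", {
  same <- ks_enrichment(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- ks_enrichment(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(sep$statistic, 1)

  # interleaved 3 vs 3: oracle = direct sweep over the pooled support
  hits <- c(1, 4, 5); miss <- c(2, 3, 6)
  cdf <- function(v, x) mean(v <= x)
  d_oracle <- max(vapply(sort(c(hits, miss)),
                         function(x) abs(cdf(hits, x) - cdf(miss, x)),
                         numeric(1)))
  expect_equal(ks_enrichment(hits, miss)$statistic, d_oracle)
  expect_error(ks_enrichment(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon enrichment reports the hit rank sum with an exact p", {
  res <- wilcoxon_enrichment(c(10, 11), c(1, 2, 3))
  expect_equal(res$statistic, 9)  # ranks 4 + 5
  # oracle: exact permutation distribution over the 10 assignments
  r <- rank(c(10, 11, 1, 2, 3))
  w_all <- utils::combn(5, 2, function(i) sum(r[i]))
  mu <- 2 * 6 / 2
  p_oracle <- mean(abs(w_all - mu) >= abs(9 - mu))
  expect_equal(res$p_value, p_oracle)

  expect_equal(wilcoxon_enrichment(1, 2)$p_value, 1)

  identical_groups <- wilcoxon_enrichment(c(1, 2, 3), c(1, 2, 3))
  expect_equal(identical_groups$statistic, 3 * 7 / 2)
  expect_gt(identical_groups$p_value, 0.9)
})

test_that("preranked GSEA finds maximal enrichment and respects min_size", {
  set.seed(41)
  scores <- stats::setNames(sort(stats::rnorm(100), decreasing = TRUE),
                            paste0("g", 1:100))
  top <- gsea_preranked(scores, names(scores)[1:20], nperm = 999,
                        min_size = 15, seed = 1)
  expect_gt(top$es, 0)
  expect_lte(top$p_value, 1 / 1000)
  expect_equal(top$status, "tested")

  small <- gsea_preranked(scores, names(scores)[1:5], nperm = 99,
                          min_size = 15, seed = 1)
  expect_equal(small$status, "not_tested")
  expect_true(is.na(small$p_value))
})

test_that("reversing the ranking flips the ES sign for an extreme set", {
  set.seed(42)
  scores <- stats::setNames(stats::rnorm(60), paste0("g", 1:60))
  set_ids <- names(sort(scores, decreasing = TRUE))[1:16]
  fwd <- gsea_preranked(scores, set_ids, nperm = 9, seed = 2)
  rev <- gsea_preranked(-scores, set_ids, nperm = 9, seed = 2)
  expect_equal(rev$es, -fwd$es, tolerance = 1e-12)
})

test_that("GSEA permutation p-values are reproducible bit for bit", {
  set.seed(4)
  scores <- stats::setNames(stats::rnorm(80), paste0("g", 1:80))
  gs <- sample(names(scores), 20)
  a <- gsea_preranked(scores, gs, nperm = 200, seed = 7)
  b <- gsea_preranked(scores, gs, nperm = 200, seed = 7)
  expect_identical(a, b)
  # and a random set is not flagged as extreme
  expect_gt(a$p_value, 1 / 201)
})

test_that("the enrichment score matches fgsea's statistic at exponent 1", {
  set.seed(8)
  scores <- stats::setNames(sort(stats::rnorm(50), decreasing = TRUE),
                            paste0("g", 1:50))
  gs <- sample(names(scores), 17)
  mine <- gsea_preranked(scores, gs, nperm = 1, min_size = 1, seed = 1)$es
  ref <- fgsea::calcGseaStat(scores, selectedStats = which(names(scores)
                                                           %in% gs),
                             gseaParam = 1)
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("the IPA overlap sum equals the exhaustive Fisher upper tail", {
  expect_equal(ipa_overlap_p(1, 0, 0, 0), 1)
  expect_equal(ipa_overlap_p(0, 3, 2, 0), 1)  # least extreme observation
  expect_equal(ipa_overlap_p(3, 1, 1, 5), fisher_one_sided(3, 1, 1, 5),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:40) {
    cells <- as.integer(stats::rmultinom(1, sample(2:40, 1), rep(1, 4)))
    expect_equal(ipa_overlap_p(cells[1], cells[2], cells[3], cells[4]),
                 enum_fisher_upper(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  expect_error(ipa_overlap_p(-1, 1, 1, 1), "non-negative")
})

test_that("activation z-scores match the closed form and calling rule", {
  all_agree <- ipa_zscore(rep(1, 4), rep(1, 4), rep(1, 4))
  expect_equal(all_agree$z, 2)
  expect_equal(all_agree$call, "activated")

  half <- ipa_zscore(rep(1, 4), rep(1, 4), c(1, 1, -1, -1))
  expect_equal(half$z, 0)
  expect_equal(half$call, "none")

  weighted <- ipa_zscore(c(2, 1), c(1, 1), c(1, -1))
  expect_equal(weighted$z, 1 / sqrt(5))

  single <- ipa_zscore(1, 1, -1)
  expect_equal(abs(single$z), 1)  # a lone edge can never reach |z| = 2
  expect_equal(single$call, "none")

  undefined <- ipa_zscore(numeric(0), integer(0), integer(0))
  expect_true(is.na(undefined$z))
  expect_equal(undefined$call, "none")
})

test_that("z grows as the square root of the agreeing unit-weight edges", {
  for (m in c(1, 4, 9, 16)) {
    expect_equal(ipa_zscore(rep(1, m), rep(1, m), rep(1, m))$z, sqrt(m))
  }
})

test_that("run_method validates names and produces ranked reports", {
  expect_error(run_method("magic", toy_kb(), NULL), "Unknown method")

  cfg <- sim_config(seed = 6)
  kb <- generate_kb(cfg)
  de <- generate_profile(kb, "CDT02", cfg)
  rep_pure <- run_method("pure", kb, de)
  expect_setequal(names(rep_pure),
                  c("method", "cdt_id", "statistic", "p_or_z", "significant",
                    "rank"))
  expect_equal(rank_of_true(rep_pure, "CDT02")$rank_of_true, 1)

  ranks <- rep_pure$rank[!is.na(rep_pure$rank)]
  expect_equal(sum(ranks), length(ranks) * (length(ranks) + 1) / 2)

  # determinism: identical inputs and seed give identical reports
  expect_identical(run_method("gsea", kb, de,
                              params = list(nperm = 50, min_size = 3)),
                   run_method("gsea", kb, de,
                              params = list(nperm = 50, min_size = 3)))
})

test_that("sign-blind methods ignore edge signs; PURE and z-score do not", {
  cfg <- sim_config(seed = 14, background_de_rate = 0.1)
  kb <- generate_kb(cfg)
  de <- generate_profile(kb, "CDT04", cfg)
  kb_flip <- dplyr::mutate(kb, sign = -sign)

  for (mth in c("ora", "ks", "wilcoxon")) {
    expect_identical(run_method(mth, kb, de), run_method(mth, kb_flip, de),
                     info = mth)
  }
  gsea_p <- list(nperm = 50, min_size = 3)
  expect_identical(run_method("gsea", kb, de, gsea_p),
                   run_method("gsea", kb_flip, de, gsea_p))

  pure_a <- run_method("pure", kb, de)
  pure_b <- run_method("pure", kb_flip, de)
  expect_false(identical(pure_a$statistic, pure_b$statistic))
  # flipping edge signs negates every z-score
  z_a <- run_method("ipa_like", kb, de)
  z_b <- run_method("ipa_like", kb_flip, de)
  z_b <- z_b[match(z_a$cdt_id, z_b$cdt_id), ]
  expect_equal(z_a$p_or_z, -z_b$p_or_z)
})

test_that("an all-agreeing 4-edge regulator is called activated", {
  kb <- tibble::tibble(
    cdt_id = c(rep("hit", 4), rep("other", 2)),
    cdt_name = cdt_id, gene_id = paste0("g", c(1:4, 1, 2)),
    gene_symbol = gene_id, sign = c(rep(1L, 4), 1L, -1L),
    weight = 1, organism = "synthetic", provenance = "test"
  )
  de <- tibble::tibble(gene_id = paste0("g", 1:4),
                       log_fc = rep(1.5, 4), p_value = rep(0.001, 4))
  rep_z <- run_method("ipa_like", kb, de)
  expect_true(rep_z$significant[rep_z$cdt_id == "hit"])
  expect_equal(rep_z$p_or_z[rep_z$cdt_id == "hit"], 2)
  expect_false(rep_z$significant[rep_z$cdt_id == "other"])
})
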