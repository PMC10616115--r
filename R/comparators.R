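#' Over-representation p-value (hypergeometric upper tail)
#'
#' Probability of observing `x` or more DE genes among the `M` targets of a
#' CDT, drawing `n` DE genes from `N` background genes:
#' \deqn{P(X \ge x) = 1 - \sum_{i=0}^{x-1}
#'   \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}.}
#' Signs of genes and edges play no role.
#'
#' @param N Background size (genes eligible for testing).
#' @param M Number of background genes targeted by the CDT.
#' @param n Number of DE genes in the background.
#' @param x Number of DE genes among the CDT's targets.
#' @return The upper-tail probability.
#' @export
#' @examples
#' ora_pvalue(10, 4, 4, 3)  # 25/210
ora_pvalue <- function(N, M, n, x) {
  if (any(c(N, M, n, x) < 0) || M > N || n > N || x > min(M, n)) {
    stop("Impossible hypergeometric counts (need x <= min(M, n); M, n <= N)",
         call. = FALSE)
  }
  if (x == 0) return(1)
  # the complement identity 1 - P(X <= x-1) cancels catastrophically when the
  # upper tail is tiny; summing the tail directly is the same quantity
  i <- x:min(M, n)
  min(1, sum(exp(lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n))))
}

#' Two-sample KS enrichment test on fold-change scores
#'
#' Compares the empirical CDF of the log fold-changes of DE genes targeted
#' by a CDT ("DEhit") against that of the remaining DE genes ("DEmiss") with
#' the two-sided two-sample Kolmogorov-Smirnov test. Uses fold-change signs
#' but ignores edge signs.
#'
#' @param hit_scores,miss_scores Log fold-changes of the two groups; both
#'   must be non-empty.
#' @return A one-row tibble with `statistic` (D) and `p_value`.
#' @export
ks_enrichment <- function(hit_scores, miss_scores) {
  if (length(hit_scores) == 0 || length(miss_scores) == 0) {
    stop("Both DEhit and DEmiss must be non-empty for the KS test",
         call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(hit_scores, miss_scores,
                                        alternative = "two.sided"))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value))
}

#' Wilcoxon rank-sum enrichment test on fold-change scores
#'
#' Pools DEhit and DEmiss fold-changes, ranks them, and reports the rank sum
#' `W` of the hit group with a two-sided p-value (exact for small untied
#' samples, normal approximation with tie correction otherwise, via
#' `stats::wilcox.test`).
#'
#' @inheritParams ks_enrichment
#' @return A one-row tibble with `statistic` (the hit-group rank sum `W`)
#'   and `p_value`.
#' @export
wilcoxon_enrichment <- function(hit_scores, miss_scores) {
  if (length(hit_scores) == 0 || length(miss_scores) == 0) {
    stop("Both DEhit and DEmiss must be non-empty for the Wilcoxon test",
         call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(hit_scores, miss_scores,
                                            alternative = "two.sided"))
  n_hit <- length(hit_scores)
  W <- unname(wt$statistic) + n_hit * (n_hit + 1) / 2  # U -> rank sum
  tibble::tibble(statistic = W, p_value = unname(wt$p.value))
}

#' Preranked gene-set enrichment by gene permutation
#'
#' Classic weighted Kolmogorov-Smirnov-style enrichment: genes are ordered
#' by decreasing score, the running sum gains `|score| / NR` at each gene of
#' the set and loses `1 / (N - Nh)` elsewhere, and the enrichment score (ES)
#' is the largest deviation from zero. Significance comes from a
#' gene-permutation null of `nperm` random sets of the same size, with the
#' +1 correction: `p = (1 + #permutations with |ES*| >= |ES|) / (nperm + 1)`.
#' The weight exponent is 1.
#'
#' @param scores Named numeric vector of gene-level scores (names = gene
#'   ids), typically log fold-changes of all measured genes.
#' @param gene_set Character vector of gene ids.
#' @param nperm Number of permutations (default `1e4`).
#' @param min_size Minimum size of the set after intersection with the
#'   scored genes (default 15); smaller sets are reported `not_tested`
#'   with `NA` statistics rather than dropped silently.
#' @param seed Optional integer; when supplied the permutation draw is
#'   seeded locally (the caller's RNG state is untouched) so p-values are
#'   reproducible bit for bit.
#' @return A one-row tibble: `es`, `p_value`, `n_hits`, `nperm`, `status`
#'   (`"tested"` or `"not_tested"`).
#' @export
gsea_preranked <- function(scores, gene_set, nperm = 1e4, min_size = 15,
                           seed = NULL) {
  stopifnot(nperm >= 1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  hit_pos <- which(names(s) %in% gene_set)
  nh <- length(hit_pos)
  N <- length(s)
  if (nh < min_size || nh == N) {
    return(tibble::tibble(es = NA_real_, p_value = NA_real_, n_hits = nh,
                          nperm = as.integer(nperm), status = "not_tested"))
  }
  s_abs <- abs(s)
  es_obs <- gsea_es(s_abs, hit_pos, N)
  perm <- local_seed(seed, {
    vapply(seq_len(nperm), function(i) {
      gsea_es(s_abs, sample.int(N, nh), N)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(es_obs))) / (nperm + 1)
  tibble::tibble(es = es_obs, p_value = p, n_hits = nh,
                 nperm = as.integer(nperm), status = "tested")
}

# running-sum extreme evaluated only where extremes can occur: at each hit
# (candidate maximum) and just before each hit (candidate minimum)
gsea_es <- function(s_abs, hit_pos, N) {
  hit_pos <- sort(hit_pos)
  w <- s_abs[hit_pos]
  NR <- sum(w)
  if (NR == 0) {
    w[] <- 1
    NR <- length(w)
  }
  nm <- N - length(hit_pos)
  p_hit <- cumsum(w) / NR
  p_miss <- (hit_pos - seq_along(hit_pos)) / nm
  top <- p_hit - p_miss
  bottom <- c(0, p_hit[-length(p_hit)]) - p_miss
  mx <- max(top)
  mn <- min(bottom)
  if (mx >= -mn) mx else mn
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' IPA-style overlap p-value
#'
#' One-sided Fisher exact p-value for the enrichment of a regulator's
#' targets among the DE genes, parameterised gene-wise: `a` DE genes
#' regulated by `r`, `b` DE genes not regulated, `c` regulated but not DE,
#' and `d = n - a - b - c` with `n` background genes. The tail sum
#' \deqn{p(r) = \sum_k \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}
#'   {(a+k)!\,(b-k)!\,(c-k)!\,(d+k)!\,n!}}
#' runs over every table reachable by shifting mass into the `a` cell, i.e.
#' `k = 0, ..., min(b, c)` (beyond which the factorial terms vanish), which
#' makes it the exact upper tail of the hypergeometric distribution.
#'
#' @param a,b,c,d Non-negative gene counts as above.
#' @return The overlap p-value.
#' @export
ipa_overlap_p <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    stop("Overlap counts must be non-negative", call. = FALSE)
  }
  n <- a + b + c + d
  if (n < 1) stop("Overlap table must contain at least one gene",
                  call. = FALSE)
  k <- 0:min(b, c)
  terms <- exp(lfactorial(a + b) + lfactorial(c + d) + lfactorial(a + c) +
                 lfactorial(b + d) -
                 (lfactorial(a + k) + lfactorial(b - k) + lfactorial(c - k) +
                    lfactorial(d + k) + lfactorial(n)))
  min(1, sum(terms))
}

#' Activation z-score of a regulator
#'
#' Weighted agreement between a regulator's edge signs and the observed DE
#' signs of its targets:
#' \deqn{z = \frac{\sum_v w(v)\, s_R(v)\, s_D(v)}
#'   {\left(\sum_v w(v)^2\right)^{1/2}},}
#' approximately standard normal when signs are random. Calls `activated`
#' at `z >= 2` and `inhibited` at `z <= -2`. A regulator with no DE targets
#' (or all-zero weights) gets no z-score (`NA`, call `"none"`), mirroring
#' tools that omit the score in that case; note a single unit-weight edge
#' yields `|z| = 1` and can never be called — significance requires
#' accumulated agreeing evidence.
#'
#' @param weight Non-negative regulation weights.
#' @param s_r Edge signs, +1 activation / -1 inhibition.
#' @param s_d DE signs of the targeted genes, +1 up / -1 down.
#' @return A one-row tibble with `z` and `call`
#'   (`activated` / `inhibited` / `none`).
#' @export
#' @examples
#' ipa_zscore(rep(1, 4), rep(1, 4), rep(1, 4))  # z = 2, activated
ipa_zscore <- function(weight, s_r, s_d) {
  stopifnot(length(weight) == length(s_r), length(s_r) == length(s_d))
  if (length(weight) == 0 || all(weight == 0)) {
    return(tibble::tibble(z = NA_real_, call = "none"))
  }
  if (any(weight < 0)) stop("Weights must be non-negative", call. = FALSE)
  z <- sum(weight * s_r * s_d) / sqrt(sum(weight^2))
  call <- if (z >= 2) "activated" else if (z <= -2) "inhibited" else "none"
  tibble::tibble(z = z, call = call)
}

#' Run one upstream-regulator method over a knowledge base and DE profile
#'
#' Common harness producing a ranked, significance-flagged CDT list (a
#' "method report") from any of the seven methods, so that different methods
#' are directly comparable. P-value methods (`pure`, `ora`, `ks`,
#' `wilcoxon`, `gsea`) are ranked by FDR-adjusted p-value and called
#' significant at adjusted p `<= 0.05`; z-score methods (`ipa_like`,
#' `ipa_cdt_like`) are ranked by decreasing `|z|` and called significant at
#' `|z| >= 2`. Ties receive average ranks throughout; CDTs a method cannot
#' score (e.g. gene sets below `min_size` for GSEA, no DE target for the
#' z-score) keep `NA` statistics and `NA` ranks.
#'
#' `ipa_cdt_like` is the report restricted to chemical regulators; since
#' this knowledge base contains only CDTs, it differs from `ipa_like` by
#' label only.
#'
#' @param method One of `"pure"`, `"ora"`, `"ks"`, `"wilcoxon"`, `"gsea"`,
#'   `"ipa_like"`, `"ipa_cdt_like"`.
#' @param kb Knowledge-base edge tibble.
#' @param de Full DE profile tibble (`gene_id`, `log_fc`, `p_value`).
#' @param params Named list of method parameters: `logfc_cut`, `p_cut`,
#'   `alpha` (defaults 0.6 / 0.05 / 0.05), `hypothesis` (`"H1"` default or
#'   `"H2"`; used by `pure` to pick the ranking family and by the z-score
#'   methods to orient the significance call), `nperm` (GSEA, default
#'   `1e4`), `min_size` (GSEA, default 15), `seed` (GSEA permutations,
#'   default 1).
#' @return A method-report tibble: `method`, `cdt_id`, `statistic` (the
#'   ranking statistic: adjusted p or z), `p_or_z` (raw p-value or z),
#'   `significant` (logical), `rank`.
#' @export
run_method <- function(method, kb, de, params = list()) {
  methods <- c("pure", "ora", "ks", "wilcoxon", "gsea", "ipa_like",
               "ipa_cdt_like")
  if (!is.character(method) || length(method) != 1 || !method %in% methods) {
    stop("Unknown method '", paste(method, collapse = ","),
         "'; use one of: ", paste(methods, collapse = ", "), call. = FALSE)
  }
  p <- utils::modifyList(
    list(logfc_cut = 0.6, p_cut = 0.05, alpha = 0.05, hypothesis = "H1",
         nperm = 1e4, min_size = 15, seed = 1),
    params)
  stopifnot(p$hypothesis %in% c("H1", "H2"))

  de_genes <- select_de_genes(de, logfc_cut = p$logfc_cut, p_cut = p$p_cut)

  report <- switch(
    method,
    pure = report_pure(kb, de_genes, p),
    ora = report_ora(kb, de, de_genes, p),
    ks = report_scorecmp(kb, de_genes, p, ks_enrichment),
    wilcoxon = report_scorecmp(kb, de_genes, p, wilcoxon_enrichment),
    gsea = report_gsea(kb, de, p),
    ipa_like = report_zscore(kb, de_genes, p),
    ipa_cdt_like = report_zscore(kb, de_genes, p)
  )
  report <- dplyr::arrange(report, dplyr::coalesce(.data$rank, Inf),
                           .data$cdt_id)
  tibble::tibble(method = method, report)
}

report_pure <- function(kb, de_genes, p) {
  res <- pure_test(kb, de_genes, alpha = p$alpha)
  if (p$hypothesis == "H1") {
    tibble::tibble(cdt_id = res$cdt_id, statistic = res$fdr_h1,
                   p_or_z = res$p_h1,
                   significant = res$fdr_h1 <= p$alpha, rank = res$rank_h1)
  } else {
    tibble::tibble(cdt_id = res$cdt_id, statistic = res$fdr_h2,
                   p_or_z = res$p_h2,
                   significant = res$fdr_h2 <= p$alpha, rank = res$rank_h2)
  }
}

report_ora <- function(kb, de, de_genes, p) {
  background <- intersect(unique(de$gene_id), unique(kb$gene_id))
  n_de <- sum(de_genes$gene_id %in% background)
  tab <- kb |>
    dplyr::filter(.data$gene_id %in% background) |>
    dplyr::summarise(
      M = dplyr::n_distinct(.data$gene_id),
      x = dplyr::n_distinct(.data$gene_id[.data$gene_id %in%
                                            de_genes$gene_id]),
      .by = "cdt_id")
  pv <- mapply(ora_pvalue, N = length(background), M = tab$M, n = n_de,
               x = tab$x)
  finish_p_report(tab$cdt_id, pv, p$alpha)
}

report_scorecmp <- function(kb, de_genes, p, test_fun) {
  targets <- kb |>
    dplyr::filter(.data$gene_id %in% de_genes$gene_id) |>
    dplyr::distinct(.data$cdt_id, .data$gene_id)
  cdts <- unique(targets$cdt_id)
  pv <- vapply(cdts, function(cd) {
    hit_genes <- targets$gene_id[targets$cdt_id == cd]
    hits <- de_genes$log_fc[de_genes$gene_id %in% hit_genes]
    miss <- de_genes$log_fc[!de_genes$gene_id %in% hit_genes]
    if (length(hits) == 0 || length(miss) == 0) return(NA_real_)
    test_fun(hits, miss)$p_value
  }, numeric(1))
  finish_p_report(cdts, pv, p$alpha)
}

report_gsea <- function(kb, de, p) {
  scores <- stats::setNames(de$log_fc, de$gene_id)
  sets <- split(kb$gene_id, kb$cdt_id)
  pv <- vapply(seq_along(sets), function(i) {
    gsea_preranked(scores, unique(sets[[i]]), nperm = p$nperm,
                   min_size = p$min_size, seed = p$seed + i)$p_value
  }, numeric(1))
  finish_p_report(names(sets), pv, p$alpha)
}

report_zscore <- function(kb, de_genes, p) {
  edges <- dplyr::inner_join(
    kb, dplyr::select(de_genes, "gene_id", de_sign = "sign"), by = "gene_id")
  zs <- edges |>
    dplyr::summarise(
      z = ipa_zscore(.data$weight, .data$sign, .data$de_sign)$z,
      .by = "cdt_id")
  # H1 looks for activated regulators (z >= 2), H2 for inhibited (z <= -2);
  # the ranking itself is |z|-based either way
  tibble::tibble(
    cdt_id = zs$cdt_id,
    statistic = zs$z,
    p_or_z = zs$z,
    significant = !is.na(zs$z) & abs(zs$z) >= 2,
    rank = rank_results(-abs(zs$z))
  )
}

finish_p_report <- function(cdt_id, p_raw, alpha) {
  fdr <- rep(NA_real_, length(p_raw))
  ok <- !is.na(p_raw)
  fdr[ok] <- fdr_adjust(p_raw[ok])
  tibble::tibble(
    cdt_id = as.character(cdt_id),
    statistic = fdr,
    p_or_z = p_raw,
    significant = !is.na(fdr) & fdr <= alpha,
    rank = rank_results(fdr)
  )
}

#' Write a method report
#'
#' TSV serialization (`cdt_id`, `statistic`, `p_or_z`, `significant` as
#' 0/1, `rank`) plus a JSON manifest recording the method, its parameters
#' and the seed, sufficient to re-create the report.
#'
#' @param report Method-report tibble from [run_method()].
#' @param path Output TSV path; the manifest is written beside it as
#'   `<path>.manifest.json`.
#' @param params Parameter list to record (as passed to [run_method()]).
#' @return `path`, invisibly.
#' @export
write_method_report <- function(report, path, params = list()) {
  out <- report |>
    dplyr::mutate(significant = as.integer(.data$significant),
                  dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(out, path, progress = FALSE)
  jsonlite::write_json(
    list(method = report$method[1], parameters = params,
         n_cdts = nrow(report)),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}
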