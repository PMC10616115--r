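#' Rank of the true CDT in a method report
#'
#' Returns the true CDT's average rank in the report's ordering. When the
#' method did not score the true CDT at all (absent from the report or `NA`
#' rank), the rank is imputed as the number of significant CDTs the report
#' contains plus one — e.g. a report of 30 significant CDTs without the
#' true one yields rank 31 — and `found` is `FALSE`.
#'
#' @param report Method-report tibble ([run_method()]), or any tibble with
#'   `cdt_id`, `significant`, `rank` columns.
#' @param true_cdt The identifier of the CDT actually administered (H1) or
#'   lacking (H2) in the experiment.
#' @return A one-row tibble: `rank_of_true`, `found`, `n_significant`.
#' @export
rank_of_true <- function(report, true_cdt) {
  n_sig <- sum(report$significant, na.rm = TRUE)
  hit <- which(report$cdt_id == true_cdt)
  rk <- if (length(hit) == 1) report$rank[hit] else NA_real_
  found <- length(hit) == 1 && !is.na(rk)
  tibble::tibble(
    rank_of_true = if (found) rk else n_sig + 1,
    found = found,
    n_significant = n_sig
  )
}

#' Count false positives in a method report
#'
#' The number of CDTs reported significant that are not the true CDT:
#' the significant count, minus one when the true CDT itself is among the
#' significant calls.
#'
#' @inheritParams rank_of_true
#' @return Integer count.
#' @export
count_false_positives <- function(report, true_cdt) {
  hit <- report$cdt_id == true_cdt
  sum(report$significant & !hit, na.rm = TRUE)
}

#' Evaluate one method report against the known true CDT
#'
#' @inheritParams rank_of_true
#' @return A one-row tibble: `method`, `rank_of_true`, `found`,
#'   `n_significant`, `false_positives`.
#' @export
evaluate_report <- function(report, true_cdt) {
  rt <- rank_of_true(report, true_cdt)
  tibble::tibble(
    method = if ("method" %in% names(report) && nrow(report) > 0)
      report$method[1] else NA_character_,
    rt,
    false_positives = count_false_positives(report, true_cdt)
  )
}

#' Aggregate evaluation rows per method
#'
#' Mean and sample standard deviation of the true-CDT ranks and of the
#' significant-CDT counts, per method, the summary layout used to compare
#' methods across a panel of experiments. With a single experiment the
#' standard deviations are reported as 0 and flagged.
#'
#' @param rows Evaluation rows ([evaluate_report()] stacked over
#'   experiments), needing columns `method`, `rank_of_true`,
#'   `n_significant`.
#' @return A tibble per method: `n_experiments`, `mean_rank`, `sd_rank`,
#'   `mean_significant`, `sd_significant`, `sd_defined` (FALSE when a
#'   single experiment made the sd degenerate).
#' @export
aggregate_evaluations <- function(rows) {
  if (nrow(rows) == 0) stop("No evaluation rows to aggregate", call. = FALSE)
  rows |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      mean_rank = mean(.data$rank_of_true),
      sd_rank = if (dplyr::n() > 1) stats::sd(.data$rank_of_true) else 0,
      mean_significant = mean(.data$n_significant),
      sd_significant = if (dplyr::n() > 1) stats::sd(.data$n_significant)
        else 0,
      sd_defined = dplyr::n() > 1,
      .by = "method"
    )
}

#' Compare two methods' per-experiment values with a Wilcoxon test
#'
#' Two-sided comparison of paired per-experiment values (true-CDT ranks or
#' significant-CDT counts), with both the unpaired rank-sum and the paired
#' signed-rank variant available; missing ranks must already be imputed
#' (see [rank_of_true()]).
#'
#' Exact p-values are computed by complete enumeration (all
#' \eqn{\binom{n_a+n_b}{n_a}} group assignments for the rank-sum, all
#' \eqn{2^n} sign flips of the non-zero differences for the signed-rank),
#' which remains valid under ties; the approximate path delegates to
#' `stats::wilcox.test` (normal approximation with tie correction). By
#' default enumeration is used when feasible (total n <= 14 unpaired,
#' n <= 20 paired). Identical paired vectors (all differences zero) give
#' p = 1 by convention.
#'
#' @param values_a,values_b Equal-length numeric vectors over the same
#'   experiments.
#' @param variant `"ranksum"` (unpaired, default) or `"signed_rank"`
#'   (paired).
#' @param exact `TRUE`, `FALSE`, or `NULL` (auto by size, as above).
#' @return A one-row tibble: `variant`, `statistic`, `p_value`, `exact`.
#' @export
compare_methods <- function(values_a, values_b,
                            variant = c("ranksum", "signed_rank"),
                            exact = NULL) {
  variant <- match.arg(variant)
  if (variant == "signed_rank" && length(values_a) != length(values_b)) {
    stop("Paired comparison needs equal-length vectors", call. = FALSE)
  }
  if (variant == "ranksum") {
    na <- length(values_a); nb <- length(values_b)
    if (is.null(exact)) exact <- (na + nb) <= 14
    if (exact) {
      pooled <- c(values_a, values_b)
      r <- rank(pooled)
      w_obs <- sum(r[seq_len(na)])
      mu <- na * (na + nb + 1) / 2
      combos <- utils::combn(na + nb, na)
      w_all <- colSums(matrix(r[combos], nrow = na))
      p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
      return(tibble::tibble(variant = variant, statistic = w_obs,
                            p_value = p, exact = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = FALSE))
    return(tibble::tibble(variant = variant,
                          statistic = unname(wt$statistic) +
                            na * (na + 1) / 2,
                          p_value = unname(wt$p.value), exact = FALSE))
  }
  d <- values_a - values_b
  d <- d[d != 0]
  if (length(d) == 0) {
    return(tibble::tibble(variant = variant, statistic = 0, p_value = 1,
                          exact = TRUE))
  }
  if (is.null(exact)) exact <- length(d) <= 20
  if (exact) {
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    mu <- sum(r) / 2
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
    return(tibble::tibble(variant = variant, statistic = v_obs, p_value = p,
                          exact = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            paired = TRUE, exact = FALSE))
  tibble::tibble(variant = variant, statistic = unname(wt$statistic),
                 p_value = unname(wt$p.value), exact = FALSE)
}

#' Published benchmark summaries for the PURE method
#'
#' The per-experiment evaluation of PURE over the 16 public GEO expression
#' experiments of its original benchmark (14 where the administered CDT is
#' known and elevated, hypothesis H1; 2 COVID-19 infection contrasts where
#' methylprednisolone is the known reversal drug, hypothesis H2):
#' experiment roster, true CDT, the rank PURE assigned the true CDT, and
#' the number of CDTs PURE reported significant. Shipped as a plain TSV in
#' `inst/extdata/` so the aggregation utilities can be exercised on real
#' evaluation numbers without re-running the 16 analyses.
#'
#' @return A tibble with columns `experiment_id`, `geo_id`, `organism`,
#'   `true_cdt`, `hypothesis`, `rank_true_pure`, `n_significant_pure`.
#' @export
#' @examples
#' bench <- published_benchmarks()
#' bench |>
#'   dplyr::filter(hypothesis == "H1") |>
#'   dplyr::summarise(mean_rank = mean(rank_true_pure))
published_benchmarks <- function() {
  path <- system.file("extdata", "pure_published_benchmarks.tsv",
                      package = "pureR", mustWork = TRUE)
  readr::read_tsv(path, col_types = "iccccdi", progress = FALSE)
}

#' Read a benchmark manifest
#'
#' A manifest is a YAML file with a top-level `experiments:` list; each
#' entry needs `id`, `kb`, `de`, `true_cdt`, `hypothesis`, and optionally
#' `organism`. Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest YAML path.
#' @return An experiments tibble for [benchmark_experiments()].
#' @export
read_benchmark_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$experiments) || length(man$experiments) == 0) {
    stop("Manifest '", path, "' lists no experiments", call. = FALSE)
  }
  base <- dirname(path)
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  purrr::map_dfr(man$experiments, function(ex) {
    for (f in c("id", "kb", "de", "true_cdt", "hypothesis")) {
      if (is.null(ex[[f]])) {
        stop("Manifest experiment is missing field '", f, "'", call. = FALSE)
      }
    }
    tibble::tibble(
      experiment_id = as.character(ex$id),
      kb_path = resolve(ex$kb),
      de_path = resolve(ex$de),
      organism = ex$organism %||% NA_character_,
      true_cdt = as.character(ex$true_cdt),
      hypothesis = match.arg(ex$hypothesis, c("H1", "H2"))
    )
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run a panel of benchmark experiments
#'
#' Applies a set of methods to each experiment (a knowledge base, a DE
#' profile, the known true CDT and its hypothesis) and evaluates every
#' report. Failures of a single experiment (e.g. an unreadable DE file) are
#' recorded and the run continues.
#'
#' @param experiments A tibble with one row per experiment and columns
#'   `experiment_id`, `true_cdt`, `hypothesis` (`"H1"`/`"H2"`), and either
#'   `kb`/`de` list-columns of tibbles or `kb_path`/`de_path` columns of
#'   file paths (normalized KB TSV and DE table).
#' @param methods Character vector of method names ([run_method()]).
#' @param params Shared method parameter list; `hypothesis` is set per
#'   experiment.
#' @return A tibble of evaluation rows (`experiment_id`, `method`,
#'   `rank_of_true`, `found`, `n_significant`, `false_positives`, `error`).
#' @export
#' Read a benchmark manifest
#'
#' A manifest is a YAML file with a top-level `experiments:` list; each
#' entry needs `id`, `kb`, `de`, `true_cdt`, `hypothesis`, and optionally
#' `organism`. Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest YAML path.
#' @return An experiments tibble for [benchmark_experiments()].
#' @export
benchmark_experiments <- function(experiments,
                                  methods = c("pure", "ora", "ks",
                                              "wilcoxon", "ipa_like"),
                                  params = list()) {
  purrr::map_dfr(seq_len(nrow(experiments)), function(i) {
    ex <- experiments[i, ]
    rows <- tryCatch({
      kb <- if ("kb" %in% names(ex)) ex$kb[[1]] else read_kb(ex$kb_path)
      de <- if ("de" %in% names(ex)) ex$de[[1]] else read_de(ex$de_path)
      purrr::map_dfr(methods, function(mth) {
        rep <- run_method(mth, kb, de,
                          utils::modifyList(params,
                                            list(hypothesis = ex$hypothesis)))
        evaluate_report(rep, ex$true_cdt)
      }) |>
        dplyr::mutate(error = NA_character_)
    }, error = function(e) {
      tibble::tibble(method = methods, rank_of_true = NA_real_, found = NA,
                     n_significant = NA_integer_,
                     false_positives = NA_integer_,
                     error = conditionMessage(e))
    })
    tibble::tibble(experiment_id = ex$experiment_id, rows)
  })
}
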