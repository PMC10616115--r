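#' Restrict a knowledge base to the differentially expressed genes
#'
#' Builds the overlap network: the set `G` of genes present both in the DE
#' list and in the knowledge base, the knowledge-base edges `E` targeting
#' those genes, and the CDTs `C` owning at least one such edge. An empty
#' overlap is returned as an empty (zero-row) tibble, not an error.
#'
#' @param kb Knowledge-base edge tibble ([read_ctd()], [generate_kb()], ...).
#' @param de_genes Signed DE genes from [select_de_genes()].
#' @return A tibble of overlap edges: the kb columns plus `de_sign` (the DE
#'   sign of the targeted gene). Pass to [label_edges()] before testing.
#' @export
build_overlap <- function(kb, de_genes) {
  net <- dplyr::inner_join(
    kb,
    dplyr::select(de_genes, "gene_id", de_sign = "sign"),
    by = "gene_id"
  )
  if (nrow(net) == 0) {
    message("build_overlap: no knowledge-base edge targets a DE gene; ",
            "the overlap network is empty")
  }
  net
}

#' Label overlap edges by the hypothesis they support
#'
#' An edge supports hypothesis 1 (the CDT is elevated in the phenotype) when
#' its regulation sign agrees with the DE sign of its target gene
#' (activation edge onto an up-regulated gene, or inhibition edge onto a
#' down-regulated gene); otherwise it supports hypothesis 2 (the CDT is
#' lacking). The two sets partition the overlap edges.
#'
#' @param net Overlap edge tibble from [build_overlap()].
#' @return The same tibble with a logical column `h1_support`.
#' @export
label_edges <- function(net) {
  dplyr::mutate(net, h1_support = .data$sign == .data$de_sign)
}

#' Contingency table for one CDT
#'
#' Counts, over a labelled overlap network, `l` = the focal CDT's
#' H1-supporting edges, `k` = its H2-supporting edges, `m` and `n` = the
#' same counts over all other CDTs' edges. `l + k + m + n` is the total
#' number of overlap edges.
#'
#' @param net Labelled overlap edges ([label_edges()]).
#' @param cdt_id Focal CDT identifier (must own at least one overlap edge).
#' @return A one-row tibble with columns `l`, `k`, `m`, `n`.
#' @export
contingency_for <- function(net, cdt_id) {
  if (!"h1_support" %in% names(net)) {
    stop("Overlap edges are unlabelled; call label_edges() first",
         call. = FALSE)
  }
  if (!cdt_id %in% net$cdt_id) {
    stop("CDT '", cdt_id, "' has no edge in the overlap network",
         call. = FALSE)
  }
  focal <- net$cdt_id == cdt_id
  tibble::tibble(
    l = sum(focal & net$h1_support),
    k = sum(focal & !net$h1_support),
    m = sum(!focal & net$h1_support),
    n = sum(!focal & !net$h1_support)
  )
}

#' One-sided Fisher exact p-value on an edge contingency table
#'
#' The probability of each 2x2 table with the observed margins is the
#' hypergeometric mass
#' \deqn{p = \frac{\binom{l+k}{l}\binom{m+n}{m}}{\binom{\|E\|}{l+m}},}
#' and the one-sided p-value sums this mass over all tables whose
#' first cell is at least the observed `l` (upper tail, inclusive of the
#' observed table), holding margins fixed. The inclusive tail is the
#' default because an exclusive tail (`"strict"`, P\[X > l\]) assigns 0 to
#' maximal tables and is offered only for sensitivity checks.
#'
#' All four arguments are vectorised in parallel.
#'
#' @param l,k,m,n Non-negative integer cell counts (see [contingency_for()]).
#' @param tail `"inclusive"` (default) or `"strict"`.
#' @return P-value(s) in \[0, 1\].
#' @export
#' @examples
#' fisher_one_sided(2, 0, 0, 3)   # 0.1
#' fisher_one_sided(3, 1, 1, 5)   # 25/210
fisher_one_sided <- function(l, k, m, n, tail = c("inclusive", "strict")) {
  tail <- match.arg(tail)
  counts <- vctrs_recycle(l = l, k = k, m = m, n = n)
  if (any(unlist(counts) < 0)) {
    stop("Contingency counts must be non-negative", call. = FALSE)
  }
  if (any(counts$l + counts$k + counts$m + counts$n < 1)) {
    stop("Contingency table must contain at least one edge", call. = FALSE)
  }
  mapply(fisher_tail_scalar, counts$l, counts$k, counts$m, counts$n,
         MoreArgs = list(strict = identical(tail, "strict")))
}

fisher_tail_scalar <- function(l, k, m, n, strict = FALSE) {
  r1 <- l + k          # edges of the focal CDT
  c1 <- l + m          # H1-supporting edges
  N <- l + k + m + n
  from <- if (strict) l + 1 else l
  hi <- min(r1, c1)
  if (from > hi) return(0)
  j <- from:hi
  p <- sum(exp(lchoose(r1, j) + lchoose(N - r1, c1 - j) - lchoose(N, c1)))
  min(p, 1)
}

# minimal common-length recycling for scalar-or-vector numeric args
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(x) {
    if (length(x) == n) x else rep_len(x, n)
  })
}

#' H2 p-value by column swap
#'
#' Every edge supporting H1 opposes H2 and vice versa, so the H2 contingency
#' table is the H1 table with its columns swapped; the H2 p-value is the
#' one-sided Fisher test of the swapped table:
#' `p_value_h2(l, k, m, n) == fisher_one_sided(k, l, n, m)`.
#'
#' @inheritParams fisher_one_sided
#' @return P-value(s) in \[0, 1\].
#' @export
p_value_h2 <- function(l, k, m, n, tail = c("inclusive", "strict")) {
  fisher_one_sided(k, l, n, m, tail = tail)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin, domain-checked wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p P-values in \[0, 1\] (NAs preserved).
#' @return Adjusted p-values, each at least as large as its input.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Average ranks, smaller statistic first
#'
#' Ranks an ordering statistic with the average-rank tie convention: tied
#' values receive the arithmetic mean of the rank positions they jointly
#' occupy (four tied leaders are each ranked 2.5). NAs keep NA ranks.
#'
#' @param x Ordering statistic; smaller is better.
#' @return Numeric ranks summing to n(n+1)/2 over the non-NA entries.
#' @export
rank_results <- function(x) {
  rank(x, ties.method = "average", na.last = "keep")
}

#' Test every CDT of a labelled overlap network under both hypotheses
#'
#' For each CDT with at least one overlap edge, builds the edge contingency
#' table, computes the one-sided Fisher p-value for H1 (CDT elevated) and,
#' by column swap, for H2 (CDT lacking), FDR-corrects, ranks by adjusted
#' p-value with average ties, and calls significance at `alpha`.
#'
#' FDR correction is applied within each hypothesis family by default (all
#' H1 p-values together, all H2 p-values together — one test family per
#' research hypothesis); `fdr = "pooled"` corrects the concatenated vector
#' instead.
#'
#' @param net Labelled overlap edges from [label_edges()].
#' @param alpha Significance level for the FDR-adjusted p-values
#'   (inclusive `<=`), default 0.05.
#' @param fdr `"by_hypothesis"` (default) or `"pooled"`.
#' @param tail Fisher tail mode, see [fisher_one_sided()].
#' @param min_edges Drop CDTs with fewer overlap edges than this (default 0:
#'   every CDT is tested regardless of edge count).
#' @param tiebreak_raw_p If `TRUE` (default), adjusted-p ties are broken by
#'   the raw p-value before average ranks are assigned; CDTs tied on both
#'   values still share an average rank. Benjamini-Hochberg saturates many
#'   adjusted values at 1 in small overlap networks, and the raw p-value
#'   preserves the ordering information the adjustment flattens. Set
#'   `FALSE` to average ties on adjusted values only.
#' @return A `pure_result` tibble, one row per CDT, ordered by
#'   (call priority, best adjusted p, cdt_id): `cdt_id`, `cdt_name`,
#'   `n_edges`, `l`, `k`, `m`, `n`, `p_h1`, `fdr_h1`, `rank_h1`, `p_h2`,
#'   `fdr_h2`, `rank_h2`, `call` (one of `present`, `absent`, `both`,
#'   `none`).
#' @seealso [pure_test()] for the one-call interface from a knowledge base
#'   and a DE table, [significant_set()], [tidy.pure_result()].
#' @export
test_all <- function(net, alpha = 0.05, fdr = c("by_hypothesis", "pooled"),
                     tail = c("inclusive", "strict"), min_edges = 0,
                     tiebreak_raw_p = TRUE) {
  fdr <- match.arg(fdr)
  tail <- match.arg(tail)
  stopifnot(alpha > 0, alpha < 1)
  empty <- tibble::tibble(
    cdt_id = character(), cdt_name = character(), n_edges = integer(),
    l = integer(), k = integer(), m = integer(), n = integer(),
    p_h1 = double(), fdr_h1 = double(), rank_h1 = double(),
    p_h2 = double(), fdr_h2 = double(), rank_h2 = double(),
    call = character()
  )
  if (nrow(net) == 0) {
    return(new_pure_result(empty, alpha = alpha, fdr = fdr, tail = tail))
  }
  if (!"h1_support" %in% names(net)) {
    stop("Overlap edges are unlabelled; call label_edges() first",
         call. = FALSE)
  }
  if (!"cdt_name" %in% names(net)) net$cdt_name <- net$cdt_id

  h1_total <- sum(net$h1_support)
  e_total <- nrow(net)
  res <- net |>
    dplyr::summarise(
      cdt_name = .data$cdt_name[1],
      l = sum(.data$h1_support),
      k = sum(!.data$h1_support),
      .by = "cdt_id"
    ) |>
    dplyr::mutate(
      m = h1_total - .data$l,
      n = (e_total - h1_total) - .data$k,
      n_edges = .data$l + .data$k
    ) |>
    dplyr::filter(.data$n_edges >= min_edges)

  res$p_h1 <- fisher_one_sided(res$l, res$k, res$m, res$n, tail = tail)
  res$p_h2 <- p_value_h2(res$l, res$k, res$m, res$n, tail = tail)
  if (fdr == "by_hypothesis") {
    res$fdr_h1 <- fdr_adjust(res$p_h1)
    res$fdr_h2 <- fdr_adjust(res$p_h2)
  } else {
    adj <- fdr_adjust(c(res$p_h1, res$p_h2))
    res$fdr_h1 <- adj[seq_len(nrow(res))]
    res$fdr_h2 <- adj[nrow(res) + seq_len(nrow(res))]
  }
  if (tiebreak_raw_p) {
    res$rank_h1 <- rank_lex(res$fdr_h1, res$p_h1)
    res$rank_h2 <- rank_lex(res$fdr_h2, res$p_h2)
  } else {
    res$rank_h1 <- rank_results(res$fdr_h1)
    res$rank_h2 <- rank_results(res$fdr_h2)
  }
  res$call <- dplyr::case_when(
    res$fdr_h1 <= alpha & res$fdr_h2 <= alpha ~ "both",
    res$fdr_h1 <= alpha ~ "present",
    res$fdr_h2 <= alpha ~ "absent",
    .default = "none"
  )
  res <- res |>
    dplyr::mutate(
      .priority = match(.data$call, c("present", "absent", "both", "none")),
      .best = pmin(.data$fdr_h1, .data$fdr_h2)
    ) |>
    dplyr::arrange(.data$.priority, .data$.best, .data$cdt_id) |>
    dplyr::select(dplyr::all_of(names(empty)))
  new_pure_result(res, alpha = alpha, fdr = fdr, tail = tail)
}

# average ranks over the lexicographic order of (a, b); pairs tie only when
# both components are equal
rank_lex <- function(a, b) {
  df <- data.frame(a = a, b = b)
  o <- do.call(order, df)
  dense <- integer(length(a))
  dense[o] <- cumsum(!duplicated(df[o, , drop = FALSE]))
  rank_results(dense)
}

new_pure_result <- function(x, alpha, fdr, tail) {
  structure(x, class = c("pure_result", class(x)),
            alpha = alpha, fdr_mode = fdr, tail = tail)
}

#' Run PURE end to end
#'
#' Convenience wrapper chaining [select_de_genes()] (if the DE table is not
#' already filtered/signed), [build_overlap()], [label_edges()] and
#' [test_all()].
#'
#' @param kb Knowledge-base edge tibble.
#' @param de DE tibble (`gene_id`, `log_fc`, `p_value`), or an already
#'   signed DE-gene tibble carrying a `sign` column.
#' @param logfc_cut,p_cut DE selection thresholds, see [select_de_genes()].
#' @inheritParams test_all
#' @return A `pure_result` tibble, see [test_all()].
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' kb <- generate_kb(cfg)
#' de <- generate_profile(kb, true_cdt = "CDT01", cfg)
#' res <- pure_test(kb, de)
#' head(res, 3)
pure_test <- function(kb, de, logfc_cut = 0.6, p_cut = 0.05, alpha = 0.05,
                      fdr = c("by_hypothesis", "pooled"),
                      tail = c("inclusive", "strict"), min_edges = 0,
                      tiebreak_raw_p = TRUE) {
  de_genes <- if ("sign" %in% names(de)) de else
    select_de_genes(de, logfc_cut = logfc_cut, p_cut = p_cut)
  net <- label_edges(build_overlap(kb, de_genes))
  test_all(net, alpha = alpha, fdr = match.arg(fdr), tail = match.arg(tail),
           min_edges = min_edges, tiebreak_raw_p = tiebreak_raw_p)
}

#' Significant CDTs from a PURE result
#'
#' A CDT is called `present` when its H1 FDR is at or below `alpha`,
#' `absent` when its H2 FDR is, and `both` when both hold (reported rather
#' than suppressed; a `both` call is statistically valid but biologically
#' hard to interpret).
#'
#' @param results A `pure_result` tibble ([test_all()], [pure_test()]).
#' @param alpha Significance level (inclusive `<=`), default 0.05.
#' @return The rows of `results` with any call, with `call` recomputed at
#'   `alpha`.
#' @export
significant_set <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  results |>
    tibble::as_tibble() |>
    dplyr::mutate(call = dplyr::case_when(
      .data$fdr_h1 <= alpha & .data$fdr_h2 <= alpha ~ "both",
      .data$fdr_h1 <= alpha ~ "present",
      .data$fdr_h2 <= alpha ~ "absent",
      .default = "none"
    )) |>
    dplyr::filter(.data$call != "none")
}

#' Write a PURE result table
#'
#' TSV with one header line and floats at 6 significant digits, so repeated
#' runs diff cleanly.
#'
#' @param results A `pure_result` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pure_result <- function(results, path) {
  out <- tibble::as_tibble(results) |>
    dplyr::mutate(dplyr::across(
      dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
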