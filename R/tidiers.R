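#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PURE result
#'
#' Returns the per-CDT test table as a plain tibble (one row per CDT and
#' hypothesis when `long = TRUE`).
#'
#' @param x A `pure_result` ([pure_test()], [test_all()]).
#' @param long If `TRUE`, pivot to one row per (CDT, hypothesis) with
#'   columns `hypothesis`, `p_value`, `fdr`, `rank`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pure_result
#' @export
tidy.pure_result <- function(x, long = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (!long) return(out)
  out |>
    tidyr::pivot_longer(
      cols = c("p_h1", "fdr_h1", "rank_h1", "p_h2", "fdr_h2", "rank_h2"),
      names_to = c(".value", "hypothesis"),
      names_pattern = "(p|fdr|rank)_(h[12])"
    ) |>
    dplyr::mutate(hypothesis = toupper(.data$hypothesis)) |>
    dplyr::rename(p_value = "p", fdr_value = "fdr")
}

#' One-row summary of a PURE result
#'
#' @param x A `pure_result`.
#' @param ... Unused.
#' @return A one-row tibble: CDT/edge counts, H1/H2 edge split, the number
#'   of CDTs per call, and the testing parameters (`alpha`, FDR mode, tail
#'   mode).
#' @method glance pure_result
#' @export
glance.pure_result <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tibble::tibble(
    n_cdts = nrow(tb),
    n_edges = sum(tb$l + tb$k),
    n_h1_edges = sum(tb$l),
    n_h2_edges = sum(tb$k),
    n_present = sum(tb$call == "present"),
    n_absent = sum(tb$call == "absent"),
    n_both = sum(tb$call == "both"),
    n_significant = sum(tb$call != "none"),
    alpha = attr(x, "alpha"),
    fdr_mode = attr(x, "fdr_mode"),
    tail = attr(x, "tail")
  )
}

#' @export
print.pure_result <- function(x, ...) {
  g <- glance(x)
  cat("PURE upstream-regulator test: ", g$n_cdts, " CDTs over ",
      g$n_edges, " overlap edges (", g$n_h1_edges, " H1 / ", g$n_h2_edges,
      " H2)\n", sep = "")
  cat("Significant at FDR <= ", format(g$alpha), ": ", g$n_significant,
      " (present ", g$n_present, ", absent ", g$n_absent, ", both ",
      g$n_both, ")\n\n", sep = "")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Plot a PURE result
#'
#' Scatter of the evidence for the two directional hypotheses: each CDT at
#' (`-log10` H1 FDR, `-log10` H2 FDR), coloured by its call, with the
#' significance threshold drawn on both axes. CDTs in the upper-left are
#' called present, lower-right absent.
#'
#' @param object A `pure_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pure_result
#' @export
autoplot.pure_result <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(tb, ggplot2::aes(x = -log10(.data$fdr_h1),
                                   y = -log10(.data$fdr_h2),
                                   colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = expression(-log[10] ~ "FDR (H1: CDT elevated)"),
      y = expression(-log[10] ~ "FDR (H2: CDT lacking)"),
      colour = "call",
      title = "PURE directional evidence per CDT"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recovery experiment
#'
#' Mean rank of the planted CDT per method (lower is better), with one
#' point per replicate jittered behind the summary.
#'
#' @param recovery Output of [recovery_experiment()] (optionally several,
#'   row-bound, e.g. over a noise grid with an extra grouping column named
#'   in `facet`).
#' @param facet Optional column name to facet by (e.g. `"agreement_noise"`).
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery, facet = NULL) {
  p <- ggplot2::ggplot(recovery,
                       ggplot2::aes(x = .data$method,
                                    y = .data$rank_of_true)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3) +
    ggplot2::labs(x = NULL, y = "rank of planted CDT (mean in red)") +
    ggplot2::theme_minimal()
  if (!is.null(facet)) {
    p <- p + ggplot2::facet_wrap(facet)
  }
  p
}
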