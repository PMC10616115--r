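#' Read a differential-expression table
#'
#' Reads a delimited table (delimiter auto-detected among tab, comma and
#' semicolon) with one row per gene and at least a gene identifier, a log
#' fold-change and a p-value. Column names are matched case-insensitively;
#' alternative names can be supplied through `col_map`.
#'
#' @param path Path to the DE table.
#' @param col_map Named character vector mapping the canonical names
#'   `gene_id`, `log_fc`, `p_value` to the columns used in the file, e.g.
#'   `c(gene_id = "SYMBOL", log_fc = "logFC", p_value = "P.Value")`. Besides
#'   explicit mappings, the common spellings `gene`, `gene_symbol`, `logfc`,
#'   `log2fc`, `pvalue`, `p.value`, `pval` are recognised.
#' @return A tibble with columns `gene_id` (character), `log_fc` (double),
#'   `p_value` (double).
#' @export
read_de <- function(path, col_map = NULL) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) {
    stop("DE table '", path, "' is empty", call. = FALSE)
  }
  delim <- c("\t", ",", ";")[which.max(c(
    lengths(regmatches(first, gregexpr("\t", first))),
    lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
    lengths(regmatches(first, gregexpr(";", first, fixed = TRUE)))
  ))]
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  aliases <- list(
    gene_id = c("gene_id", "gene", "gene_symbol", "geneid", "symbol", "id"),
    log_fc  = c("log_fc", "logfc", "log2fc", "log2foldchange", "lfc", "fc"),
    p_value = c("p_value", "pvalue", "p.value", "pval", "p")
  )
  pick <- function(canon) {
    if (!is.null(col_map) && canon %in% names(col_map)) {
      hit <- match(tolower(col_map[[canon]]), tolower(names(tab)))
    } else {
      hit <- match(aliases[[canon]], tolower(names(tab)))
      hit <- hit[!is.na(hit)][1]
    }
    if (is.na(hit) || length(hit) == 0) {
      stop("DE table is missing required column '", canon, "' (in ", path, ")",
           call. = FALSE)
    }
    hit
  }
  out <- tibble::tibble(
    gene_id = as.character(tab[[pick("gene_id")]]),
    log_fc  = as.numeric(tab[[pick("log_fc")]]),
    p_value = as.numeric(tab[[pick("p_value")]])
  )
  bad <- !is.na(out$p_value) & (out$p_value < 0 | out$p_value > 1)
  if (any(bad)) {
    stop("p_value outside [0, 1] in ", sum(bad), " row(s)", call. = FALSE)
  }
  out
}

#' Collapse duplicated gene entries in a DE table
#'
#' Multi-probe genes (or redundant rows) are collapsed to one record per
#' gene. The default rule keeps the record with the smallest p-value,
#' breaking ties on the largest `|log_fc|` and then on row order, so the
#' result is deterministic.
#'
#' @param de DE tibble as returned by [read_de()].
#' @param rule `"min_p"` (default, two-level rule above) or `"error"` to
#'   fail when duplicated gene ids carry conflicting fold-change signs.
#' @return A DE tibble with unique `gene_id`s.
#' @export
aggregate_duplicates <- function(de, rule = c("min_p", "error")) {
  rule <- match.arg(rule)
  if (!anyDuplicated(de$gene_id)) return(de)
  if (rule == "error") {
    conflicts <- de |>
      dplyr::summarise(conflict = dplyr::n_distinct(sign(.data$log_fc)) > 1,
                       .by = "gene_id")
    if (any(conflicts$conflict)) {
      stop("Duplicated gene_id(s) with conflicting fold-change signs: ",
           paste(utils::head(conflicts$gene_id[conflicts$conflict], 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  de |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$log_fc)), .data$.row) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

#' Select differentially expressed genes
#'
#' Applies the DE selection rule `|log_fc| > logfc_cut` and
#' `p_value < p_cut` (both strict, so boundary values are excluded) and
#' attaches the regulation sign: +1 for up-regulated, -1 for down-regulated
#' genes. Defaults are `|log(FC)| > 0.6` and `p < 0.05`.
#'
#' The log base of `log_fc` is the caller's: the cutoff is applied to the
#' values as given. Whether p-values are raw or adjusted is likewise the
#' caller's choice; the filter is agnostic.
#'
#' @param de DE tibble (`gene_id`, `log_fc`, `p_value`), unique gene ids
#'   (see [aggregate_duplicates()]).
#' @param logfc_cut Positive fold-change cutoff (strict `>`), default 0.6.
#' @param p_cut P-value cutoff (strict `<`), default 0.05.
#' @return A tibble of DE genes: `gene_id`, `log_fc`, `p_value`, `sign`.
#' @export
#' @examples
#' de <- tibble::tibble(gene_id = c("A", "B", "C"),
#'                      log_fc = c(0.7, -0.6, -1.4),
#'                      p_value = c(0.01, 0.001, 0.2))
#' select_de_genes(de)  # A passes; B fails |logFC|>0.6; C fails p<0.05
select_de_genes <- function(de, logfc_cut = 0.6, p_cut = 0.05) {
  stopifnot(logfc_cut > 0, p_cut > 0, p_cut <= 1)
  if (anyDuplicated(de$gene_id)) {
    stop("DE table has duplicated gene_id(s); run aggregate_duplicates() first",
         call. = FALSE)
  }
  de |>
    dplyr::filter(abs(.data$log_fc) > logfc_cut, .data$p_value < p_cut) |>
    dplyr::mutate(sign = as.integer(sign(.data$log_fc)))
}
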