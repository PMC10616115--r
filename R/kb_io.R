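#' Read a CTD-style chemical-gene interaction table into a signed knowledge base
#'
#' Parses a tab-separated chemical-gene interaction file in the layout of the
#' Comparative Toxicogenomics Database (CTD) `chem_gene_ixns` export and keeps
#' only the interactions that describe a direct change in gene *expression*:
#' `increases^expression` becomes an activation edge (sign +1) and
#' `decreases^expression` an inhibition edge (sign -1). All other interaction
#' types (abundance, methylation, activity, response to substance, ...) are
#' dropped, as are direction-less `affects^expression` rows (a note is emitted
#' with their count). Duplicate (chemical, gene, sign) triples collapse to a
#' single edge.
#'
#' CTD exports prefix the table with `#` comment lines and usually leave the
#' column header itself commented out; both that layout and a plain header
#' line are accepted.
#'
#' @param path Path to the interaction table (plain or gzip TSV).
#' @param organism Optional organism name, matched case-insensitively and
#'   exactly against the `Organism` column (e.g. `"Homo sapiens"`). Rows with
#'   an empty organism field are excluded when a filter is set.
#' @return A tibble of signed edges (the knowledge base) with columns
#'   `cdt_id`, `cdt_name`, `gene_id`, `gene_symbol`, `sign` (+1 activation,
#'   -1 inhibition), `weight` (1 for CTD edges), `organism`, `provenance`
#'   (source row reference).
#' @seealso [kb_summary()], [write_kb()], [read_kb()]
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste("ChemicalName", "ChemicalID", "CasRN", "GeneSymbol", "GeneID",
#'     "GeneForms", "Organism", "OrganismID", "Interaction",
#'     "InteractionActions", "PubMedIDs", sep = "\t"),
#'   paste("Dexamethasone", "D003907", "50-02-2", "FKBP5", "2289", "mRNA",
#'     "Homo sapiens", "9606", "Dexamethasone results in increased expression",
#'     "increases^expression", "12345", sep = "\t")
#' ), tsv)
#' read_ctd(tsv, organism = "Homo sapiens")
read_ctd <- function(path, organism = NULL) {
  raw <- read_ctd_table(path)
  required <- c("ChemicalName", "ChemicalID", "GeneSymbol", "GeneID",
                "Organism", "InteractionActions")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("CTD interaction table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$`..row` <- seq_len(nrow(raw))

  if (!is.null(organism)) {
    keep <- !is.na(raw$Organism) & nzchar(raw$Organism) &
      tolower(raw$Organism) == tolower(organism)
    raw <- raw[keep, , drop = FALSE]
  }

  if (nrow(raw) == 0) {
    stop("No expression-changing edges retained from '", path, "'",
         if (!is.null(organism)) paste0(" for organism '", organism, "'"),
         "; check the organism spelling and the InteractionActions column.",
         call. = FALSE)
  }
  actions <- strsplit(ifelse(is.na(raw$InteractionActions), "",
                             raw$InteractionActions), "|", fixed = TRUE)
  n_undirected <- sum(vapply(
    actions, function(a) any(a == "affects^expression"), logical(1)))
  if (n_undirected > 0) {
    message("read_ctd: ", n_undirected,
            " row(s) with direction-less 'affects^expression' were not used")
  }

  per_row <- purrr::map2(actions, seq_along(actions), function(a, i) {
    signs <- c(if (any(a == "increases^expression")) 1L,
               if (any(a == "decreases^expression")) -1L)
    if (is.null(signs)) return(NULL)
    tibble::tibble(row = i, sign = signs)
  })
  hits <- dplyr::bind_rows(per_row)

  if (nrow(hits) == 0) {
    stop("No expression-changing edges retained from '", path, "'",
         if (!is.null(organism)) paste0(" for organism '", organism, "'"),
         "; check the organism spelling and the InteractionActions column.",
         call. = FALSE)
  }

  edges <- tibble::tibble(
    cdt_id      = as.character(raw$ChemicalID[hits$row]),
    cdt_name    = as.character(raw$ChemicalName[hits$row]),
    gene_id     = as.character(raw$GeneID[hits$row]),
    gene_symbol = as.character(raw$GeneSymbol[hits$row]),
    sign        = hits$sign,
    weight      = 1,
    organism    = as.character(raw$Organism[hits$row]),
    provenance  = paste0("row", raw$`..row`[hits$row])
  )
  edges <- dplyr::distinct(edges, .data$cdt_id, .data$gene_id, .data$sign,
                           .keep_all = TRUE)
  dplyr::arrange(edges, .data$cdt_id, .data$gene_id, .data$sign)
}

# CTD files comment the header out; locate it in either the first data line or
# the last comment line listing the known field names.
read_ctd_table <- function(path) {
  lines <- readr::read_lines(path)
  is_comment <- startsWith(lines, "#")
  body <- lines[!is_comment]
  if (length(body) == 0) {
    stop("No data rows found in '", path, "'", call. = FALSE)
  }
  first_fields <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if ("ChemicalName" %in% first_fields) {
    header <- first_fields
    body <- body[-1]
  } else {
    comment_lines <- lines[is_comment]
    candidates <- grep("ChemicalName", comment_lines, value = TRUE)
    if (length(candidates) == 0) {
      stop("CTD interaction table is missing required column(s): ChemicalName",
           call. = FALSE)
    }
    header <- strsplit(sub("^#\\s*", "", candidates[length(candidates)]),
                       "\t", fixed = TRUE)[[1]]
    header <- trimws(header)
  }
  if (length(body) == 0) {
    return(tibble::as_tibble(stats::setNames(
      replicate(length(header), character(0), simplify = FALSE), header)))
  }
  readr::read_tsv(I(body), col_names = header,
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

#' Summarise a knowledge base
#'
#' @param kb A knowledge-base edge tibble, from [read_ctd()], [read_kb()] or
#'   [generate_kb()].
#' @return A one-row tibble with `n_cdts`, `n_genes`, `n_edges`,
#'   `n_activation`, `n_inhibition`.
#' @export
kb_summary <- function(kb) {
  tibble::tibble(
    n_cdts       = dplyr::n_distinct(kb$cdt_id),
    n_genes      = dplyr::n_distinct(kb$gene_id),
    n_edges      = nrow(kb),
    n_activation = sum(kb$sign == 1),
    n_inhibition = sum(kb$sign == -1)
  )
}

#' Write / read a normalized knowledge-base edge table
#'
#' The normalized format is a plain TSV with columns `cdt_id`, `cdt_name`,
#' `gene_id`, `gene_symbol`, `sign`, `weight`, `organism` — the output
#' contract of the parser, re-readable with [read_kb()].
#'
#' @param kb Knowledge-base edge tibble.
#' @param path Output (input) file path.
#' @return `write_kb()` returns `path` invisibly; `read_kb()` returns the
#'   edge tibble.
#' @export
write_kb <- function(kb, path) {
  out <- kb[, intersect(c("cdt_id", "cdt_name", "gene_id", "gene_symbol",
                          "sign", "weight", "organism"), names(kb))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_kb
#' @export
read_kb <- function(path) {
  kb <- readr::read_tsv(path, col_types = readr::cols(
    cdt_id = readr::col_character(),
    gene_id = readr::col_character(),
    sign = readr::col_integer(),
    weight = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (!all(c("cdt_id", "gene_id", "sign") %in% names(kb))) {
    stop("Edge table is missing required column(s): ",
         paste(setdiff(c("cdt_id", "gene_id", "sign"), names(kb)),
               collapse = ", "), call. = FALSE)
  }
  if (!all(kb$sign %in% c(-1L, 1L))) {
    stop("Edge signs must be +1 or -1", call. = FALSE)
  }
  if (!"cdt_name" %in% names(kb)) kb$cdt_name <- kb$cdt_id
  if (!"weight" %in% names(kb)) kb$weight <- 1
  if (!"organism" %in% names(kb)) kb$organism <- NA_character_
  dplyr::distinct(tibble::as_tibble(kb), .data$cdt_id, .data$gene_id,
                  .data$sign, .keep_all = TRUE)
}
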