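# Shared in-code fixtures: a tiny CTD-style interaction file and hand-built
# knowledge bases / DE tables small enough to verify by eye.

ctd_header <- paste("ChemicalName", "ChemicalID", "CasRN", "GeneSymbol",
                    "GeneID", "GeneForms", "Organism", "OrganismID",
                    "Interaction", "InteractionActions", "PubMedIDs",
                    sep = "\t")

ctd_row <- function(chem = "Dexamethasone", chem_id = "D003907",
                    gene = "FKBP5", gene_id = "2289",
                    organism = "Homo sapiens", org_id = "9606",
                    actions = "increases^expression") {
  paste(chem, chem_id, "50-02-2", gene, gene_id, "mRNA", organism, org_id,
        "interaction text", actions, "12345", sep = "\t")
}

write_ctd_fixture <- function(rows, header = TRUE, preamble = FALSE) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- character(0)
  if (preamble) {
    lines <- c(paste("#", c("CTD chemical-gene interactions (synthetic",
                            "fixture)", rep("filler comment", 27))),
               paste0("# ", ctd_header))
  } else if (header) {
    lines <- ctd_header
  }
  writeLines(c(lines, rows), path)
  path
}

# 5-edge toy KB over 2 CDTs; genes g1..g4
toy_kb <- function() {
  tibble::tibble(
    cdt_id = c("c1", "c1", "c1", "c2", "c2"),
    cdt_name = c("one", "one", "one", "two", "two"),
    gene_id = c("g1", "g2", "g3", "g1", "g4"),
    gene_symbol = c("g1", "g2", "g3", "g1", "g4"),
    sign = c(1L, -1L, 1L, -1L, 1L),
    weight = 1,
    organism = "synthetic",
    provenance = paste0("row", 1:5)
  )
}

# signed DE genes g1 (up) and g2 (down); g4 untouched, g5 not in the KB
toy_de_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g5"),
    log_fc = c(1.2, -0.9, 2.0),
    p_value = c(0.001, 0.01, 0.002),
    sign = c(1L, -1L, 1L)
  )
}

# exhaustive one-sided upper-tail p-value over all 2x2 tables with the
# observed margins: the independent oracle for fisher_one_sided
enum_fisher_upper <- function(l, k, m, n) {
  r1 <- l + k
  c1 <- l + m
  N <- l + k + m + n
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(j) {
    choose(r1, j) * choose(N - r1, c1 - j) / choose(N, c1)
  }, numeric(1))
  sum(probs[(lo:hi) >= l])
}
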