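#' Configuration for the synthetic knowledge-base / DE-profile generator
#'
#' Collects and validates the parameters of the generative model the PURE
#' test assumes: a signed CDT-to-gene knowledge base, one perturbed ("true")
#' CDT whose targets respond in the direction its edges imply, sign noise on
#' that response, and background differential expression unrelated to the
#' perturbation.
#'
#' Defaults describe a compact but structured benchmark universe: 50 CDTs
#' over 200 genes with 5-20 edges each (half activating), a noiseless H1
#' perturbation, a 2% background DE rate, DE fold-change magnitudes
#' log-normal above the 0.6 selection threshold, and p-values drawn strictly
#' inside (0, 0.05) for DE genes (scaled Beta) and strictly inside
#' (0.05, 1) for the rest, so threshold behaviour is deterministic.
#'
#' @param n_cdts Number of CDTs (>= 2).
#' @param n_genes Number of genes in the universe.
#' @param edges_per_cdt Integer range `c(min, max)` of edges per CDT, drawn
#'   uniformly; targets are sampled without replacement.
#' @param activation_fraction Probability an edge is an activation (+1).
#' @param true_cdt_hypothesis `"H1"` (targets respond with the edge sign —
#'   the CDT is present) or `"H2"` (targets respond against it — the CDT is
#'   lacking).
#' @param agreement_noise Probability a perturbed target's DE sign
#'   contradicts the implied direction.
#' @param background_de_rate Probability a non-target gene is DE (random
#'   sign).
#' @param logfc_magnitude `c(meanlog, sdlog)` of the log-normal excess of
#'   `|log_fc|` above the threshold for DE genes.
#' @param de_p_value_beta `c(shape1, shape2)` of the Beta draw scaled into
#'   (0, 0.05) for DE genes' p-values.
#' @param logfc_cut,p_cut Selection thresholds the generated profile is
#'   built around (defaults 0.6 / 0.05).
#' @param seed Integer seed; all generator draws derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cdts = 50, n_genes = 200, edges_per_cdt = c(5, 20),
                       activation_fraction = 0.5,
                       true_cdt_hypothesis = c("H1", "H2"),
                       agreement_noise = 0, background_de_rate = 0.02,
                       logfc_magnitude = c(0, 0.5),
                       de_p_value_beta = c(1, 4),
                       logfc_cut = 0.6, p_cut = 0.05, seed = 1) {
  true_cdt_hypothesis <- match.arg(true_cdt_hypothesis)
  probs <- c(activation_fraction, agreement_noise, background_de_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("activation_fraction, agreement_noise and background_de_rate must ",
         "lie in [0, 1]", call. = FALSE)
  }
  if (n_cdts < 2) stop("n_cdts must be at least 2", call. = FALSE)
  if (length(edges_per_cdt) != 2 || edges_per_cdt[1] < 1 ||
      edges_per_cdt[2] < edges_per_cdt[1]) {
    stop("edges_per_cdt must be c(min, max) with min >= 1", call. = FALSE)
  }
  if (edges_per_cdt[2] > n_genes) {
    stop("edges_per_cdt max (", edges_per_cdt[2],
         ") exceeds n_genes (", n_genes, ")", call. = FALSE)
  }
  structure(list(
    n_cdts = as.integer(n_cdts), n_genes = as.integer(n_genes),
    edges_per_cdt = as.integer(edges_per_cdt),
    activation_fraction = activation_fraction,
    true_cdt_hypothesis = true_cdt_hypothesis,
    agreement_noise = agreement_noise,
    background_de_rate = background_de_rate,
    logfc_magnitude = logfc_magnitude,
    de_p_value_beta = de_p_value_beta,
    logfc_cut = logfc_cut, p_cut = p_cut,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic signed knowledge base
#'
#' Each CDT receives an edge count drawn uniformly from
#' `cfg$edges_per_cdt`, target genes sampled without replacement, and each
#' edge an activation sign with probability `cfg$activation_fraction`
#' (inhibition otherwise). Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A knowledge-base edge tibble (same columns as [read_ctd()]).
#' @export
generate_kb <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_seed(cfg$seed, {
    cdt_ids <- sprintf("CDT%02d", seq_len(cfg$n_cdts))
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    n_edges <- sample(cfg$edges_per_cdt[1]:cfg$edges_per_cdt[2],
                      cfg$n_cdts, replace = TRUE)
    purrr::map_dfr(seq_len(cfg$n_cdts), function(i) {
      targets <- sample(gene_ids, n_edges[i])
      tibble::tibble(
        cdt_id = cdt_ids[i],
        cdt_name = cdt_ids[i],
        gene_id = targets,
        gene_symbol = targets,
        sign = ifelse(stats::runif(n_edges[i]) < cfg$activation_fraction,
                      1L, -1L),
        weight = 1,
        organism = "synthetic",
        provenance = paste0("sim:", cdt_ids[i])
      )
    })
  })
}

#' Generate a synthetic DE profile with one perturbed CDT
#'
#' Target genes of `true_cdt` become DE with the sign its edges imply under
#' `cfg$true_cdt_hypothesis` (H1: DE sign equals the edge sign; H2:
#' opposite), each flipped independently with probability
#' `cfg$agreement_noise`. Every other gene is DE with probability
#' `cfg$background_de_rate`, with a uniformly random sign. DE genes draw
#' `|log_fc| = logfc_cut + LogNormal(meanlog, sdlog)` and
#' `p = p_cut * Beta(shape1, shape2)`; non-DE genes draw
#' `|log_fc| ~ U(0, logfc_cut)` and `p ~ U(p_cut, 1)`, so the profile
#' partitions exactly at the selection thresholds.
#'
#' The profile seed is derived from `cfg$seed` (offset so the knowledge-base
#' and profile draws are independent); pass `seed` to override, e.g. for
#' replicate substreams.
#'
#' @param kb Knowledge base containing `true_cdt` (typically
#'   [generate_kb()]).
#' @param true_cdt CDT identifier to perturb.
#' @param cfg A [sim_config()].
#' @param seed Optional integer overriding the derived profile seed.
#' @return A full DE profile tibble: `gene_id`, `log_fc`, `p_value` for all
#'   `cfg$n_genes` genes.
#' @export
generate_profile <- function(kb, true_cdt, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!true_cdt %in% kb$cdt_id) {
    stop("true_cdt '", true_cdt, "' is not in the knowledge base",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- (cfg$seed + 500009L) %% .Machine$integer.max
  local_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    edges <- kb[kb$cdt_id == true_cdt, ]
    implied <- if (cfg$true_cdt_hypothesis == "H1") edges$sign else
      -edges$sign
    flip <- stats::runif(nrow(edges)) < cfg$agreement_noise
    target_sign <- stats::setNames(ifelse(flip, -implied, implied),
                                   edges$gene_id)

    is_target <- gene_ids %in% edges$gene_id
    bg_de <- !is_target & stats::runif(cfg$n_genes) < cfg$background_de_rate
    de <- is_target | bg_de
    sign_vec <- integer(cfg$n_genes)
    sign_vec[is_target] <- target_sign[gene_ids[is_target]]
    sign_vec[bg_de] <- sample(c(-1L, 1L), sum(bg_de), replace = TRUE)

    n <- cfg$n_genes
    log_fc <- numeric(n)
    p_value <- numeric(n)
    log_fc[de] <- sign_vec[de] *
      (cfg$logfc_cut + stats::rlnorm(sum(de), cfg$logfc_magnitude[1],
                                     cfg$logfc_magnitude[2]))
    p_value[de] <- cfg$p_cut * stats::rbeta(sum(de), cfg$de_p_value_beta[1],
                                            cfg$de_p_value_beta[2])
    log_fc[!de] <- stats::runif(sum(!de), -cfg$logfc_cut, cfg$logfc_cut)
    p_value[!de] <- stats::runif(sum(!de), cfg$p_cut, 1)

    tibble::tibble(gene_id = gene_ids, log_fc = log_fc, p_value = p_value)
  })
}

#' Recovery experiment: can each method find the planted CDT?
#'
#' For each replicate, draws a knowledge base and a DE profile with one
#' perturbed CDT (chosen deterministically from the replicate substream),
#' runs the requested methods under the simulated hypothesis, and records
#' the rank of the true CDT, whether it was scored, the significant count
#' and false positives. Replicate `r` uses seed `cfg$seed + r`, so any
#' replicate is reproducible in isolation.
#'
#' @param cfg A [sim_config()].
#' @param n_replicates Number of replicates (>= 1).
#' @param methods Methods to run (default `"pure"`; see [run_method()]).
#' @param params Extra method parameters; `hypothesis` is forced to
#'   `cfg$true_cdt_hypothesis` unless overridden here.
#' @return A tibble with one row per (replicate, method): `replicate`,
#'   `true_cdt`, `method`, `rank_of_true`, `found`, `n_significant`,
#'   `false_positives`.
#' @seealso [aggregate_evaluations()] to summarise the result.
#' @export
recovery_experiment <- function(cfg, n_replicates, methods = "pure",
                                params = list()) {
  stopifnot(inherits(cfg, "sim_config"), n_replicates >= 1)
  params <- utils::modifyList(
    list(hypothesis = cfg$true_cdt_hypothesis,
         logfc_cut = cfg$logfc_cut, p_cut = cfg$p_cut),
    params)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    rep_seed <- (cfg$seed + r) %% .Machine$integer.max
    rep_cfg <- cfg
    rep_cfg$seed <- rep_seed
    kb <- generate_kb(rep_cfg)
    true_cdt <- local_seed(rep_seed + 1L,
                           sample(unique(kb$cdt_id), 1))
    de <- generate_profile(kb, true_cdt, rep_cfg,
                           seed = (rep_seed + 1000003L) %%
                             .Machine$integer.max)
    purrr::map_dfr(methods, function(mth) {
      rep_params <- utils::modifyList(params, list(seed = rep_seed))
      report <- run_method(mth, kb, de, rep_params)
      tibble::tibble(replicate = r, true_cdt = true_cdt,
                     evaluate_report(report, true_cdt))
    })
  })
}

#' Write simulation fixtures to disk
#'
#' Writes `kb.tsv` (normalized edge table), `de.tsv` and `truth.json` (the
#' perturbed CDT, its hypothesis, and the full configuration) for each
#' replicate, in numbered subdirectories when `replicates > 1`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param replicates Number of replicate fixture sets (default 1).
#' @return The paths of the written directories, invisibly.
#' @export
write_simulation <- function(cfg, out_dir, replicates = 1) {
  stopifnot(inherits(cfg, "sim_config"), replicates >= 1)
  dirs <- character(replicates)
  for (r in seq_len(replicates)) {
    dir_r <- if (replicates == 1) out_dir else
      file.path(out_dir, sprintf("replicate_%03d", r))
    dir.create(dir_r, recursive = TRUE, showWarnings = FALSE)
    rep_cfg <- cfg
    rep_cfg$seed <- (cfg$seed + r - 1L) %% .Machine$integer.max
    kb <- generate_kb(rep_cfg)
    true_cdt <- local_seed(rep_cfg$seed + 1L,
                           sample(unique(kb$cdt_id), 1))
    de <- generate_profile(kb, true_cdt, rep_cfg,
                           seed = (rep_cfg$seed + 1000003L) %%
                             .Machine$integer.max)
    write_kb(kb, file.path(dir_r, "kb.tsv"))
    readr::write_tsv(de, file.path(dir_r, "de.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(true_cdt = true_cdt, hypothesis = cfg$true_cdt_hypothesis,
           replicate = r, config = unclass(rep_cfg)),
      file.path(dir_r, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    dirs[r] <- dir_r
  }
  invisible(dirs)
}
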