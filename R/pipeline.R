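#' Run the full module-and-GO gene prioritization pipeline
#'
#' Orchestrates every stage: module/expression intersection, consensus
#' differential expression, per-module consensus differential correlation,
#' GO fuzzy-measure gene importance, module and gene scoring, local ranking,
#' and rank fusion into one global gene ranking. One master seed derives
#' independent per-stage seed streams so each stage is reproducible on its
#' own; two runs with identical inputs and seed produce identical output
#' files.
#'
#' @param expr an [expression_data()] object.
#' @param modules a [module_set()].
#' @param go a [read_go()] object.
#' @param seeds character vector of known disease gene ids.
#' @param de a [de_params()] object (its `rng_seed` is overridden by the
#'   derived stage seed when `seed` is given).
#' @param corr a [corr_params()] object (same seed handling).
#' @param padj_mode,corc_indicator see [gene_importance()] and [gene_corc()].
#' @param padj_table optional precomputed full-data adjusted p-values passed
#'   to [consensus_de()] (see [read_padj_table()]).
#' @param seed master integer seed; `NULL` keeps the seeds inside `de`/`corr`.
#' @param include_unmoduled append genes outside all modules to the tail of
#'   the ranking, ordered by `1 - padj`.
#' @param out_dir optional directory: writes `ranking.tsv`,
#'   `module_scores.tsv`, `gene_scores.tsv` and `report.json`.
#' @param verbose print stage progress.
#' @return List with `ranking` (global ranking data frame), `module_scores`,
#'   `gene_scores` (per-module list), `de`, `diffcorr`, and `report`
#'   (parameter echo, gene-universe coverage, dropped modules, seed).
#' @export
mgogp_run <- function(expr, modules, go, seeds,
                      de = de_params(), corr = corr_params(),
                      padj_mode = c("complement", "raw"),
                      corc_indicator = c("dee", "sc_full"),
                      padj_table = NULL,
                      seed = NULL, include_unmoduled = TRUE,
                      out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(expr, "ExpressionData"), inherits(modules, "ModuleSet"),
            inherits(go, "GoKnowledge"))
  padj_mode <- match.arg(padj_mode)
  corc_indicator <- match.arg(corc_indicator)
  if (!is.null(seed)) {
    de$rng_seed <- derive_seed(seed, "de")
    corr$rng_seed <- derive_seed(seed, "corr")
  }
  say <- function(...) if (verbose) message(sprintf(...))

  ms <- intersect_modules(modules, expr, verbose = verbose)
  if (ms$M < 1L) stop("io_formats: no module retains >= 2 expressed genes")

  say("consensus differential expression (S=%d)", de$S)
  de_res <- consensus_de(expr, de, padj_table = padj_table)

  say("consensus differential correlation over %d modules (S=%d)", ms$M, corr$S)
  dc <- consensus_diffcorr_all(expr, ms, corr, verbose = verbose)

  say("GO term probabilities and module/gene scoring")
  probs <- term_probability(go)
  mod_scores <- score_modules(ms, de_res, dc, seeds)
  gene_scores <- score_module_genes(ms, de_res, dc, seeds, go, probs,
                                    padj_mode = padj_mode,
                                    corc_indicator = corc_indicator)

  say("rank fusion")
  p_mod <- stats::setNames(mod_scores$p_module, mod_scores$module)
  probs_mod <- suppressWarnings(normalize_module_probs(p_mod))
  unmod <- NULL
  if (include_unmoduled) {
    outside <- setdiff(expr$genes, unique(unlist(ms$modules, use.names = FALSE)))
    if (length(outside)) unmod <- de_res$padj[outside]
  }
  ranking <- fuse_rankings(gene_scores, probs_mod, p_module = p_mod,
                           unmoduled = unmod)

  report <- list(
    parameters = list(S_de = de$S, omega = de$omega, mu = de$mu,
                      S_corr = corr$S, delta = corr$delta,
                      upsilon = corr$upsilon,
                      subsample_fraction_de = de$subsample_fraction,
                      subsample_fraction_corr = corr$subsample_fraction,
                      fdr_method = corr$fdr_method,
                      padj_mode = padj_mode,
                      corc_indicator = corc_indicator),
    seed = if (is.null(seed)) NA else seed,
    stage_seeds = list(de = de$rng_seed, corr = corr$rng_seed),
    n_genes = length(expr$genes),
    n_samples = list(normal = expr$L, tumor = expr$Q),
    n_modules_input = modules$M,
    n_modules_used = ms$M,
    dropped_modules = attr(ms, "dropped"),
    module_gene_coverage = attr(ms, "coverage"),
    n_seed_genes = length(seeds),
    n_ranked = nrow(ranking),
    n_consensus_deg = sum(de_res$deg))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ranking(ranking, file.path(out_dir, "ranking.tsv"))
    utils::write.table(mod_scores, file.path(out_dir, "module_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs <- do.call(rbind, lapply(names(gene_scores), function(nm)
      cbind(module = nm, gene_scores[[nm]])))
    utils::write.table(gs, file.path(out_dir, "gene_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(ranking = ranking, module_scores = mod_scores,
       gene_scores = gene_scores, de = de_res, diffcorr = dc,
       report = report)
}
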