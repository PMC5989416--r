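#' Module differential-expression ratio
#'
#' Fraction of module genes called consensus DEGs.
#'
#' @param module character vector of gene ids.
#' @param de a [consensus_de()] result.
#' @return Value in \[0, 1\].
#' @export
module_ncr <- function(module, de) {
  stopifnot(inherits(de, "DeResult"), length(module) >= 1L)
  deg <- de$deg[module]
  deg[is.na(deg)] <- 0L
  sum(deg) / length(module)
}

#' Module differential-correlation ratio
#'
#' Fraction of the module's `K = N(N-1)/2` gene pairs flagged as consensus
#' differential correlations.
#'
#' @param diffcorr a [consensus_diffcorr()] result.
#' @return Value in \[0, 1\].
#' @export
module_ecr <- function(diffcorr) {
  stopifnot(inherits(diffcorr, "ModuleDiffCorr"))
  k <- length(diffcorr$dee)
  if (k < 1L) stop("module has no gene pairs")
  sum(diffcorr$dee) / k
}

#' Basic importance of a module from its seed-gene content
#'
#' `(number of known disease genes in the module + 1) / N`. Small modules
#' dense in seeds can exceed 1; the literal formula is kept and such modules
#' are flagged.
#'
#' @param module character vector of gene ids.
#' @param seeds character vector of known disease gene ids.
#' @return Positive value; attribute `exceeds_one = TRUE` when above 1.
#' @export
module_basic_importance <- function(module, seeds) {
  n <- length(module)
  stopifnot(n >= 1L)
  v <- (length(intersect(module, seeds)) + 1) / n
  if (v > 1) attr(v, "exceeds_one") <- TRUE
  v
}

#' Module importance
#'
#' `p(m) = ((Ncr + Ecr) / 2) * info`.
#'
#' @param ncr,ecr,info the three module-level components.
#' @return Non-negative value.
#' @export
module_importance <- function(ncr, ecr, info) {
  ((ncr + ecr) / 2) * as.numeric(info)
}

#' A gene's within-module differential-correlation ratio
#'
#' Fraction of the gene's `N - 1` within-module pairs flagged as
#' differentially correlated. The default counts the sampling-consensus DEE
#' indicator; `indicator = "sc_full"` counts the single full-data-round Sc
#' instead.
#'
#' @param gene gene id (member of the module).
#' @param diffcorr a [consensus_diffcorr()] result.
#' @param indicator `"dee"` or `"sc_full"`.
#' @return Value in \[0, 1\].
#' @export
gene_corc <- function(gene, diffcorr, indicator = c("dee", "sc_full")) {
  stopifnot(inherits(diffcorr, "ModuleDiffCorr"))
  indicator <- match.arg(indicator)
  if (!gene %in% diffcorr$genes) stop("gene is not in the module")
  n <- length(diffcorr$genes)
  hit <- diffcorr$pairs$gene_a == gene | diffcorr$pairs$gene_b == gene
  flags <- if (indicator == "dee") diffcorr$dee else diffcorr$sc_full
  sum(flags[hit]) / (n - 1)
}

#' Module-specific gene importance
#'
#' Combines the gene's differential-expression term, its differential-
#' correlation ratio and its GO-based basic importance. In the default
#' `complement` mode the DE addend is `1 - padj`, so stronger differential
#' expression increases importance; `raw` mode adds the adjusted p-value
#' itself.
#'
#' @param de_padj the gene's full-data adjusted p-value.
#' @param corc the gene's [gene_corc()] value.
#' @param info the gene's [gene_basic_importance()] value.
#' @param padj_mode `"complement"` or `"raw"`.
#' @return Importance score (at most 3 in complement mode).
#' @export
gene_importance <- function(de_padj, corc, info,
                            padj_mode = c("complement", "raw")) {
  padj_mode <- match.arg(padj_mode)
  de_term <- if (padj_mode == "complement") 1 - de_padj else de_padj
  de_term + corc + as.numeric(info)
}

#' Order a module's gene scores into a local ranking
#'
#' Descending by importance; ties broken by higher `info`, then higher
#' `corc`, then lexicographic gene id, making the order deterministic.
#'
#' @param scores data frame with columns `gene`, `p_gene`, `info`, `corc`.
#' @return The data frame reordered, with a `local_rank` column.
#' @export
rank_module_genes <- function(scores) {
  stopifnot(all(c("gene", "p_gene", "info", "corc") %in% names(scores)))
  ord <- order(-scores$p_gene, -scores$info, -scores$corc, scores$gene,
               method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$local_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Score every module
#'
#' @param ms a [module_set()] already intersected with the expression
#'   universe.
#' @param de a [consensus_de()] result.
#' @param diffcorr named list of `ModuleDiffCorr` objects (one per module).
#' @param seeds character vector of known disease gene ids.
#' @return Data frame: module, n_genes, n_seeds, ncr, ecr, info, p_module.
#' @export
score_modules <- function(ms, de, diffcorr, seeds) {
  stopifnot(inherits(ms, "ModuleSet"))
  rows <- lapply(names(ms$modules), function(nm) {
    g <- ms$modules[[nm]]
    ncr <- module_ncr(g, de)
    ecr <- module_ecr(diffcorr[[nm]])
    info <- module_basic_importance(g, seeds)
    data.frame(module = nm, n_genes = length(g),
               n_seeds = length(intersect(g, seeds)),
               ncr = ncr, ecr = ecr, info = as.numeric(info),
               p_module = module_importance(ncr, ecr, info),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score and locally rank the genes of every module
#'
#' @inheritParams score_modules
#' @param go a [read_go()] object.
#' @param probs optional precomputed [term_probability()] table.
#' @param padj_mode passed to [gene_importance()].
#' @param corc_indicator passed to [gene_corc()].
#' @return Named list (per module) of ranked gene-score data frames with
#'   columns gene, de_term, corc, info, p_gene, local_rank.
#' @export
score_module_genes <- function(ms, de, diffcorr, seeds, go, probs = NULL,
                               padj_mode = c("complement", "raw"),
                               corc_indicator = c("dee", "sc_full")) {
  padj_mode <- match.arg(padj_mode)
  corc_indicator <- match.arg(corc_indicator)
  if (is.null(probs)) probs <- term_probability(go)
  cache <- new.env(parent = emptyenv())
  out <- lapply(names(ms$modules), function(nm) {
    g <- ms$modules[[nm]]
    padj <- de$padj[g]
    padj[is.na(padj)] <- 1
    corc <- vapply(g, gene_corc, numeric(1), diffcorr = diffcorr[[nm]],
                   indicator = corc_indicator)
    info <- vapply(g, gene_basic_importance, numeric(1), module = g,
                   seeds = seeds, go = go, probs = probs, cache = cache)
    de_term <- if (padj_mode == "complement") 1 - padj else padj
    df <- data.frame(gene = g, de_term = unname(de_term),
                     corc = unname(corc), info = unname(info),
                     stringsAsFactors = FALSE)
    df$p_gene <- df$de_term + df$corc + df$info
    rank_module_genes(df)
  })
  stats::setNames(out, names(ms$modules))
}
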