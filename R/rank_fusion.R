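#' Normalize module importance values into selection probabilities
#'
#' Probabilities are proportional to module importance and sum to 1 over
#' modules with positive importance. Zero-importance modules keep probability
#' 0 (they are emitted only after all positive-probability modules are
#' exhausted). When every module has zero importance, a uniform distribution
#' is used with a warning.
#'
#' @param p_module named numeric vector of module importance values.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
normalize_module_probs <- function(p_module) {
  if (!length(p_module)) stop("need at least one module")
  if (any(p_module < 0)) stop("module importance values must be non-negative")
  tot <- sum(p_module)
  if (tot == 0) {
    warning("all module importance values are zero; using uniform probabilities")
    return(stats::setNames(rep(1 / length(p_module), length(p_module)),
                           names(p_module)))
  }
  p_module / tot
}

#' Fuse per-module local rankings into one global gene ranking
#'
#' Recursive expectation-driven fusion: with `i` genes globally ranked and
#' `m(i,j)` of them claimed by module `j`, the next emission comes from the
#' module maximizing `e(i,j) = (i+1) * prob(j) - m(i,j)`, i.e. the module
#' whose expected share of the top `i+1` positions most exceeds what it has
#' already placed. Ties go to the larger probability, then larger raw module
#' importance, then earlier module order. Modules may overlap: the first
#' module to emit a gene claims it, and a later module skips it with its
#' pointer and `m(i,j)` both advanced so the expectation bookkeeping stays
#' consistent. Zero-probability modules are processed, in order, only after
#' every positive-probability module is exhausted. Genes present in the
#' expression matrix but in no module can be appended afterwards, ordered by
#' `1 - padj` descending, flagged with module `"unmoduled"`.
#'
#' @param local_rankings named list (per module) of either character vectors
#'   of gene ids in local-rank order or data frames as returned by
#'   [score_module_genes()] (columns `gene`, `p_gene`).
#' @param probs named numeric vector of module probabilities (see
#'   [normalize_module_probs()]); must cover every module.
#' @param p_module optional named numeric of raw module importance (used for
#'   tie-breaking and reported as `module_score`; defaults to `probs`).
#' @param unmoduled optional named numeric vector of adjusted p-values for
#'   genes outside all modules.
#' @return Data frame (class `GlobalRanking`): rank, gene, module,
#'   local_rank, gene_score, module_score.
#' @export
fuse_rankings <- function(local_rankings, probs, p_module = NULL,
                          unmoduled = NULL) {
  mods <- names(local_rankings)
  if (is.null(mods) || !all(mods %in% names(probs)))
    stop("every local ranking needs a probability")
  if (is.null(p_module)) p_module <- probs
  genes_of <- lapply(local_rankings, function(x)
    if (is.data.frame(x)) as.character(x$gene) else as.character(x))
  score_of <- lapply(local_rankings, function(x)
    if (is.data.frame(x) && "p_gene" %in% names(x)) as.numeric(x$p_gene)
    else rep(NA_real_, if (is.data.frame(x)) nrow(x) else length(x)))

  nmod <- length(mods)
  ptr <- rep(1L, nmod)           # next unconsumed local position
  m_ij <- rep(0L, nmod)          # genes claimed per module
  npm <- vapply(genes_of, length, integer(1))
  total <- length(unique(unlist(genes_of, use.names = FALSE)))
  emitted <- new.env(parent = emptyenv())
  pv <- as.numeric(probs[mods])
  pm <- as.numeric(p_module[mods])

  res_rank <- integer(total); res_gene <- character(total)
  res_mod <- character(total); res_lrank <- integer(total)
  res_gs <- numeric(total); res_ms <- numeric(total)

  i <- 0L
  while (i < total) {
    # advance pointers past genes already claimed elsewhere, incrementing
    # m(i,j) for each skip so the expectation bookkeeping stays consistent
    for (j in seq_len(nmod)) {
      while (ptr[j] <= npm[j] &&
             !is.null(emitted[[genes_of[[j]][ptr[j]]]])) {
        ptr[j] <- ptr[j] + 1L
        m_ij[j] <- m_ij[j] + 1L
      }
    }
    alive <- which(ptr <= npm)
    pos <- alive[pv[alive] > 0]
    cand <- if (length(pos)) pos else alive[1L]  # zero-prob: file order
    if (length(cand) > 1L) {
      e <- (i + 1) * pv[cand] - m_ij[cand]
      ord <- order(-e, -pv[cand], -pm[cand], cand, method = "radix")
      j <- cand[ord[1L]]
    } else j <- cand[1L]
    lr <- ptr[j]
    g <- genes_of[[j]][lr]
    i <- i + 1L
    res_rank[i] <- i; res_gene[i] <- g; res_mod[i] <- mods[j]
    res_lrank[i] <- lr; res_gs[i] <- score_of[[j]][lr]; res_ms[i] <- pm[j]
    emitted[[g]] <- TRUE
    ptr[j] <- ptr[j] + 1L
    m_ij[j] <- m_ij[j] + 1L
  }

  out <- data.frame(rank = res_rank, gene = res_gene, module = res_mod,
                    local_rank = res_lrank, gene_score = res_gs,
                    module_score = res_ms, stringsAsFactors = FALSE)

  if (!is.null(unmoduled) && length(unmoduled)) {
    extra <- unmoduled[!names(unmoduled) %in% out$gene]
    if (length(extra)) {
      ord <- order(extra, names(extra), method = "radix")  # padj ascending
      add <- data.frame(rank = total + seq_along(extra),
                        gene = names(extra)[ord],
                        module = "unmoduled",
                        local_rank = NA_integer_,
                        gene_score = 1 - unname(extra)[ord],
                        module_score = 0,
                        stringsAsFactors = FALSE)
      out <- rbind(out, add)
    }
  }
  class(out) <- c("GlobalRanking", "data.frame")
  validate_ranking(out)
  out
}
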