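#' Specification for a synthetic pipeline fixture
#'
#' Defines a fully deterministic emulation of every pipeline input: an
#' expression matrix with planted differentially expressed genes and planted
#' condition-specific correlation blocks, a GMT module collection (signal
#' modules around the planted blocks plus pure-noise modules), a balanced toy
#' GO DAG with gene annotations in which seed genes and designated "related"
#' genes share subtrees, and a seed gene list.
#'
#' @param n_genes total genes.
#' @param n_normal,n_tumor samples per condition.
#' @param n_modules total modules (the first `n_corr_blocks` carry signal).
#' @param module_size_range integer length-2: min/max module size.
#' @param n_de_genes planted differentially expressed genes (block genes are
#'   planted first, extras drawn from the remaining pool).
#' @param de_log2_fold tumor log2 fold change of planted DE genes.
#' @param n_corr_blocks,corr_block_size planted correlation blocks.
#' @param r_normal,r_tumor within-block pairwise correlation per condition.
#' @param n_seeds known disease genes (distributed over signal modules).
#' @param go_depth,go_branching balanced-DAG shape (>= 2 each).
#' @param terms_per_gene annotation records per gene.
#' @param rng_seed integer master seed; identical seeds give byte-identical
#'   outputs.
#' @return Object of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_genes = 500L, n_normal = 50L, n_tumor = 50L,
                         n_modules = 20L, module_size_range = c(10L, 25L),
                         n_de_genes = 50L, de_log2_fold = 2,
                         n_corr_blocks = 5L, corr_block_size = 8L,
                         r_normal = 0.9, r_tumor = 0.0,
                         n_seeds = 10L, go_depth = 4L, go_branching = 3L,
                         terms_per_gene = 5L, rng_seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
               n_tumor = as.integer(n_tumor), n_modules = as.integer(n_modules),
               module_size_range = as.integer(module_size_range),
               n_de_genes = as.integer(n_de_genes),
               de_log2_fold = de_log2_fold,
               n_corr_blocks = as.integer(n_corr_blocks),
               corr_block_size = as.integer(corr_block_size),
               r_normal = r_normal, r_tumor = r_tumor,
               n_seeds = as.integer(n_seeds), go_depth = as.integer(go_depth),
               go_branching = as.integer(go_branching),
               terms_per_gene = as.integer(terms_per_gene),
               rng_seed = as.integer(rng_seed))
  with(spec, {
    stopifnot(n_genes >= 10L, n_normal >= 4L, n_tumor >= 4L, n_modules >= 1L,
              length(module_size_range) == 2L,
              module_size_range[1L] >= 2L,
              module_size_range[2L] >= module_size_range[1L],
              n_de_genes >= 0L, n_corr_blocks >= 0L,
              r_normal >= 0, r_normal < 1, r_tumor >= 0, r_tumor < 1,
              n_seeds >= 0L, go_depth >= 2L, go_branching >= 2L,
              terms_per_gene >= 1L)
    if (n_corr_blocks > 0L && corr_block_size < 2L)
      stop("corr_block_size must be >= 2")
    if (n_corr_blocks > 0L && corr_block_size > module_size_range[2L])
      stop("corr_block_size exceeds the maximum module size")
    if (n_corr_blocks * corr_block_size + n_seeds + n_de_genes > n_genes)
      stop("planted gene sets exceed n_genes")
    if (n_corr_blocks > n_modules)
      stop("more correlation blocks than modules")
  })
  class(spec) <- "FixtureSpec"
  spec
}

#' Generate a synthetic fixture on disk
#'
#' Writes `expression.tsv`, `conditions.tsv`, `modules.gmt`,
#' `annotations.tsv`, `go.obo`, `seeds.txt` and a ground-truth
#' `manifest.json` into `out_dir`. Within-block correlation is induced by a
#' shared latent factor per block and condition: on the log2 scale each block
#' gene is `sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving expected
#' pairwise correlation `rho`. Seed genes and the per-block "related" genes
#' are annotated with a common deep GO subtree so their fuzzy-measure
#' similarity is high; background genes draw terms uniformly from the leaves.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the ground-truth manifest (also written as JSON):
#'   planted DE genes, correlation blocks, seed genes, related genes, signal
#'   and noise module names, and file paths.
#' @export
generate_fixture <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- with_seed(spec$rng_seed, build_fixture(spec))

  paths <- list(
    expression = file.path(out_dir, "expression.tsv"),
    conditions = file.path(out_dir, "conditions.tsv"),
    modules = file.path(out_dir, "modules.gmt"),
    annotations = file.path(out_dir, "annotations.tsv"),
    obo = file.path(out_dir, "go.obo"),
    seeds = file.path(out_dir, "seeds.txt"),
    manifest = file.path(out_dir, "manifest.json"))

  expr_chr <- cbind(gene = manifest$genes,
                    matrix(sprintf("%.4f", manifest$values),
                           nrow = length(manifest$genes),
                           dimnames = list(NULL, colnames(manifest$values))))
  utils::write.table(expr_chr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(manifest$values),
               condition = manifest$condition),
    paths$conditions, sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(manifest$module_set, paths$modules)
  utils::write.table(manifest$annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(manifest$obo_lines, paths$obo)
  writeLines(manifest$seed_genes, paths$seeds)

  truth <- list(spec = unclass(spec),
                de_genes = manifest$de_genes,
                seed_genes = manifest$seed_genes,
                related_genes = manifest$related_genes,
                blocks = manifest$blocks,
                signal_modules = manifest$signal_modules,
                noise_modules = manifest$noise_modules)
  jsonlite::write_json(truth, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(truth, list(paths = paths)))
}

# All random construction happens here, under the caller's seed.
build_fixture <- function(spec) {
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  samples <- c(sprintf("N%03d", seq_len(spec$n_normal)),
               sprintf("T%03d", seq_len(spec$n_tumor)))
  condition <- c(rep("normal", spec$n_normal), rep("tumor", spec$n_tumor))

  pool <- sample(genes)
  take <- function(k) {
    if (k == 0L) return(character(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  blocks <- if (spec$n_corr_blocks > 0L)
    lapply(seq_len(spec$n_corr_blocks), function(b) take(spec$corr_block_size))
  else list()
  names(blocks) <- if (length(blocks)) sprintf("block%02d", seq_along(blocks))
  seed_genes <- if (spec$n_seeds > 0L) sort(take(spec$n_seeds)) else character(0)
  block_genes <- unlist(blocks, use.names = FALSE)
  n_de_from_blocks <- min(spec$n_de_genes, length(block_genes))
  de_genes <- c(if (n_de_from_blocks) block_genes[seq_len(n_de_from_blocks)],
                if (spec$n_de_genes > n_de_from_blocks)
                  take(spec$n_de_genes - n_de_from_blocks))
  de_genes <- sort(de_genes)
  background <- pool  # untouched genes

  # expression on the log2 scale
  base_mean <- stats::runif(spec$n_genes, 5, 9)
  sdw <- 0.5
  lg <- matrix(stats::rnorm(spec$n_genes * length(samples)),
               nrow = spec$n_genes,
               dimnames = list(genes, samples))
  for (b in seq_along(blocks)) {
    rows <- match(blocks[[b]], genes)
    for (cond in c("normal", "tumor")) {
      rho <- if (cond == "normal") spec$r_normal else spec$r_tumor
      cols <- which(condition == cond)
      f <- stats::rnorm(length(cols))
      lg[rows, cols] <- sqrt(rho) *
        matrix(f, nrow = length(rows), ncol = length(cols), byrow = TRUE) +
        sqrt(1 - rho) * matrix(stats::rnorm(length(rows) * length(cols)),
                               nrow = length(rows))
    }
  }
  lg <- base_mean + sdw * lg
  if (length(de_genes))
    lg[match(de_genes, genes), condition == "tumor"] <-
      lg[match(de_genes, genes), condition == "tumor"] + spec$de_log2_fold
  values <- 2^lg

  # modules: one signal module per block (block + its seeds + related +
  # background fillers), then pure-noise modules from the background pool
  n_signal <- length(blocks)
  mod_names <- c(if (n_signal) sprintf("signal_module%02d", seq_len(n_signal)),
                 if (spec$n_modules > n_signal)
                   sprintf("noise_module%02d",
                           seq_len(spec$n_modules - n_signal)))
  seed_home <- if (n_signal > 0L && length(seed_genes))
    stats::setNames(rep(seq_len(n_signal), length.out = length(seed_genes)),
                    seed_genes)
  else if (length(seed_genes))
    stats::setNames(rep(1L, length(seed_genes)), seed_genes)
  else stats::setNames(integer(0), character(0))

  related_genes <- character(0)
  modules <- vector("list", spec$n_modules)
  names(modules) <- mod_names
  noise_pool <- setdiff(background, de_genes)
  for (j in seq_len(spec$n_modules)) {
    size <- sample(seq(spec$module_size_range[1L], spec$module_size_range[2L]),
                   1L)
    if (j <= n_signal) {
      core <- c(blocks[[j]], names(seed_home)[seed_home == j])
      rel <- blocks[[j]][seq_len(min(2L, length(blocks[[j]])))]
      related_genes <- c(related_genes, rel)
      fill_n <- max(0L, size - length(core))
      fill <- if (fill_n) sample(noise_pool, min(fill_n, length(noise_pool)))
              else character(0)
      modules[[j]] <- c(core, fill)
    } else if (j == n_signal + 1L && n_signal == 0L && length(seed_genes)) {
      core <- seed_genes
      fill <- sample(noise_pool, max(0L, size - length(core)))
      modules[[j]] <- c(core, fill)
    } else {
      modules[[j]] <- sample(noise_pool, min(size, length(noise_pool)))
    }
  }
  related_genes <- sort(unique(related_genes))

  # toy GO: balanced DAG (tree) of given depth/branching
  dag <- build_toy_dag(spec$go_depth, spec$go_branching)
  # subtree roots used to co-annotate seeds and related genes per module
  sub_roots <- dag$by_depth[[min(3L, length(dag$by_depth))]]
  deep_terms <- unlist(dag$by_depth[seq(min(3L, length(dag$by_depth)),
                                        length(dag$by_depth))],
                       use.names = FALSE)
  leaf_terms <- dag$by_depth[[length(dag$by_depth)]]

  module_terms <- lapply(seq_len(max(1L, n_signal)), function(j) {
    root <- sub_roots[((j - 1L) %% length(sub_roots)) + 1L]
    cand <- intersect(c(root, dag$descendants[[root]]), deep_terms)
    sample(cand, min(spec$terms_per_gene, length(cand)))
  })

  ann_gene <- character(0)
  ann_term <- character(0)
  annotate <- function(g, terms) {
    ann_gene <<- c(ann_gene, rep(g, length(terms)))
    ann_term <<- c(ann_term, terms)
  }
  home_of <- function(g) {
    for (j in seq_len(n_signal)) if (g %in% modules[[j]]) return(j)
    1L
  }
  for (g in genes) {
    if (g %in% seed_genes) {
      annotate(g, module_terms[[home_of(g)]])
    } else if (g %in% related_genes) {
      mt <- module_terms[[home_of(g)]]
      keep <- mt[seq_len(max(1L, length(mt) - 1L))]
      extra <- sample(setdiff(leaf_terms, keep),
                      max(0L, spec$terms_per_gene - length(keep)))
      annotate(g, c(keep, extra))
    } else {
      annotate(g, sample(leaf_terms, min(spec$terms_per_gene,
                                         length(leaf_terms))))
    }
  }

  list(genes = genes, values = values, condition = condition,
       module_set = module_set(modules),
       annotations = data.frame(gene = ann_gene, term = ann_term,
                                stringsAsFactors = FALSE),
       obo_lines = dag$obo_lines,
       de_genes = de_genes, seed_genes = seed_genes,
       related_genes = related_genes, blocks = blocks,
       signal_modules = mod_names[seq_len(n_signal)],
       noise_modules = setdiff(mod_names, mod_names[seq_len(n_signal)]))
}

# Balanced is_a tree: level 1 is the root, each node has `branching`
# children, `depth + 1` levels in total. Returns OBO text plus adjacency.
build_toy_dag <- function(depth, branching) {
  n_levels <- depth + 1L
  by_depth <- vector("list", n_levels)
  counter <- 0L
  new_term <- function() {
    counter <<- counter + 1L
    sprintf("GO:%07d", counter)
  }
  parents <- list()
  by_depth[[1L]] <- new_term()
  parents[[by_depth[[1L]]]] <- character(0)
  for (lev in 2:n_levels) {
    kids <- character(0)
    for (p in by_depth[[lev - 1L]]) {
      for (k in seq_len(branching)) {
        id <- new_term()
        parents[[id]] <- p
        kids <- c(kids, id)
      }
    }
    by_depth[[lev]] <- kids
  }
  terms <- unlist(by_depth, use.names = FALSE)
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms)
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  obo <- c("format-version: 1.2", "")
  for (t in terms) {
    obo <- c(obo, "[Term]", paste0("id: ", t),
             paste0("name: synthetic term ", t))
    for (p in parents[[t]])
      obo <- c(obo, paste0("is_a: ", p, " ! synthetic parent"))
    obo <- c(obo, "")
  }
  list(terms = terms, by_depth = by_depth, parents = parents,
       children = children,
       descendants = descendant_closure(children, terms),
       obo_lines = obo)
}

#' Achieved within-block correlations of a generated fixture
#'
#' Mean pairwise Pearson correlation (log2 scale) within every planted block,
#' per condition, next to the planted targets.
#'
#' @param expr an [expression_data()] object loaded from the fixture.
#' @param manifest manifest returned by [generate_fixture()] (or read from
#'   its `manifest.json`).
#' @return Data frame: block, target_normal, target_tumor, achieved_normal,
#'   achieved_tumor.
#' @export
empirical_correlation_check <- function(expr, manifest) {
  stopifnot(inherits(expr, "ExpressionData"))
  blocks <- manifest$blocks
  if (!length(blocks)) return(data.frame())
  lg <- log2(expr$values + 1)
  mean_block_cor <- function(g, cond) {
    m <- stats::cor(t(lg[g, expr$condition == cond, drop = FALSE]))
    mean(m[upper.tri(m)])
  }
  tn <- manifest$spec$r_normal
  tt <- manifest$spec$r_tumor
  data.frame(
    block = names(blocks),
    target_normal = tn, target_tumor = tt,
    achieved_normal = vapply(blocks, mean_block_cor, numeric(1), "normal"),
    achieved_tumor = vapply(blocks, mean_block_cor, numeric(1), "tumor"),
    row.names = NULL, stringsAsFactors = FALSE)
}
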