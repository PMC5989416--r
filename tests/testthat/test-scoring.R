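make_de_result <- function(padj, deg) {
  structure(list(padj = padj,
                 vote_fraction = stats::setNames(as.numeric(deg), names(deg)),
                 deg = deg,
                 params = de_params(S = 1)),
            class = "DeResult")
}

make_dc <- function(genes, dee, sc_full = dee) {
  pairs <- t(combn(genes, 2))
  structure(list(module_name = "m", genes = genes,
                 pairs = data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                                    stringsAsFactors = FALSE),
                 sc_full = sc_full, sc_fraction = as.numeric(dee), dee = dee),
            class = "ModuleDiffCorr")
}

test_that("module-level ratios follow their defining fractions", {
  deg <- stats::setNames(c(1L, 1L, 0L, 0L, 0L), sprintf("g%d", 1:5))
  de <- make_de_result(stats::setNames(rep(0.5, 5), names(deg)), deg)
  expect_equal(module_ncr(sprintf("g%d", 1:5), de), 0.4)
  expect_equal(module_ncr(sprintf("g%d", 1:2), de), 1.0)
  expect_equal(module_ncr(sprintf("g%d", 3:5), de), 0.0)
  # genes missing from the DE result count as non-DE
  expect_equal(module_ncr(c("g1", "unknown"), de), 0.5)

  dc <- make_dc(sprintf("g%d", 1:4), c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(module_ecr(dc), 0.5)
  expect_equal(module_ecr(make_dc(sprintf("g%d", 1:3), rep(1L, 3))), 1.0)
  expect_equal(module_ecr(make_dc(sprintf("g%d", 1:3), rep(0L, 3))), 0.0)
})

test_that("module basic importance is (seeds + 1) / N, allowed above 1", {
  expect_equal(as.numeric(module_basic_importance(sprintf("g%d", 1:10),
                                                  character(0))), 0.1)
  expect_equal(as.numeric(module_basic_importance(sprintf("g%d", 1:6),
                                                  c("g1", "g2"))), 0.5)
  v <- module_basic_importance("g1", "g1")
  expect_equal(as.numeric(v), 2.0)
  expect_true(attr(v, "exceeds_one"))
})

test_that("module importance combines its three components exactly", {
  expect_equal(module_importance(0.4, 0.2, 0.3), 0.09)
  expect_equal(module_importance(0, 0, 0.99), 0)
  expect_equal(module_importance(1, 1, 1), 1)
})

test_that("gene corc is the flagged fraction of the gene's pairs", {
  genes <- sprintf("g%d", 1:5)
  dc <- make_dc(genes, rep(0L, 10))
  # flag pairs g1-g2 and g1-g3 via dee, and also test the sc_full variant
  dee <- rep(0L, 10)
  pairs <- dc$pairs
  dee[(pairs$gene_a == "g1" & pairs$gene_b %in% c("g2", "g3"))] <- 1L
  dc$dee <- dee
  dc$sc_full <- rep(1L, 10)
  expect_equal(gene_corc("g1", dc), 0.5)
  expect_equal(gene_corc("g4", dc), 0)
  expect_equal(gene_corc("g1", dc, indicator = "sc_full"), 1.0)
  expect_error(gene_corc("zz", dc), "not in the module")
})

test_that("gene importance handles both padj directions", {
  expect_equal(gene_importance(0.01, 0.5, 0.2, padj_mode = "raw"), 0.71)
  expect_equal(gene_importance(0.01, 0.5, 0.2, padj_mode = "complement"),
               1.69)
  expect_equal(gene_importance(0, 1, 1, padj_mode = "complement"), 3)
})

test_that("local ranking is deterministic with documented tie-breaks", {
  sc <- data.frame(gene = c("b", "a", "c"),
                   p_gene = c(3.0, 1.5, 0.2),
                   info = c(0, 0, 0), corc = c(0, 0, 0),
                   stringsAsFactors = FALSE)
  expect_equal(rank_module_genes(sc)$gene, c("b", "a", "c"))

  tie <- data.frame(gene = c("zed", "ann"),
                    p_gene = c(1, 1), info = c(0.5, 0.5), corc = c(0, 0),
                    stringsAsFactors = FALSE)
  expect_equal(rank_module_genes(tie)$gene, c("ann", "zed"))

  tie2 <- data.frame(gene = c("a", "b"), p_gene = c(1, 1),
                     info = c(0.2, 0.9), corc = c(0, 0),
                     stringsAsFactors = FALSE)
  expect_equal(rank_module_genes(tie2)$gene, c("b", "a"))

  single <- data.frame(gene = "x", p_gene = 0.5, info = 0, corc = 0,
                       stringsAsFactors = FALSE)
  expect_equal(rank_module_genes(single)$local_rank, 1L)
})

test_that("a seed gene never ranks below a non-seed with equal DE and corc", {
  # both non-seeds share only the common term a with the seed; the seed's
  # rarest term b is unshared, so every similarity (hence info) stays < 1
  go <- make_go(list(r = character(0), a = "r", b = "r", d = "r"),
                list(s1 = c("a", "b"), g1 = c("a", "d"), g2 = "a"))
  genes <- c("s1", "g1", "g2")
  deg <- stats::setNames(rep(0L, 3), genes)
  padj <- stats::setNames(rep(0.5, 3), genes)
  de <- make_de_result(padj, deg)
  dc <- list(m = make_dc(genes, rep(0L, 3)))
  ms <- module_set(list(m = genes))
  ranked <- score_module_genes(ms, de, dc, seeds = "s1", go = go)$m
  expect_equal(ranked$gene[1], "s1")
  expect_equal(ranked$info[ranked$gene == "s1"], 1)
})

test_that("pipeline scores are recomputable from upstream artifacts", {
  sp <- fixture_spec(n_genes = 80, n_normal = 10, n_tumor = 10,
                     n_modules = 4, module_size_range = c(6, 9),
                     n_de_genes = 10, n_corr_blocks = 1,
                     corr_block_size = 4, n_seeds = 2, rng_seed = 3)
  d <- tempfile()
  mf <- generate_fixture(sp, d)
  expr <- read_expression(mf$paths$expression, mf$paths$conditions)
  ms <- read_gmt(mf$paths$modules)
  go <- read_go(mf$paths$annotations, mf$paths$obo)
  seeds <- read_seed_genes(mf$paths$seeds)
  res <- suppressMessages(
    mgogp_run(expr, ms, go, seeds, de = de_params(S = 5),
              corr = corr_params(S = 5, fdr_method = "bh"), seed = 4))

  msx <- suppressMessages(intersect_modules(ms, expr, verbose = FALSE))
  for (k in seq_len(nrow(res$module_scores))) {
    row <- res$module_scores[k, ]
    g <- msx$modules[[row$module]]
    expect_equal(row$ncr, module_ncr(g, res$de))
    expect_equal(row$ecr, module_ecr(res$diffcorr[[row$module]]))
    expect_equal(row$info,
                 as.numeric(module_basic_importance(g, seeds)))
    expect_equal(row$p_module,
                 module_importance(row$ncr, row$ecr, row$info))
  }
  gs <- res$gene_scores[[1]]
  expect_equal(gs$p_gene, gs$de_term + gs$corc + gs$info)
})
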