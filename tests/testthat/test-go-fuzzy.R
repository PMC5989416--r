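test_that("term probabilities count descendant-closed corpus frequencies", {
  # 10 annotation records; leaf t3 annotated once; root covers everything
  go <- make_go(list(root = character(0), t2 = "root", t3 = "root"),
                list(gA = rep("t2", 1), gB = "t3",
                     gC = c("t2", "root"), gD = "t2"))
  # records: t2 x3, t3 x1, root x1 -> total 5
  tp <- term_probability(go)
  expect_equal(tp$corpus_size, 5)
  expect_equal(unname(tp$p[["root"]]), 1)           # closure covers all
  expect_equal(unname(tp$p[["t3"]]), 1 / 5)

  # diamond: a record at the sink counts once at the root
  go2 <- make_go(list(r = character(0), a = "r", b = "r", s = c("a", "b")),
                 list(gA = "s", gB = "a"))
  tp2 <- term_probability(go2)
  expect_equal(unname(tp2$p[["r"]]), 1)
  expect_equal(unname(tp2$p[["a"]]), 1)   # s under a, plus a itself
  expect_equal(unname(tp2$p[["s"]]), 1 / 2)
})

test_that("term probability is monotone up the DAG", {
  set.seed(31)
  n <- 15
  terms <- sprintf("t%02d", 1:n)
  parents <- stats::setNames(vector("list", n), terms)
  for (k in 2:n) parents[[terms[k]]] <- sample(terms[1:(k - 1)], 1)
  ann <- lapply(1:20, function(i) sample(terms, 3))
  names(ann) <- sprintf("g%02d", 1:20)
  go <- make_go(parents, ann)
  tp <- term_probability(go)
  for (t in terms)
    for (p in go$parents[[t]])
      expect_gte(tp$p[[p]], tp$p[[t]])
})

test_that("fuzzy densities are normalized information content", {
  probs <- make_probs(c(A = exp(-2), B = exp(-1), C = 1))
  fd <- fuzzy_density(c("A", "B"), probs)
  expect_equal(unname(fd$density[c("A", "B")]), c(1, 0.5))
  expect_false(fd$all_zero)

  fd1 <- fuzzy_density("A", probs)
  expect_equal(unname(fd1$density[["A"]]), 1)  # self-normalization

  fdC <- fuzzy_density(c("A", "C"), probs)
  expect_equal(unname(fdC$density[["C"]]), 0)  # p = 1 -> density 0

  fd0 <- fuzzy_density("C", probs)
  expect_true(fd0$all_zero)

  expect_warning(fuzzy_density(c("A", "missing"), probs), "dropped")
})

test_that("lambda solver reproduces closed-form quadratic roots", {
  expect_equal(solve_lambda(c(0.5, 0.5)), 0)
  expect_equal(solve_lambda(c(0.2, 0.3)), 25 / 3, tolerance = 1e-9)
  expect_equal(solve_lambda(c(0.6, 0.6)), -5 / 9, tolerance = 1e-9)
  # single density: identity holds for every lambda; 0 by convention
  l1 <- solve_lambda(1.0)
  expect_equal(as.numeric(l1), 0)
  expect_true(attr(l1, "degenerate"))
  expect_error(solve_lambda(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("lambda residuals stay tiny on random density sets", {
  set.seed(7)
  for (k in 1:200) {
    d <- runif(sample(2:20, 1), 0.01, 0.99)
    l <- as.numeric(solve_lambda(d))
    expect_lt(abs(prod(1 + l * d) - (1 + l)), 1e-10)
    expect_gt(l, -1)
  }
})

test_that("the Sugeno measure satisfies its boundary and monotonicity axioms", {
  probs <- make_probs(c(A = exp(-2), B = exp(-1), C = exp(-0.5)))
  fd <- fuzzy_density(c("A", "B", "C"), probs)
  expect_equal(sugeno_measure(character(0), fd), 0)
  expect_equal(sugeno_measure(c("A", "B", "C"), fd), 1, tolerance = 1e-9)
  expect_equal(sugeno_measure("B", fd), unname(fd$density[["B"]]),
               tolerance = 1e-9)
  expect_error(sugeno_measure("Z", fd), "outside")

  # lambda-rule evaluation on a hand-solved density set
  fd2 <- structure(list(terms = c("x", "y"),
                        density = c(x = 0.2, y = 0.3),
                        lambda = 25 / 3, all_zero = FALSE),
                   class = "FuzzyDensitySet")
  expect_equal(sugeno_measure(c("x", "y"), fd2),
               min(1, 0.2 + 0.3 + (25 / 3) * 0.06), tolerance = 1e-12)

  # random monotonicity checks
  set.seed(12)
  for (k in 1:100) {
    terms <- letters[1:6]
    probs_k <- make_probs(stats::setNames(runif(6, 0.05, 0.9), terms))
    fdk <- fuzzy_density(terms, probs_k)
    a <- sample(terms, sample(0:5, 1))
    b <- unique(c(a, sample(terms, sample(1:6, 1))))
    expect_lte(sugeno_measure(a, fdk), sugeno_measure(b, fdk) + 1e-12)
  }
})

test_that("near-additive density sets agree with the additive measure", {
  # densities summing to 1 +/- 1e-6: lambda-rule must match the sum to
  # first order
  for (s in c(1 - 1e-6, 1 + 1e-6)) {
    d <- c(0.4, 0.35, 0.25) * s
    fd <- structure(list(terms = c("a", "b", "c"),
                         density = stats::setNames(d, c("a", "b", "c")),
                         lambda = as.numeric(solve_lambda(d)),
                         all_zero = FALSE),
                    class = "FuzzyDensitySet")
    expect_equal(sugeno_measure(c("a", "b"), fd), d[1] + d[2],
                 tolerance = 1e-5)
  }
})

test_that("fuzzy-measure similarity is symmetric with exact boundary cases", {
  probs <- make_probs(c(A = exp(-2), B = exp(-1), C = exp(-3),
                        D = exp(-0.4)))
  expect_equal(fms_similarity(c("A", "B"), c("A", "B"), probs), 1,
               tolerance = 1e-9)
  expect_equal(fms_similarity(c("A", "B"), c("C", "D"), probs), 0)

  # hand trace: genes {A,B} and {B,C}; shared singleton {B} measures each
  # gene's own density of B, so FMS = (0.5 + 1/3) / 2 = 5/12
  expect_equal(fms_similarity(c("A", "B"), c("B", "C"), probs), 5 / 12,
               tolerance = 1e-9)

  set.seed(5)
  terms <- sprintf("T%02d", 1:12)
  probs_big <- make_probs(stats::setNames(runif(12, 0.02, 0.95), terms))
  for (k in 1:50) {
    ta <- sample(terms, sample(1:6, 1))
    tb <- sample(terms, sample(1:6, 1))
    expect_identical(fms_similarity(ta, tb, probs_big),
                     fms_similarity(tb, ta, probs_big))
  }

  # unusable gene (all terms have probability 1)
  probs1 <- make_probs(c(A = 1, B = exp(-1)))
  expect_equal(fms_similarity("A", c("A", "B"), probs1), 0)
})

test_that("gene basic importance follows the three-branch rule", {
  go <- make_go(list(r = character(0), a = "r", b = "r", c = "r"),
                list(gene1 = c("a", "b"), seed1 = c("a", "b"),
                     seed2 = "c", other = "c"))
  module <- c("gene1", "seed1", "seed2", "other")
  seeds <- c("seed1", "seed2")

  expect_equal(gene_basic_importance("gene1", module, character(0), go), 0)
  expect_equal(gene_basic_importance("seed1", module, seeds, go), 1)

  # gene1 shares all terms with seed1 (sim 1) and none with seed2 (sim 0)
  probs <- term_probability(go)
  v <- gene_basic_importance("gene1", module, seeds, go, probs)
  expect_equal(v, 0.5, tolerance = 1e-9)
  expect_error(gene_basic_importance("absent", module, seeds, go),
               "not a member")
})
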