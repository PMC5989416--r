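test_that("pearson_cor matches the textbook formula and flags degeneracy", {
  expect_equal(pearson_cor(1:4, 1:4), 1.0)
  expect_equal(pearson_cor(1:4, 4:1), -1.0)

  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y), manual, tolerance = 1e-14)

  r <- pearson_cor(c(5, 5, 5, 5), 1:4)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(pearson_cor(1:4, 1:5), "length mismatch")
  expect_error(pearson_cor(1:3, 1:3), ">= 4")
})

test_that("fisher_z is arctanh with clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(-0.37), -fisher_z(0.37))
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_warning(z <- fisher_z(1), "clamped")
  expect_true(is.finite(z))
})

test_that("the z statistic matches a hand evaluation and is antisymmetric", {
  expect_equal(diffcorr_z(0.5, 0.5, 50, 50), 0)
  expect_equal(diffcorr_z(0.5, 0, 103, 103),
               0.5 * log(3) / sqrt(1 / 100 + 1 / 100), tolerance = 1e-12)
  expect_equal(diffcorr_z(0.3, 0.7, 40, 60), -diffcorr_z(0.7, 0.3, 40, 60))
  expect_error(diffcorr_z(0.1, 0.2, 3, 50), "L > 3")

  # brute-force re-evaluation of the transform + standardization
  set.seed(99)
  for (k in 1:1000) {
    rN <- runif(1, -0.95, 0.95); rT <- runif(1, -0.95, 0.95)
    L <- sample(5:200, 1); Q <- sample(5:200, 1)
    manual <- (0.5 * log((1 + rN) / (1 - rN)) -
               0.5 * log((1 + rT) / (1 - rT))) /
      sqrt(1 / (L - 3) + 1 / (Q - 3))
    expect_equal(diffcorr_z(rN, rT, L, Q), manual, tolerance = 1e-12)
  }
})

test_that("local fdr separates null from strong signal and guards small n", {
  expect_warning(f <- pair_fdr(rnorm(50), "local_fdr"), "falling back")

  set.seed(123)
  z_null <- rnorm(10000)
  f_null <- pair_fdr(z_null, "local_fdr")
  expect_gte(mean(f_null > 0.05), 0.99)

  z_mix <- c(rnorm(9500), sample(c(-8, 8), 500, replace = TRUE))
  f_mix <- pair_fdr(z_mix, "local_fdr")
  expect_true(all(f_mix[9501:10000] < 0.05))

  expect_equal(pair_fdr(rep(2, 300), "local_fdr"), rep(1, 300))

  # BH route agrees with p.adjust on two-sided normal p-values
  z <- rnorm(40)
  expect_equal(pair_fdr(z, "bh"),
               p.adjust(2 * pnorm(-abs(z)), "BH"), tolerance = 1e-14)
})

test_that("consensus differential correlation recovers a planted block", {
  set.seed(17)
  n <- 50
  cond <- stats::setNames(rep(c("normal", "tumor"), each = n),
                          c(sprintf("n%02d", 1:n), sprintf("t%02d", 1:n)))
  # 4 genes sharing a factor in normal only, 2 independent genes
  lgN <- sqrt(0.9) * matrix(rnorm(n), 4, n, byrow = TRUE) +
    sqrt(0.1) * matrix(rnorm(4 * n), 4)
  lgT <- matrix(rnorm(4 * n), 4)
  lg <- rbind(cbind(lgN, lgT), matrix(rnorm(2 * 2 * n), 2))
  rownames(lg) <- sprintf("g%d", 1:6)
  colnames(lg) <- names(cond)
  expr <- expression_data(2^(6 + 0.5 * lg), cond)

  res <- consensus_diffcorr(expr, rownames(lg),
                            corr_params(S = 10, delta = 0.9, upsilon = 0.05,
                                        rng_seed = 3, fdr_method = "bh"),
                            module_name = "toy")
  expect_equal(nrow(res$pairs), 15)  # K = N(N-1)/2
  planted <- res$pairs$gene_a %in% sprintf("g%d", 1:4) &
    res$pairs$gene_b %in% sprintf("g%d", 1:4)
  expect_true(all(res$dee[planted] == 1L))
  expect_true(all(res$r_normal[planted] > 0.6))
  expect_true(all(abs(res$r_tumor[planted]) < 0.4))
  # no self pairs, each unordered pair once
  expect_true(all(res$pairs$gene_a != res$pairs$gene_b))
  key <- apply(res$pairs, 1, function(r) paste(sort(r), collapse = "|"))
  expect_false(any(duplicated(key)))
  # dee recomputable from the vote fractions; monotone in delta
  expect_equal(res$dee, as.integer(res$sc_fraction >= 0.9))
  expect_true(all(which(res$sc_fraction >= 0.95) %in%
                  which(res$sc_fraction >= 0.5)))
})

test_that("two-gene modules give exactly one pair", {
  expr <- make_expr(n_genes = 6, n_normal = 8, n_tumor = 8, seed = 6)
  res <- consensus_diffcorr(expr, c("g001", "g002"),
                            corr_params(S = 3, rng_seed = 1,
                                        fdr_method = "bh"))
  expect_equal(nrow(res$pairs), 1)
})

test_that("degenerate pairs never vote", {
  expr <- make_expr(n_genes = 5, n_normal = 8, n_tumor = 8, seed = 9)
  vals <- expr$values
  vals[1, ] <- 3  # constant
  expr <- expression_data(vals, expr$condition)
  res <- consensus_diffcorr(expr, expr$genes[1:3],
                            corr_params(S = 4, rng_seed = 2,
                                        fdr_method = "bh"))
  bad <- res$pairs$gene_a == "g001" | res$pairs$gene_b == "g001"
  expect_true(all(res$sc_fraction[bad] == 0))
  expect_true(all(res$fdr[bad] == 1))
  expect_true(all(res$z_stat[bad] == 0))
})
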