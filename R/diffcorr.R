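#' Parameters for consensus differential-correlation calling
#'
#' @param S number of random subsampling rounds (default 1000).
#' @param delta vote threshold in (0,1]: a gene pair is a consensus
#'   differential correlation (DEE) when its per-round significance indicator
#'   reaches this fraction (default 0.9).
#' @param upsilon local-fdr threshold for the per-round call (default 0.05).
#' @param subsample_fraction fraction of each condition subsampled per round.
#' @param rng_seed integer seed for the subsample draws.
#' @param fdr_method `"local_fdr"` (empirical-null local false discovery
#'   rate) or `"bh"` (Benjamini-Hochberg q-values on two-sided normal p).
#' @return Object of class `CorrParams`.
#' @export
corr_params <- function(S = 1000L, delta = 0.9, upsilon = 0.05,
                        subsample_fraction = 0.8, rng_seed = 1L,
                        fdr_method = c("local_fdr", "bh")) {
  stopifnot(S >= 1L, delta > 0, delta <= 1, upsilon > 0, upsilon < 1,
            subsample_fraction > 0, subsample_fraction <= 1)
  out <- list(S = as.integer(S), delta = delta, upsilon = upsilon,
              subsample_fraction = subsample_fraction,
              rng_seed = as.integer(rng_seed),
              fdr_method = match.arg(fdr_method))
  class(out) <- "CorrParams"
  out
}

#' Pearson product-moment correlation with degeneracy handling
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return Correlation in \[-1, 1\]; if either vector has zero variance the
#'   value is 0 with attribute `degenerate = TRUE`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 4L) stop("need >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- 0
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  stats::cor(x, y)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `arctanh(r) = 0.5 * log((1 + r) / (1 - r))`; inputs with `|r| >= 1` are
#' clamped to `1 - 1e-7` in magnitude with a warning.
#'
#' @param r correlation value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("correlation(s) with |r| >= 1 clamped before the z-transform")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

#' Fisher z-test statistic for a difference of correlations
#'
#' `Z = (arctanh(rN) - arctanh(rT)) / sqrt(1/(L-3) + 1/(Q-3))`, approximately
#' standard normal when the two population correlations are equal.
#'
#' @param rN,rT condition-specific Pearson correlations (vectors allowed).
#' @param L,Q normal and tumor sample counts; both must exceed 3.
#' @return z statistic(s).
#' @export
diffcorr_z <- function(rN, rT, L, Q) {
  if (L <= 3 || Q <= 3) stop("Fisher z-test needs L > 3 and Q > 3")
  (fisher_z(rN) - fisher_z(rT)) / sqrt(1 / (L - 3) + 1 / (Q - 3))
}

#' Per-pair false discovery rates from z statistics
#'
#' `local_fdr` fits an empirical null Normal(0, sigma) by central matching on
#' the inner 50% of the z values, estimates the null proportion pi0 from the
#' mass consistent with that null, estimates the full density f by a kernel
#' estimate, and returns `fdr(z) = min(1, pi0 * f0(z) / f(z))`. It needs at
#' least 200 values; below that it falls back to `bh` with a warning. `bh`
#' converts z to two-sided normal p-values and applies Benjamini-Hochberg.
#'
#' @param z numeric vector of z statistics.
#' @param method `"local_fdr"` or `"bh"`.
#' @return Numeric vector of fdr values in \[0, 1\], parallel to `z`.
#' @export
pair_fdr <- function(z, method = c("local_fdr", "bh")) {
  method <- match.arg(method)
  z <- as.numeric(z)
  n <- length(z)
  if (n < 1L) stop("need at least one z value")
  if (all(z == z[1L])) return(rep(1, n))
  if (method == "local_fdr" && n < 200L) {
    warning("local_fdr needs >= 200 z values; falling back to BH")
    method <- "bh"
  }
  if (method == "bh") {
    p <- 2 * stats::pnorm(-abs(z))
    return(stats::p.adjust(p, method = "BH"))
  }
  qs <- stats::quantile(z, c(0.25, 0.75), names = FALSE, type = 7)
  sigma <- (qs[2L] - qs[1L]) / (2 * stats::qnorm(0.75))
  if (!is.finite(sigma) || sigma <= 0) return(rep(1, n))
  p0_mass <- 2 * stats::pnorm(1) - 1  # null mass within one sigma
  pi0 <- min(1, mean(abs(z) <= sigma) / p0_mass)
  dens <- stats::density(z, n = 1024L)
  f <- stats::approx(dens$x, dens$y, xout = z, rule = 2)$y
  f <- pmax(f, 1e-12)
  pmin(1, pi0 * stats::dnorm(z, 0, sigma) / f)
}

# Index pairs (i < j) of an N-gene module, K = N(N-1)/2 rows, in the same
# column-major order that upper.tri() extraction uses for the correlation
# vectors.
module_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# Condition-specific pair correlations on the log2(x+1) scale for one module
# and one column subset. Returns list(rN, rT, degenerate).
pair_correlations <- function(lg, genes, cols_n, cols_t) {
  sub_n <- t(lg[genes, cols_n, drop = FALSE])
  sub_t <- t(lg[genes, cols_t, drop = FALSE])
  suppressWarnings({
    cn <- stats::cor(sub_n)
    ct <- stats::cor(sub_t)
  })
  ut <- upper.tri(cn)
  rN <- cn[ut]; rT <- ct[ut]
  degenerate <- !is.finite(rN) | !is.finite(rT)
  rN[degenerate] <- 0; rT[degenerate] <- 0
  list(rN = rN, rT = rT, degenerate = degenerate)
}

new_module_diffcorr <- function(module_name, genes, pairs, full, z_full,
                                fdr_full, sc_counts, S, delta, upsilon) {
  sc_fraction <- sc_counts / S
  out <- list(module_name = module_name,
              genes = genes,
              pairs = data.frame(gene_a = genes[pairs[, 1L]],
                                 gene_b = genes[pairs[, 2L]],
                                 stringsAsFactors = FALSE),
              r_normal = full$rN,
              r_tumor = full$rT,
              z_stat = z_full,
              fdr = fdr_full,
              sc_full = as.integer(fdr_full <= upsilon & !full$degenerate),
              sc_fraction = sc_fraction,
              dee = as.integer(sc_fraction >= delta),
              degenerate = full$degenerate)
  class(out) <- "ModuleDiffCorr"
  out
}

#' @export
print.ModuleDiffCorr <- function(x, ...) {
  cat(sprintf("ModuleDiffCorr '%s': %d genes, %d pairs, %d consensus DEE\n",
              x$module_name, length(x$genes), nrow(x$pairs), sum(x$dee)))
  invisible(x)
}

#' Consensus differential correlation for one module
#'
#' Per round: a stratified column subsample is drawn, all within-module pair
#' correlations are computed per condition on log2(x+1), converted to Fisher
#' z-test statistics, assigned an fdr, and thresholded at `upsilon` into the
#' indicator Sc. After `S` rounds a pair is a consensus differential
#' correlation (DEE) when its Sc vote fraction reaches `delta`. Full-data
#' correlations, z statistics and fdr are recorded alongside.
#'
#' Zero-variance (degenerate) pairs get z = 0, fdr = 1 and never vote.
#'
#' @param expr an [expression_data()] object.
#' @param module character vector of gene ids (>= 2 present in `expr`).
#' @param params a [corr_params()] object.
#' @param module_name label stored in the result.
#' @return Object of class `ModuleDiffCorr`.
#' @export
consensus_diffcorr <- function(expr, module, params = corr_params(),
                               module_name = "module") {
  res <- consensus_diffcorr_all(expr,
                                module_set(stats::setNames(list(module),
                                                           module_name)),
                                params, verbose = FALSE)
  res[[module_name]]
}

#' Consensus differential correlation across a module collection
#'
#' Shares one subsample stream across all modules per round. For the
#' local-fdr method, modules with at least 200 pairs get their own
#' empirical-null fit; smaller modules are pooled into one joint fit per
#' round so the null distribution is estimated from enough values.
#'
#' @param expr an [expression_data()] object.
#' @param ms a [module_set()] (already intersected with the expression
#'   universe; every module must have >= 2 expressed genes).
#' @param params a [corr_params()] object.
#' @param verbose print progress.
#' @return Named list of `ModuleDiffCorr` objects, one per module.
#' @export
consensus_diffcorr_all <- function(expr, ms, params = corr_params(),
                                   verbose = FALSE) {
  stopifnot(inherits(expr, "ExpressionData"), inherits(ms, "ModuleSet"),
            inherits(params, "CorrParams"))
  mods <- lapply(ms$modules, function(g) {
    g <- g[g %in% expr$genes]
    if (length(g) < 2L)
      stop("module with < 2 expressed genes; run intersect_modules() first")
    g
  })
  lg <- log2(expr$values + 1)
  idx_n <- which(expr$condition == "normal")
  idx_t <- which(expr$condition == "tumor")
  k_n <- round(params$subsample_fraction * length(idx_n))
  k_t <- round(params$subsample_fraction * length(idx_t))
  if (k_n < 4L || k_t < 4L)
    stop("subsample_fraction leaves fewer than 4 samples in a condition")

  pairs <- lapply(mods, function(g) module_pairs(length(g)))
  kcount <- vapply(pairs, nrow, integer(1))
  pooled <- params$fdr_method == "local_fdr" & kcount < 200L
  sc_counts <- lapply(kcount, numeric)

  # one pass: compute z for every module on the given columns, then fdr with
  # the pooling rule, returning per-module Sc indicator vectors
  round_sc <- function(cols_n, cols_t) {
    L <- length(cols_n); Q <- length(cols_t)
    zs <- vector("list", length(mods))
    degs <- vector("list", length(mods))
    for (m in seq_along(mods)) {
      pc <- pair_correlations(lg, mods[[m]], cols_n, cols_t)
      z <- diffcorr_z(pc$rN, pc$rT, L, Q)
      z[pc$degenerate] <- 0
      zs[[m]] <- z
      degs[[m]] <- pc$degenerate
    }
    fdrs <- vector("list", length(mods))
    if (any(pooled)) {
      pool_z <- unlist(zs[pooled], use.names = FALSE)
      pool_fdr <- suppressWarnings(pair_fdr(pool_z, params$fdr_method))
      at <- 0L
      for (m in which(pooled)) {
        fdrs[[m]] <- pool_fdr[at + seq_len(kcount[m])]
        at <- at + kcount[m]
      }
    }
    for (m in which(!pooled))
      fdrs[[m]] <- pair_fdr(zs[[m]], params$fdr_method)
    lapply(seq_along(mods), function(m)
      as.integer(fdrs[[m]] <= params$upsilon & !degs[[m]]))
  }

  with_seed(params$rng_seed, {
    for (s in seq_len(params$S)) {
      cols_n <- idx_n[sample(length(idx_n), k_n)]
      cols_t <- idx_t[sample(length(idx_t), k_t)]
      sc <- round_sc(cols_n, cols_t)
      for (m in seq_along(mods)) sc_counts[[m]] <- sc_counts[[m]] + sc[[m]]
      if (verbose && s %% 50L == 0L)
        message(sprintf("  diffcorr round %d/%d", s, params$S))
    }
  })

  # full-data pass for the recorded statistics
  full_by_mod <- lapply(mods, pair_correlations, lg = lg,
                        cols_n = idx_n, cols_t = idx_t)
  z_full <- lapply(full_by_mod, function(pc) {
    z <- diffcorr_z(pc$rN, pc$rT, length(idx_n), length(idx_t))
    z[pc$degenerate] <- 0
    z
  })
  fdr_full <- vector("list", length(mods))
  if (any(pooled)) {
    pool_fdr <- suppressWarnings(
      pair_fdr(unlist(z_full[pooled], use.names = FALSE), params$fdr_method))
    at <- 0L
    for (m in which(pooled)) {
      fdr_full[[m]] <- pool_fdr[at + seq_len(kcount[m])]
      at <- at + kcount[m]
    }
  }
  for (m in which(!pooled))
    fdr_full[[m]] <- pair_fdr(z_full[[m]], params$fdr_method)
  for (m in seq_along(mods)) fdr_full[[m]][full_by_mod[[m]]$degenerate] <- 1

  out <- lapply(seq_along(mods), function(m)
    new_module_diffcorr(names(mods)[m], mods[[m]], pairs[[m]],
                        full_by_mod[[m]], z_full[[m]], fdr_full[[m]],
                        sc_counts[[m]], params$S, params$delta,
                        params$upsilon))
  stats::setNames(out, names(mods))
}
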