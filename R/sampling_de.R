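#' Parameters for consensus differential-expression calling
#'
#' @param S number of random subsampling rounds (default 1000).
#' @param omega vote threshold in (0,1]: a gene is a consensus DEG when it is
#'   called significant in at least this fraction of rounds (default 0.9).
#' @param mu adjusted p-value threshold for the per-round call (default 0.01).
#' @param subsample_fraction fraction of each condition's samples drawn
#'   (without replacement) per round, in (0,1] (default 0.8).
#' @param rng_seed integer seed controlling the subsample draws.
#' @return Object of class `DeParams`.
#' @export
de_params <- function(S = 1000L, omega = 0.9, mu = 0.01,
                      subsample_fraction = 0.8, rng_seed = 1L) {
  stopifnot(S >= 1L, omega > 0, omega <= 1, mu > 0, mu < 1,
            subsample_fraction > 0, subsample_fraction <= 1)
  out <- list(S = as.integer(S), omega = omega, mu = mu,
              subsample_fraction = subsample_fraction,
              rng_seed = as.integer(rng_seed))
  class(out) <- "DeParams"
  out
}

# Vectorized two-sided Welch t-test on log2(x + 1), BH-adjusted across genes.
# Genes with zero variance in both groups (zero standard error) get p = 1.
welch_padj <- function(values, condition) {
  lg <- log2(values + 1)
  a <- lg[, condition == "normal", drop = FALSE]
  b <- lg[, condition == "tumor", drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  degenerate <- se2 == 0
  p <- 2 * stats::pt(-abs(stat), df)
  p[!is.finite(p)] <- 1
  out <- stats::setNames(stats::p.adjust(p, method = "BH"), rownames(values))
  attr(out, "degenerate") <- unname(degenerate)
  out
}

#' One differential-expression round on a sample subset
#'
#' Runs the built-in per-round test (two-sided Welch t on log2(x+1) with
#' Benjamini-Hochberg adjustment across genes) on the given samples and
#' thresholds the adjusted p-values at `mu`.
#'
#' @param expr an [expression_data()] object.
#' @param sample_subset character vector of sample ids (>= 4 per condition).
#' @param mu adjusted p-value threshold.
#' @return Named integer vector over all genes: 1 when adjusted p <= `mu`,
#'   else 0. Degenerate genes (zero variance in both groups) get 0.
#' @export
de_test_once <- function(expr, sample_subset, mu) {
  stopifnot(inherits(expr, "ExpressionData"))
  sample_subset <- as.character(sample_subset)
  if (!all(sample_subset %in% expr$samples))
    stop("unknown sample id(s) in subset")
  cond <- expr$condition[sample_subset]
  if (sum(cond == "normal") < 4L || sum(cond == "tumor") < 4L)
    stop("subset must contain >= 4 samples of each condition")
  padj <- welch_padj(expr$values[, sample_subset, drop = FALSE], cond)
  # degenerate genes have no usable test statistic and never vote
  stats::setNames(as.integer(padj <= mu & !attr(padj, "degenerate")),
                  names(padj))
}

#' Consensus differential-expression calling by repeated subsampling
#'
#' Each of `S` rounds draws a stratified random subsample (without
#' replacement, the same fraction of each condition), runs the per-round DE
#' test, and records which genes pass the `mu` threshold. A gene is a
#' consensus DEG when its vote fraction reaches `omega`. The full-data
#' adjusted p-value, reused by the gene-importance score, is computed once on
#' all samples. A precomputed adjusted-p table (e.g. exported from an
#' external DE tool) can replace the built-in full-data test.
#'
#' @param expr an [expression_data()] object.
#' @param params a [de_params()] object.
#' @param padj_table optional named numeric vector of precomputed full-data
#'   adjusted p-values (gene -> padj); genes missing from it fall back to the
#'   built-in test's value.
#' @return Object of class `DeResult`: list with `padj`, `vote_fraction`,
#'   `deg` (0/1), and `params`.
#' @export
consensus_de <- function(expr, params = de_params(), padj_table = NULL) {
  stopifnot(inherits(expr, "ExpressionData"), inherits(params, "DeParams"))
  idx_n <- which(expr$condition == "normal")
  idx_t <- which(expr$condition == "tumor")
  k_n <- round(params$subsample_fraction * length(idx_n))
  k_t <- round(params$subsample_fraction * length(idx_t))
  if (k_n < 4L || k_t < 4L)
    stop("subsample_fraction leaves fewer than 4 samples in a condition")

  padj <- welch_padj(expr$values, expr$condition)
  if (!is.null(padj_table)) {
    hit <- intersect(names(padj_table), names(padj))
    padj[hit] <- padj_table[hit]
  }

  votes <- stats::setNames(numeric(length(expr$genes)), expr$genes)
  with_seed(params$rng_seed, {
    for (s in seq_len(params$S)) {
      sub <- c(sample(idx_n, k_n), sample(idx_t, k_t))
      se <- tryCatch(
        de_test_once(expr, expr$samples[sub], params$mu),
        error = function(e) {
          warning(sprintf("round %d failed (%s); counted as all-zero votes",
                          s, conditionMessage(e)))
          stats::setNames(integer(length(expr$genes)), expr$genes)
        })
      votes <- votes + se[names(votes)]
    }
  })
  vote_fraction <- votes / params$S
  out <- list(padj = padj,
              vote_fraction = vote_fraction,
              deg = stats::setNames(as.integer(vote_fraction >= params$omega),
                                    names(vote_fraction)),
              params = params)
  class(out) <- "DeResult"
  out
}

#' @export
print.DeResult <- function(x, ...) {
  cat(sprintf("DeResult: %d genes, %d consensus DEGs (S=%d, omega=%.2f, mu=%g)\n",
              length(x$deg), sum(x$deg), x$params$S, x$params$omega,
              x$params$mu))
  invisible(x)
}

#' Read a precomputed per-gene adjusted p-value table
#'
#' Two-column TSV `gene TAB padj` (optional header), for plugging externally
#' computed differential-expression results into [consensus_de()].
#'
#' @param path TSV path.
#' @return Named numeric vector of adjusted p-values.
#' @export
read_padj_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("padj table needs two columns: gene, padj")
  if (is.na(suppressWarnings(as.numeric(tab[1L, 2L]))))
    tab <- tab[-1L, , drop = FALSE]
  p <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(p)) stop("non-numeric padj value(s)")
  if (any(p < 0 | p > 1)) stop("padj values must lie in [0, 1]")
  stats::setNames(p, trimws(as.character(tab[[1L]])))
}

# Run `code` under a temporary, restorable RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive per-stage seeds from one master seed; keeps every derived seed a
# valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offs <- c(fixture = 11L, de = 101L, corr = 211L, fusion = 307L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 1103L + offs[[stage]]) %% 2147483647)
}
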