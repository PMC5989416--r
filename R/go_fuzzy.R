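#' Term probabilities (information-content denominator) over a corpus
#'
#' For every ontology term, the probability is the number of annotation
#' records whose term is that term or any of its descendants, divided by the
#' total number of annotation records in the loaded corpus. Descendant
#' counting makes the probability monotone non-increasing down the DAG.
#' Terms never observed, even through their descendants, have no defined
#' probability and are omitted.
#'
#' @param go a [read_go()] object.
#' @return Object of class `TermProbabilityTable`: list with `p` (named
#'   numeric in (0, 1\]) and `corpus_size` (total annotation records).
#' @export
term_probability <- function(go) {
  stopifnot(inherits(go, "GoKnowledge"))
  records <- unlist(go$annotations, use.names = FALSE)
  total <- length(records)
  if (total == 0L) stop("annotation corpus is empty")
  counts <- table(records)
  direct <- stats::setNames(numeric(length(go$terms)), go$terms)
  direct[names(counts)] <- as.numeric(counts)
  p <- vapply(go$terms, function(t)
    (direct[[t]] + sum(direct[go$descendants[[t]]])) / total, numeric(1))
  p <- p[p > 0]
  out <- list(p = p, corpus_size = total)
  class(out) <- "TermProbabilityTable"
  out
}

#' Fuzzy densities of one gene's GO terms
#'
#' Each term's density is its normalized information content,
#' `(-ln p(T_k)) / max_j (-ln p(T_j))` over the gene's terms, so the most
#' specific (lowest-probability) term gets density 1 and terms with
#' probability 1 get density 0. Terms without a defined probability are
#' dropped with a warning.
#'
#' @param terms character vector of term ids.
#' @param probs a [term_probability()] table.
#' @return Object of class `FuzzyDensitySet`: list with `terms`, `density`
#'   (named numeric in \[0, 1\]), `lambda` (solved on construction), and
#'   `all_zero` (TRUE when every usable term has probability 1, in which case
#'   similarities fall back to 0).
#' @export
fuzzy_density <- function(terms, probs) {
  stopifnot(inherits(probs, "TermProbabilityTable"))
  terms <- unique(as.character(terms))
  usable <- terms %in% names(probs$p)
  if (any(!usable)) {
    warning(sprintf("%d term(s) without a defined probability dropped",
                    sum(!usable)))
    terms <- terms[usable]
  }
  if (!length(terms)) {
    out <- list(terms = character(0), density = numeric(0), lambda = 0,
                all_zero = TRUE)
    class(out) <- "FuzzyDensitySet"
    return(out)
  }
  ic <- -log(probs$p[terms])
  mx <- max(ic)
  dens <- if (mx > 0) ic / mx else ic * 0
  out <- list(terms = terms,
              density = stats::setNames(unname(dens), terms),
              lambda = solve_lambda(dens),
              all_zero = mx <= 0)
  class(out) <- "FuzzyDensitySet"
  out
}

#' Solve the Sugeno lambda-measure normalization equation
#'
#' Finds the root of `(1 + lambda) = prod(1 + lambda * d_k)` in
#' `(-1, Inf)`. When the densities sum to 1 the additive measure is already
#' normalized and lambda is exactly 0; a sum above 1 gives the unique
#' negative root in (-1, 0), a sum below 1 the unique positive root. Root
#' finding works on the log form `sum(log1p(lambda*d)) - log1p(lambda)`,
#' which is well conditioned for large positive lambda, followed by a short
#' Newton polish.
#'
#' Degenerate inputs: fewer than two positive densities leave lambda
#' undefined by the equation and return 0 (flagged via the `degenerate`
#' attribute). Densities at or above 1 are clamped to `1 - 1e-9`; a density
#' of exactly 1 forces the measure into its lambda -> -1 limit.
#'
#' @param densities numeric vector in \[0, 1\].
#' @return The solved lambda (plain numeric; attribute `degenerate = TRUE`
#'   on the fallback paths).
#' @export
solve_lambda <- function(densities) {
  d <- as.numeric(densities)
  if (any(d < 0 | d > 1 + 1e-12)) stop("densities must lie in [0, 1]")
  d <- d[d > 0]
  if (length(d) < 2L) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d <- pmin(d, 1 - 1e-9)
  s <- sum(d)
  if (abs(s - 1) < 1e-12) return(0)

  h <- function(l) sum(log1p(l * d)) - log1p(l)
  hp <- function(l) sum(d / (1 + l * d)) - 1 / (1 + l)

  if (s < 1) {
    lo <- 1e-13
    hi <- 1
    while (h(hi) <= 0 && hi < 1e12) hi <- hi * 4
    if (h(hi) <= 0) { # numerically no positive root reachable
      out <- 0; attr(out, "degenerate") <- TRUE; return(out)
    }
  } else {
    lo <- -1 + 1e-14
    hi <- -1e-13
    if (h(lo) <= 0) { # extreme density mass near 1: lambda -> -1 limit
      out <- lo; attr(out, "degenerate") <- TRUE; return(out)
    }
  }
  root <- stats::uniroot(h, lower = lo, upper = hi, tol = 1e-14,
                         maxiter = 1000L)$root
  for (k in 1:4) { # Newton polish on the log form
    step <- h(root) / hp(root)
    if (!is.finite(step)) break
    cand <- root - step
    if (cand <= -1 || (s < 1 && cand <= 0) || (s > 1 && cand >= 0)) break
    root <- cand
    if (abs(step) < abs(root) * 1e-16) break
  }
  root
}

#' Evaluate a Sugeno lambda-measure on a term subset
#'
#' `Sm(A) = (prod_{k in A}(1 + lambda * d_k) - 1) / lambda` for lambda != 0
#' and the capped sum `min(1, sum d_k)` for lambda = 0; the empty set
#' measures 0 and the full term set 1 (clamped). The measure is monotone
#' under subset inclusion.
#'
#' @param subset character vector of term ids, a subset of the density set's
#'   terms.
#' @param fds a [fuzzy_density()] object.
#' @return Measure value in \[0, 1\].
#' @export
sugeno_measure <- function(subset, fds) {
  stopifnot(inherits(fds, "FuzzyDensitySet"))
  subset <- unique(as.character(subset))
  if (!length(subset)) return(0)
  if (!all(subset %in% fds$terms))
    stop("subset contains term(s) outside the density set")
  d <- fds$density[subset]
  l <- as.numeric(fds$lambda)
  v <- if (abs(l) < 1e-12) sum(d) else (prod(1 + l * d) - 1) / l
  min(1, max(0, v))
}

#' Fuzzy-measure similarity between two genes' GO term sets
#'
#' Builds each gene's fuzzy density set, evaluates each gene's own Sugeno
#' measure on the shared term intersection, and averages the two values.
#' Symmetric; identical term sets give 1, disjoint sets give 0. A gene with
#' no usable term (all probabilities 1 or undefined) yields similarity 0.
#'
#' @param terms_a,terms_b character vectors of term ids.
#' @param probs a [term_probability()] table.
#' @return Similarity in \[0, 1\].
#' @export
fms_similarity <- function(terms_a, terms_b, probs) {
  fa <- if (inherits(terms_a, "FuzzyDensitySet")) terms_a
        else fuzzy_density(terms_a, probs)
  fb <- if (inherits(terms_b, "FuzzyDensitySet")) terms_b
        else fuzzy_density(terms_b, probs)
  if (fa$all_zero || fb$all_zero || !length(fa$terms) || !length(fb$terms))
    return(0)
  shared <- intersect(fa$terms, fb$terms)
  (sugeno_measure(shared, fa) + sugeno_measure(shared, fb)) / 2
}

#' Basic importance of a module gene from GO similarity to seed genes
#'
#' Returns 0 when the module contains no known disease (seed) genes, 1 when
#' the gene is itself a seed, and otherwise the mean fuzzy-measure similarity
#' between the gene and every seed gene in the module. A gene or seed without
#' usable GO annotation contributes similarity 0.
#'
#' @param gene gene id (must belong to `module`).
#' @param module character vector of module gene ids.
#' @param seeds character vector of known disease gene ids.
#' @param go a [read_go()] object.
#' @param probs optional precomputed [term_probability()] table.
#' @param cache optional environment memoizing per-gene density sets.
#' @return Importance value in \[0, 1\].
#' @export
gene_basic_importance <- function(gene, module, seeds, go, probs = NULL,
                                  cache = NULL) {
  stopifnot(inherits(go, "GoKnowledge"))
  if (!gene %in% module) stop("gene is not a member of the module")
  mod_seeds <- intersect(module, seeds)
  if (!length(mod_seeds)) return(0)
  if (gene %in% seeds) return(1)
  if (is.null(probs)) probs <- term_probability(go)
  fds_of <- function(g) {
    if (!is.null(cache) && !is.null(cache[[g]])) return(cache[[g]])
    f <- suppressWarnings(fuzzy_density(go$annotations[[g]], probs))
    if (!is.null(cache)) cache[[g]] <- f
    f
  }
  fg <- fds_of(gene)
  sims <- vapply(mod_seeds, function(d) fms_similarity(fg, fds_of(d), probs),
                 numeric(1))
  mean(sims)
}
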