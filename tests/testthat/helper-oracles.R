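# Independent oracles kept deliberately separate from the package's own code
# paths.

# Brute-force DAG reachability via igraph (descendants of every term).
oracle_descendants <- function(go) {
  edges <- do.call(rbind, lapply(names(go$parents), function(t) {
    p <- go$parents[[t]]
    if (length(p)) cbind(child = t, parent = p) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, "parent"], to = edges[, "child"]),
    vertices = go$terms)
  out <- lapply(go$terms, function(t) {
    r <- names(igraph::subcomponent(g, t, mode = "out"))
    setdiff(r, t)
  })
  stats::setNames(out, go$terms)
}

# Straight-line (non-recursive bookkeeping) re-implementation of the
# expectation-driven fusion rule, written against the definition rather than
# the package's data structures. Ties: larger prob, larger raw importance,
# earlier module position.
oracle_fuse <- function(genes_of, probs, p_module = probs) {
  mods <- names(genes_of)
  placed <- character(0)
  m <- stats::setNames(rep(0, length(mods)), mods)
  pos <- stats::setNames(rep(1, length(mods)), mods)
  total <- length(unique(unlist(genes_of)))
  out <- character(0)
  while (length(out) < total) {
    # skip genes already placed, counting them into m
    for (j in mods) {
      while (pos[j] <= length(genes_of[[j]]) &&
             genes_of[[j]][pos[j]] %in% placed) {
        pos[j] <- pos[j] + 1
        m[j] <- m[j] + 1
      }
    }
    avail <- mods[vapply(mods, function(j) pos[j] <= length(genes_of[[j]]),
                         logical(1))]
    cand <- avail[probs[avail] > 0]
    if (!length(cand)) cand <- avail[1]
    i <- length(out)
    best <- NULL
    best_key <- NULL
    for (j in cand) {
      key <- c((i + 1) * probs[[j]] - m[[j]], probs[[j]], p_module[[j]],
               -match(j, mods))
      if (is.null(best) || lex_gt(key, best_key)) {
        best <- j
        best_key <- key
      }
    }
    g <- genes_of[[best]][pos[best]]
    out <- c(out, g)
    placed <- c(placed, g)
    pos[best] <- pos[best] + 1
    m[best] <- m[best] + 1
  }
  out
}

lex_gt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}

# Random fusion instance: module gene lists (possibly overlapping) plus
# normalized probabilities.
random_fusion_instance <- function(max_modules = 20, max_genes = 50,
                                   overlap = TRUE) {
  nmod <- sample(1:max_modules, 1)
  universe <- sprintf("x%03d", seq_len(max_genes))
  genes_of <- lapply(seq_len(nmod), function(j) {
    n <- sample(1:max(1, max_genes %/% 2), 1)
    sample(universe, n)
  })
  if (!overlap) {
    pool <- sample(universe)
    genes_of <- list()
    at <- 1
    for (j in seq_len(nmod)) {
      n <- sample(1:5, 1)
      if (at + n - 1 > length(pool)) break
      genes_of[[j]] <- pool[at:(at + n - 1)]
      at <- at + n
    }
    if (!length(genes_of)) genes_of <- list(pool[1])
    nmod <- length(genes_of)
  }
  names(genes_of) <- sprintf("m%02d", seq_len(nmod))
  w <- runif(nmod)
  if (runif(1) < 0.2) w[sample(nmod, 1)] <- 0  # occasional zero-importance
  probs <- if (sum(w) > 0) w / sum(w) else rep(1 / nmod, nmod)
  names(probs) <- names(genes_of)
  list(genes_of = genes_of, probs = probs)
}
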