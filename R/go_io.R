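#' Read GO annotations and the term hierarchy
#'
#' Parses gene -> term annotations (GAF 2.x or a two-column `gene TAB term`
#' TSV) together with an OBO 1.2/1.4 ontology restricted to `is_a` edges, and
#' precomputes the transitive descendant closure used by term-probability
#' (information content) calculations. Obsolete terms are dropped and
#' annotations to terms absent from the ontology are quarantined; both emit
#' warnings rather than failing.
#'
#' @param annotations_path GAF 2.x file (detected via the `!gaf-version`
#'   header or >= 15 tab-separated columns) or a two-column TSV.
#' @param obo_path OBO ontology file; only `is_a` relations are used.
#' @return Object of class `GoKnowledge`: list with `annotations` (gene ->
#'   character vector of term ids), `parents`, `children`, `descendants`
#'   (named lists over term ids), and `terms`.
#' @export
read_go <- function(annotations_path, obo_path) {
  dag <- parse_obo(obo_path)
  ann <- parse_annotations(annotations_path)

  known <- ann$term %in% dag$terms
  if (any(!known)) {
    bad <- unique(ann$term[!known])
    warning(sprintf("%d annotation(s) to %d term(s) absent from the ontology were quarantined (e.g. %s)",
                    sum(!known), length(bad), bad[1L]))
    ann <- ann[known, , drop = FALSE]
  }
  if (!nrow(ann)) stop("no usable annotations remain after filtering")

  annotations <- split(ann$term, ann$gene)
  annotations <- lapply(annotations, unique)

  out <- list(annotations = annotations,
              parents = dag$parents,
              children = dag$children,
              descendants = descendant_closure(dag$children, dag$terms),
              terms = dag$terms)
  class(out) <- "GoKnowledge"
  out
}

#' @export
print.GoKnowledge <- function(x, ...) {
  cat(sprintf("GoKnowledge: %d terms, %d annotated genes, %d annotation records\n",
              length(x$terms), length(x$annotations),
              sum(lengths(x$annotations))))
  invisible(x)
}

# Minimal OBO parser: [Term] stanzas with id:, is_a: (target before any '!'
# comment) and is_obsolete:. part_of and other relationship: lines are
# deliberately ignored.
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_ids <- character(0)
  parents <- list()
  in_term <- FALSE
  cur_id <- NA_character_
  cur_parents <- character(0)
  cur_obsolete <- FALSE
  n_obsolete <- 0L

  flush <- function() {
    if (!is.na(cur_id)) {
      if (cur_obsolete) {
        n_obsolete <<- n_obsolete + 1L
      } else {
        term_ids <<- c(term_ids, cur_id)
        parents[[cur_id]] <<- unique(cur_parents)
      }
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_; cur_parents <- character(0); cur_obsolete <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur_id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      if (nzchar(tgt)) cur_parents <- c(cur_parents, tgt)
    } else if (startsWith(ln, "is_obsolete:")) {
      cur_obsolete <- isTRUE(grepl("true", ln, fixed = TRUE))
    }
  }
  flush()
  if (n_obsolete > 0L)
    warning(sprintf("dropped %d obsolete term(s)", n_obsolete))
  if (anyDuplicated(term_ids)) stop("duplicate term id(s) in OBO file")
  # drop is_a edges pointing at obsolete/unknown targets
  parents <- lapply(parents, function(p) p[p %in% term_ids])

  children <- stats::setNames(vector("list", length(term_ids)), term_ids)
  for (t in term_ids)
    for (p in parents[[t]])
      children[[p]] <- c(children[[p]], t)

  assert_acyclic(parents, term_ids)
  list(terms = term_ids, parents = parents, children = children)
}

# Kahn's algorithm over is_a edges (child -> parent).
assert_acyclic <- function(parents, terms) {
  indeg <- stats::setNames(integer(length(terms)), terms)  # number of parents left
  for (t in terms) indeg[t] <- length(parents[[t]])
  rev_children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms)
    for (p in parents[[t]])
      rev_children[[p]] <- c(rev_children[[p]], t)
  queue <- terms[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (c in rev_children[[t]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen != length(terms)) stop("cyclic is_a graph in ontology")
  invisible(TRUE)
}

# Transitive closure of the child relation, memoized over a reverse
# topological order; each descendant is counted once even when reachable by
# several paths (diamonds).
descendant_closure <- function(children, terms) {
  desc <- stats::setNames(vector("list", length(terms)), terms)
  done <- stats::setNames(logical(length(terms)), terms)
  visit <- function(t) {
    if (done[[t]]) return(desc[[t]])
    # iterative DFS to avoid deep recursion on long chains
    stack <- t
    while (length(stack)) {
      top <- stack[[length(stack)]]
      kids <- as.character(children[[top]])
      pending <- kids[!done[kids]]
      if (length(pending)) {
        stack <- c(stack, pending[1L])
      } else {
        acc <- kids
        for (k in kids) acc <- c(acc, desc[[k]])
        desc[[top]] <<- unique(acc)
        done[[top]] <<- TRUE
        stack <- stack[-length(stack)]
      }
    }
    desc[[t]]
  }
  for (t in terms) visit(t)
  desc
}

parse_annotations <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  is_gaf <- any(startsWith(first, "!gaf-version")) ||
    any(lengths(strsplit(first[!startsWith(first, "!")], "\t", fixed = TRUE)) >= 15L)
  if (is_gaf) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(f) < 5L
    if (any(short)) stop("malformed GAF line(s): fewer than 5 columns")
    ann <- data.frame(gene = trimws(vapply(f, `[[`, character(1), 3L)),
                      term = trimws(vapply(f, `[[`, character(1), 5L)),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 2L) stop("annotation TSV needs two columns: gene, term")
    ann <- data.frame(gene = trimws(as.character(tab[[1L]])),
                      term = trimws(as.character(tab[[2L]])),
                      stringsAsFactors = FALSE)
    # tolerate a header line
    if (nrow(ann) && grepl("^(gene|symbol)$", tolower(ann$gene[1L])))
      ann <- ann[-1L, , drop = FALSE]
  }
  ann[nzchar(ann$gene) & nzchar(ann$term), , drop = FALSE]
}
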