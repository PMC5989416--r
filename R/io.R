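#' Construct an ExpressionData object
#'
#' Validated container for a genes x samples expression matrix with a
#' per-sample condition label. The downstream Fisher z-test needs more than
#' three samples per condition, so at least four normal and four tumor
#' samples are required.
#'
#' @param values numeric matrix (genes x samples) of non-negative values,
#'   with rownames (gene ids) and colnames (sample ids).
#' @param condition named character vector mapping every sample id to
#'   `"normal"` or `"tumor"`.
#' @return An object of class `ExpressionData`: a list with elements
#'   `values`, `genes`, `samples`, `condition`, and the counts `L` (normal)
#'   and `Q` (tumor). Genes whose row is all zero are flagged in the
#'   `zero_genes` attribute but retained.
#' @export
expression_data <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must have rownames (genes) and colnames (samples)")
  genes <- trimws(genes)
  samples <- trimws(samples)
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (any(values < 0))
    stop("expression matrix contains negative values")
  condition <- condition[samples]
  if (anyNA(condition))
    stop("condition missing for sample(s): ",
         paste(samples[is.na(condition)], collapse = ", "))
  if (!all(condition %in% c("normal", "tumor")))
    stop("conditions must be 'normal' or 'tumor'")
  L <- sum(condition == "normal")
  Q <- sum(condition == "tumor")
  if (L < 4L || Q < 4L)
    stop(sprintf("need at least 4 samples per condition (normal=%d, tumor=%d)",
                 L, Q))
  rownames(values) <- genes
  colnames(values) <- samples
  out <- list(values = values, genes = genes, samples = samples,
              condition = stats::setNames(unname(condition), samples),
              L = L, Q = Q)
  attr(out, "zero_genes") <- genes[rowSums(values) == 0]
  class(out) <- "ExpressionData"
  out
}

#' @export
print.ExpressionData <- function(x, ...) {
  cat(sprintf("ExpressionData: %d genes x %d samples (%d normal, %d tumor)\n",
              length(x$genes), length(x$samples), x$L, x$Q))
  invisible(x)
}

#' Read an expression matrix and its condition mapping
#'
#' @param matrix_path TSV: header row of sample ids, first column gene ids,
#'   numeric cells.
#' @param conditions_path two-column TSV mapping each sample id to
#'   `normal`/`tumor`; an optional header line is detected and skipped.
#' @return An [expression_data()] object.
#' @export
read_expression <- function(matrix_path, conditions_path) {
  tab <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file needs gene ids plus >= 1 sample")
  genes <- trimws(as.character(tab[[1L]]))
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in ", matrix_path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric expression column(s): ",
         paste(names(vals)[!num], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- genes

  cond_raw <- utils::read.delim(conditions_path, header = FALSE,
                                stringsAsFactors = FALSE)
  if (ncol(cond_raw) < 2L) stop("conditions file must have two columns")
  # tolerate a header line such as "sample\tcondition"
  if (!(tolower(cond_raw[1L, 2L]) %in% c("normal", "tumor")))
    cond_raw <- cond_raw[-1L, , drop = FALSE]
  cond <- stats::setNames(tolower(trimws(cond_raw[[2L]])),
                          trimws(cond_raw[[1L]]))
  unknown <- setdiff(names(cond), colnames(m))
  if (length(unknown))
    stop("conditions file refers to unknown sample(s): ",
         paste(unknown, collapse = ", "))
  expression_data(m, cond)
}

#' Construct a ModuleSet
#'
#' @param modules named list of character vectors (gene ids); file/insertion
#'   order is preserved and duplicates within a module are removed.
#' @return Object of class `ModuleSet` with elements `modules` and `M`.
#' @export
module_set <- function(modules) {
  if (is.null(names(modules)) || any(!nzchar(names(modules))))
    stop("every module must have a non-empty name")
  if (anyDuplicated(names(modules)))
    stop("duplicate module name(s)")
  modules <- lapply(modules, function(g) unique(trimws(as.character(g))))
  out <- list(modules = modules, M = length(modules))
  class(out) <- "ModuleSet"
  out
}

#' @export
print.ModuleSet <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat(sprintf("ModuleSet: %d modules (sizes %d-%d)\n", x$M,
              if (x$M) min(sizes) else 0L, if (x$M) max(sizes) else 0L))
  invisible(x)
}

#' Read gene modules from a GMT file
#'
#' Each line is `name TAB description TAB gene TAB gene ...`. Duplicate genes
#' within a line are dropped with a warning; module and gene order follow the
#' file.
#'
#' @param path GMT file path.
#' @return A [module_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  mods <- list()
  desc <- character(0)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >= 1 gene",
                   k, length(f)))
    nm <- trimws(f[1L])
    if (!nzchar(nm)) stop(sprintf("GMT line %d has an empty module name", k))
    genes <- trimws(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("module '%s': duplicate gene(s) %s removed", nm,
                      paste(unique(genes[duplicated(genes)]), collapse = ", ")))
      genes <- unique(genes)
    }
    mods[[nm]] <- genes
    desc[nm] <- f[2L]
  }
  ms <- module_set(mods)
  attr(ms, "descriptions") <- desc
  ms
}

#' Write a ModuleSet to GMT
#'
#' @param ms a [module_set()].
#' @param path output file.
#' @export
write_gmt <- function(ms, path) {
  stopifnot(inherits(ms, "ModuleSet"))
  desc <- attr(ms, "descriptions")
  lines <- vapply(names(ms$modules), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, ms$modules[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Intersect modules with the expression gene universe
#'
#' Modules are trimmed to genes with expression information; modules that
#' fall below two genes are dropped (pair correlations need at least one
#' pair). The achieved coverage of the module gene universe is reported.
#'
#' @param ms a [module_set()].
#' @param expr an [expression_data()] object (or a character vector of gene
#'   ids).
#' @param verbose emit a coverage message.
#' @return A filtered [module_set()]; attributes `dropped` (names of removed
#'   modules) and `coverage` (fraction of distinct module genes present in
#'   the expression universe).
#' @export
intersect_modules <- function(ms, expr, verbose = TRUE) {
  stopifnot(inherits(ms, "ModuleSet"))
  universe <- if (inherits(expr, "ExpressionData")) expr$genes else as.character(expr)
  all_genes <- unique(unlist(ms$modules, use.names = FALSE))
  coverage <- if (length(all_genes)) mean(all_genes %in% universe) else NA_real_
  trimmed <- lapply(ms$modules, function(g) g[g %in% universe])
  keep <- lengths(trimmed) >= 2L
  dropped <- names(trimmed)[!keep]
  if (verbose) {
    message(sprintf("module gene universe coverage: %d/%d genes (%.1f%%) in expression matrix",
                    sum(all_genes %in% universe), length(all_genes), 100 * coverage))
    if (length(dropped))
      message(sprintf("dropped %d module(s) with < 2 expressed genes", length(dropped)))
  }
  out <- module_set(trimmed[keep])
  attr(out, "descriptions") <- attr(ms, "descriptions")
  attr(out, "dropped") <- dropped
  attr(out, "coverage") <- coverage
  out
}

#' Read a seed (known disease) gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return Character vector of unique gene ids.
#' @export
read_seed_genes <- function(path) {
  g <- trimws(readLines(path, warn = FALSE))
  g <- g[nzchar(g) & !startsWith(g, "#")]
  g <- unique(g)
  if (!length(g)) stop("seed gene list is empty")
  g
}

#' Write a global gene ranking to TSV
#'
#' Columns: rank, gene, module, local_rank, gene_score, module_score.
#' Numeric scores are serialized with 17 significant digits so that
#' [read_ranking()] round-trips losslessly.
#'
#' @param ranking data frame as produced by [fuse_rankings()].
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  validate_ranking(ranking)
  df <- data.frame(
    rank = ranking$rank,
    gene = ranking$gene,
    module = ranking$module,
    local_rank = ranking$local_rank,
    gene_score = sprintf("%.17g", ranking$gene_score),
    module_score = sprintf("%.17g", ranking$module_score),
    stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a global gene ranking written by [write_ranking()]
#'
#' @param path TSV path.
#' @return Validated ranking data frame.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(rank = "integer", gene = "character",
                                         module = "character",
                                         local_rank = "integer",
                                         gene_score = "numeric",
                                         module_score = "numeric"))
  validate_ranking(df)
  df
}

validate_ranking <- function(df) {
  need <- c("rank", "gene", "module", "local_rank", "gene_score", "module_score")
  if (!all(need %in% names(df)))
    stop("ranking is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  n <- nrow(df)
  if (n > 0L) {
    if (!identical(sort(as.integer(df$rank)), seq_len(n)))
      stop("ranks must be 1..n without gaps or duplicates")
    if (anyDuplicated(df$gene))
      stop("each gene must appear exactly once in the ranking")
  }
  invisible(df)
}
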