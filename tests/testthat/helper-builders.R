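# Shared in-code fixtures for unit tests.

# Simple expression object: baseline N(mean, sd) on the log2 scale, optional
# tumor shift for `de_genes` (given as row indices).
make_expr <- function(n_genes = 20, n_normal = 10, n_tumor = 10,
                      de_rows = integer(0), shift = 3, sd = 0.5, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- c(sprintf("n%02d", seq_len(n_normal)),
               sprintf("t%02d", seq_len(n_tumor)))
  cond <- stats::setNames(c(rep("normal", n_normal), rep("tumor", n_tumor)),
                          samples)
  lg <- matrix(rnorm(n_genes * length(samples), mean = 6, sd = sd),
               nrow = n_genes, dimnames = list(genes, samples))
  if (length(de_rows))
    lg[de_rows, cond == "tumor"] <- lg[de_rows, cond == "tumor"] + shift
  expression_data(2^lg, cond)
}

# Write a toy ontology + annotations to temp files and load them.
# `parents`: named list term -> character vector of parents.
# `annotations`: named list gene -> character vector of terms.
make_go <- function(parents, annotations, obsolete = character(0)) {
  obo <- c("format-version: 1.2", "")
  for (t in names(parents)) {
    obo <- c(obo, "[Term]", paste0("id: ", t), paste0("name: ", t))
    for (p in parents[[t]]) obo <- c(obo, paste0("is_a: ", p, " ! parent"))
    if (t %in% obsolete) obo <- c(obo, "is_obsolete: true")
    obo <- c(obo, "")
  }
  obo_path <- tempfile(fileext = ".obo")
  writeLines(obo, obo_path)
  ann_path <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = rep(names(annotations), lengths(annotations)),
                   term = unlist(annotations, use.names = FALSE))
  write.table(df, ann_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  read_go(ann_path, obo_path)
}

# Hand-built term probability table (bypasses corpus counting).
make_probs <- function(p) {
  structure(list(p = p, corpus_size = NA_integer_),
            class = "TermProbabilityTable")
}

write_expr_files <- function(expr_mat, cond, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  mp <- file.path(dir, "expr.tsv")
  cp <- file.path(dir, "cond.tsv")
  df <- cbind(gene = rownames(expr_mat), as.data.frame(expr_mat))
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(cond), condition = unname(cond)),
              cp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, conditions = cp)
}
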