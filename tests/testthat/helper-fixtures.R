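# Small in-code fixtures shared across test files.

# Write an expression TSV (header = sample ids, column 1 = gene) and
# return its path.
write_expr_tsv <- function(mat, path = tempfile(fileext = ".tsv"),
                           gene_col = "gene") {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- gene_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_class_tsv <- function(labels, path = tempfile(fileext = ".tsv")) {
  write.table(data.frame(names(labels), unname(labels)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  path
}

# A labelled expression matrix with the given per-class gene means.
make_expr <- function(case_means, control_means, n_case = 4, n_control = 4,
                      sd = 0, seed = 1) {
  genes <- names(case_means)
  set.seed(seed)
  samples <- c(paste0("c", seq_len(n_case)), paste0("n", seq_len(n_control)))
  vals <- cbind(matrix(rep(case_means, n_case), ncol = n_case),
                matrix(rep(control_means, n_control), ncol = n_control))
  if (sd > 0) vals <- vals + matrix(rnorm(length(vals), 0, sd), nrow(vals))
  dimnames(vals) <- list(genes, samples)
  labels <- setNames(rep(c("case", "control"), c(n_case, n_control)), samples)
  expression_matrix(vals, labels)
}

# igraph from a 2-column matrix of edges.
graph_from_pairs <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(m, directed = FALSE)
}

# The bridged-triangles graph: two triangles joined by a single edge.
bridged_triangles <- function() {
  graph_from_pairs("a", "b", "b", "c", "a", "c",
                   "d", "e", "e", "f", "d", "f",
                   "c", "d")
}
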