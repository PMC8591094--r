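# Seed-based expansion of the interaction network.

#' Expand a protein-protein interaction network around seed genes
#'
#' Builds the induced subgraph of the interaction database on all nodes
#' within `hops` edges of any seed gene (default one hop, the usual
#' reading of expanding a network from seed nodes). Every database edge
#' whose endpoints both fall inside the node set is retained, so
#' neighbor-neighbor edges are kept. Seeds absent from the database are
#' retained as isolated, flagged nodes with a warning; if no seed maps at
#' all, this is an error.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param db_edges Two-column character matrix or data.frame of undirected
#'   interactions (e.g. from [read_edge_list()]).
#' @param hops Expansion depth (0 = induced subgraph on the seeds only).
#' @return An `igraph` object with logical vertex attribute `is_seed`.
#' @export
expand_network <- function(seeds, db_edges, hops = 1) {
  if (!length(seeds)) stopf("seed set is empty")
  if (hops < 0) stopf("hops must be >= 0")
  em <- as.matrix(db_edges)[, 1:2, drop = FALSE]
  db <- igraph::graph_from_edgelist(em, directed = FALSE)
  db <- igraph::simplify(db)
  present <- intersect(seeds, igraph::V(db)$name)
  if (!length(present)) stopf("no seed mapped to the interaction database")
  missing <- setdiff(seeds, present)
  nbhd <- igraph::ego(db, order = hops, nodes = present)
  nodes <- unique(c(present, unlist(lapply(nbhd, function(v) v$name))))
  g <- igraph::induced_subgraph(db, vids = nodes)
  if (length(missing)) {
    warnf("%d seed(s) absent from the interaction database kept as isolated nodes: %s",
          length(missing), paste(missing, collapse = ", "))
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% seeds
  g
}

#' Summary statistics of an interaction graph
#'
#' @param g An `igraph` object (optionally with an `is_seed` vertex
#'   attribute).
#' @return A list with `n_nodes`, `n_edges`, `n_seeds`, `n_components`,
#'   and `degree_table` (a data.frame of nodes ranked by degree, the hub
#'   report).
#' @export
graph_stats <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L)
    return(list(n_nodes = 0L, n_edges = 0L, n_seeds = 0L, n_components = 0L,
                degree_table = data.frame(node = character(0),
                                          degree = integer(0),
                                          is_seed = logical(0))))
  deg <- igraph::degree(g)
  is_seed <- igraph::V(g)$is_seed %||% rep(FALSE, n)
  ord <- order(-deg, igraph::V(g)$name)
  list(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    n_seeds = sum(is_seed),
    n_components = igraph::components(g)$no,
    degree_table = data.frame(node = igraph::V(g)$name[ord],
                              degree = unname(deg[ord]),
                              is_seed = is_seed[ord],
                              row.names = NULL, stringsAsFactors = FALSE))
}

#' Write a graph as SIF plus a node table
#'
#' @param g An `igraph` object.
#' @param path Output SIF path; the node table (symbol, is_seed, degree)
#'   goes to `paste0(path, ".nodes.tsv")`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(0)
  iso <- setdiff(igraph::V(g)$name, unique(as.vector(el)))
  writeLines(c(lines, iso), path)
  st <- graph_stats(g)
  utils::write.table(st$degree_table, paste0(path, ".nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
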