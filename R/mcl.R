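# Markov Cluster Algorithm (MCL), implemented from scratch on dense
# matrices, plus the subnetwork selection rule (>=1 seed gene, >=3 nodes).
#
# MCL simulates flow on the graph: the column-stochastic transition matrix
# is alternately expanded (matrix power, spreading flow) and inflated
# (entry-wise power + column renormalization, strengthening strong flows),
# with small entries pruned, until the matrix stops changing. Clusters are
# read off the nonzero structure of the converged matrix.

#' Markov Cluster Algorithm
#'
#' Clusters an undirected graph by iterated expansion and inflation of its
#' column-stochastic adjacency matrix. Self-loops of weight
#' `self_loop_weight` are added to the diagonal before normalization
#' (damping odd/even flow oscillations). Each iteration applies, in order:
#' expansion (matrix power `expansion`), inflation (entry-wise power
#' `inflation` followed by column renormalization), and pruning (entries
#' below `prune_threshold` zeroed, then renormalization). Iteration stops
#' when the largest absolute entry change falls below `tol`, or after
#' `max_iter` rounds (returning the current clustering with
#' `converged = FALSE` and a warning, never an error).
#'
#' Clusters are the connected components of the graph on nonzero entries of
#' the converged matrix, so every node lands in exactly one cluster.
#' Clusters are ordered by size (descending), ties broken by the
#' lexicographically smallest member.
#'
#' Larger `inflation` yields more, smaller clusters; 2.0 is the
#' conventional default granularity.
#'
#' @param g An `igraph` object (undirected; edge weights are ignored).
#' @param expansion Integer matrix-power exponent, >= 2.
#' @param inflation Entry-wise power, > 1.
#' @param self_loop_weight Weight added to the diagonal, >= 0.
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute entry change.
#' @return An object of class `mcl_result`: list with `clusters` (list of
#'   character vectors, ordered as above), `membership` (named integer
#'   vector, node -> cluster id), `converged`, `n_iter`, `matrix` (the
#'   converged column-stochastic matrix) and `col_dev` (per-iteration
#'   maximum deviation of column sums from 1, recorded after the final
#'   renormalization of each iteration).
#' @export
mcl_cluster <- function(g, expansion = 2L, inflation = 2.0,
                        self_loop_weight = 1.0, prune_threshold = 1e-5,
                        max_iter = 200L, tol = 1e-8) {
  if (igraph::vcount(g) == 0L) stopf("cannot cluster an empty graph")
  if (expansion < 2L) stopf("expansion must be an integer >= 2")
  if (inflation <= 1) stopf("inflation must be > 1")
  if (self_loop_weight < 0 || prune_threshold < 0 || tol <= 0)
    stopf("invalid MCL parameters")
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A[A > 0] <- 1  # unweighted
  dimnames(A) <- list(nodes, nodes)
  diag(A) <- diag(A) + self_loop_weight
  M <- mcl_colnorm(A)
  col_dev <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M_new <- mcl_iterate(M, expansion, inflation, prune_threshold)
    col_dev[iter] <- max(abs(colSums(M_new) - 1))
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("MCL did not converge in %d iterations; returning current clustering",
          max_iter)
  clusters <- mcl_extract_clusters(M)
  membership <- integer(length(nodes))
  names(membership) <- nodes
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  structure(list(clusters = clusters, membership = membership,
                 converged = converged, n_iter = iter,
                 matrix = M, col_dev = col_dev),
            class = "mcl_result")
}

# One MCL round: expand, inflate + renormalize, prune + renormalize.
mcl_iterate <- function(M, expansion, inflation, prune_threshold) {
  E <- M
  for (k in seq_len(expansion - 1L)) E <- E %*% M
  E <- mcl_colnorm(E^inflation)
  E[E < prune_threshold] <- 0
  mcl_colnorm(E)
}

# Column-normalize to stochastic; an all-zero column (fully pruned or an
# isolated node without self-loop) gets unit mass on its diagonal.
mcl_colnorm <- function(M) {
  s <- colSums(M)
  dead <- s == 0
  if (any(dead)) {
    M[cbind(which(dead), which(dead))] <- 1
    s[dead] <- 1
  }
  sweep(M, 2, s, "/")
}

# Connected components of the symmetrized nonzero pattern, ordered by size
# descending then lexicographically smallest member.
mcl_extract_clusters <- function(M) {
  nz <- (M > 0) | (t(M) > 0)
  gg <- igraph::graph_from_adjacency_matrix(nz, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gg)$membership
  clusters <- split(rownames(M), comp)
  clusters <- lapply(clusters, function(v) sort(unname(v)))
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1), 1L))
  unname(clusters[ord])
}

#' @export
print.mcl_result <- function(x, ...) {
  cat(sprintf("MCL clustering: %d clusters over %d nodes (%s in %d iterations)\n",
              length(x$clusters), length(x$membership),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Filter MCL clusters into subnetwork markers
#'
#' Keeps clusters with at least one seed gene and at least `min_nodes`
#' members (the boundary is inclusive: a 3-node cluster with one seed is a
#' marker). Survivors are ordered by size descending, ties broken by the
#' lexicographically smallest member, and assigned ids `1..n` in that
#' order.
#'
#' @param clusters List of character vectors (e.g. `mcl_result$clusters`)
#'   or an `mcl_result`.
#' @param seeds Character vector of seed gene symbols.
#' @param min_nodes Minimum cluster size (default 3).
#' @return List of subnetwork objects: each a list with `id`, `members`,
#'   `seed_members`, and empty `up_set`/`down_set` (filled by
#'   [assign_directions()]).
#' @export
filter_subnetworks <- function(clusters, seeds, min_nodes = 3L) {
  if (inherits(clusters, "mcl_result")) clusters <- clusters$clusters
  keep <- Filter(function(cl) {
    length(cl) >= min_nodes && any(cl %in% seeds)
  }, clusters)
  if (!length(keep))
    stopf("no subnetwork markers: no cluster has >=%d nodes and a seed gene",
          min_nodes)
  ord <- order(-lengths(keep),
               vapply(keep, function(v) sort(v)[1], character(1)))
  keep <- keep[ord]
  lapply(seq_along(keep), function(i) {
    list(id = i, members = sort(keep[[i]]),
         seed_members = sort(intersect(keep[[i]], seeds)),
         up_set = character(0), down_set = character(0))
  })
}
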