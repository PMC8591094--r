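# Gene-set over-representation with the fold-enrichment statistic.

#' Gene-set over-representation analysis
#'
#' For each annotation term, compares the observed number of query genes in
#' the term with the number expected under proportional sampling from the
#' background: `expected = |query| * |term| / |background|`, with fold
#' enrichment `FE = observed / expected` and a one-sided hypergeometric
#' upper-tail p-value `P(X >= observed)`. BH-adjusted p-values are reported
#' alongside the raw ones.
#'
#' @param query Character vector of gene symbols (e.g. all subnetwork
#'   members). Genes outside the background are dropped with a warning.
#' @param sets Named list of character vectors (term -> genes), e.g. from
#'   [read_gmt()].
#' @param background Character vector of background genes; defaults to the
#'   union of all term sets.
#' @return Data frame sorted by p ascending: `term`, `term_size`,
#'   `observed`, `expected`, `fold_enrichment`, `p_value`, `adj_p`.
#' @export
enrich <- function(query, sets, background = NULL) {
  if (!length(sets)) stopf("no annotation sets supplied")
  background <- unique(background %||% unlist(sets, use.names = FALSE))
  if (!length(background)) stopf("background gene set is empty")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warnf("%d query gene(s) outside the background dropped", length(outside))
    query <- setdiff(query, outside)
  }
  if (!length(query)) stopf("no query genes remain within the background")
  N <- length(background)
  n <- length(query)
  res <- lapply(names(sets), function(term) {
    term_genes <- intersect(sets[[term]], background)
    K <- length(term_genes)
    obs <- length(intersect(query, term_genes))
    expected <- n * K / N
    data.frame(term = term, term_size = K, observed = obs,
               expected = expected,
               fold_enrichment = if (obs == 0) 0 else obs / expected,
               p_value = stats::phyper(obs - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
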