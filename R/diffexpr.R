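# Two-group differential expression, BH-FDR, fold-change filtering and
# seed-gene derivation.

#' Per-gene two-group differential expression
#'
#' One-way two-group ANOVA per gene (equivalently the pooled-variance
#' t-test; F = t^2) on a log2-scale expression matrix with case/control
#' labels. The fold change is computed on the log2 scale and reported as a
#' signed linear fold change: `sign(d) * 2^|d|` where
#' `d = mean_case - mean_control`, so `-4` means 4-fold down in cases.
#'
#' Genes with zero pooled within-group variance are handled
#' deterministically rather than dropped: p = 0 if the group means differ,
#' p = 1 otherwise, with a warning.
#'
#' @param expr An [expression_matrix()] with `class_labels` covering at
#'   least 2 samples per class.
#' @return A `data.frame` with one row per gene: `gene`, `mean_case`,
#'   `mean_control`, `signed_fc`, `p_value`, `adj_p` (BH), `direction`
#'   (`up`/`down`, `NA` on an exact tie).
#' @export
differential_expression <- function(expr) {
  if (is.null(expr$class_labels))
    stopf("differential expression needs class labels")
  labs <- expr$class_labels
  x <- expr$values[, names(labs), drop = FALSE]
  case <- names(labs)[labs == "case"]
  ctrl <- names(labs)[labs == "control"]
  n1 <- length(case); n0 <- length(ctrl)
  if (n1 < 2L || n0 < 2L)
    stopf("each class needs >=2 samples (case=%d, control=%d)", n1, n0)
  xc <- x[, case, drop = FALSE]
  x0 <- x[, ctrl, drop = FALSE]
  m1 <- rowMeans(xc); m0 <- rowMeans(x0)
  ss1 <- rowSums((xc - m1)^2)
  ss0 <- rowSums((x0 - m0)^2)
  df <- n1 + n0 - 2L
  sp2 <- (ss1 + ss0) / df
  d <- m1 - m0
  se2 <- sp2 * (1 / n1 + 1 / n0)
  p <- rep(NA_real_, nrow(x))
  ok <- se2 > 0
  fstat <- d[ok]^2 / se2[ok]
  p[ok] <- stats::pf(fstat, 1, df, lower.tail = FALSE)
  if (any(!ok)) {
    warnf("%d gene(s) with zero within-group variance: p set to 0/1 by mean difference",
          sum(!ok))
    p[!ok] <- ifelse(d[!ok] != 0, 0, 1)
  }
  signed_fc <- ifelse(d == 0, 1, sign(d) * 2^abs(d))
  data.frame(
    gene = rownames(x),
    mean_case = m1, mean_control = m0,
    signed_fc = signed_fc,
    p_value = p,
    adj_p = bh_adjust(p),
    direction = ifelse(d > 0, "up", ifelse(d < 0, "down", NA_character_)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper around the standard step-up procedure:
#' `adj_p(i) = min over j with rank(j) >= rank(i) of p(j) * m / rank(j)`,
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stopf("p-values must be numeric")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes
#'
#' Applies the strict dual cutoff: absolute signed fold change strictly
#' greater than `fc_cut` and BH-adjusted p strictly below `q_cut`.
#'
#' @param results Output of [differential_expression()].
#' @param fc_cut Linear fold-change cutoff (default 2).
#' @param q_cut Adjusted-p cutoff (default 0.05).
#' @return Character vector of selected gene symbols, attribute
#'   `source_tag = "DEG"`.
#' @export
select_degs <- function(results, fc_cut = 2, q_cut = 0.05) {
  sel <- abs(results$signed_fc) > fc_cut & results$adj_p < q_cut
  genes <- results$gene[sel]
  if (!length(genes)) warnf("no genes pass |FC| > %g and adj p < %g", fc_cut, q_cut)
  structure(genes, source_tag = "DEG")
}

#' Intersect differentially expressed genes with a copy-number gene list
#'
#' The Venn intersection defining the seed genes: differentially expressed
#' genes that also carry copy-number alterations. Region counts (DEG-only,
#' CNA-only, shared) are reported via `message()`.
#'
#' @param degs Character vector of DEG symbols.
#' @param cna Character vector of copy-number-altered gene symbols.
#' @return Character vector of seed gene symbols (sorted), attribute
#'   `source_tag = "seed"`. Empty with a warning if the sets are disjoint.
#' @export
intersect_seeds <- function(degs, cna) {
  if (!length(degs) || !length(cna))
    stopf("both gene lists must be non-empty")
  shared <- sort(intersect(degs, cna))
  message(sprintf("seed intersection: %d DEG-only, %d CNA-only, %d shared",
                  length(setdiff(degs, cna)), length(setdiff(cna, degs)),
                  length(shared)))
  if (!length(shared))
    warnf("DEG and CNA lists are disjoint: no seed genes")
  structure(shared, source_tag = "seed")
}
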