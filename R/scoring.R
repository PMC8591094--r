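# z-transformation and per-sample subnetwork activity scores.

#' Z-transform an expression matrix gene-wise
#'
#' Standardizes every gene row to mean 0 and sample standard deviation 1
#' (n-1 denominator) across all samples. Zero-variance genes carry no
#' per-sample information and are dropped with a warning.
#'
#' @param expr An [expression_matrix()] with >= 2 samples.
#' @return A standardized [expression_matrix()] (class labels preserved).
#' @export
zscore <- function(expr) {
  x <- expr$values
  if (ncol(x) < 2L) stopf("z-transformation needs >= 2 samples")
  mu <- rowMeans(x)
  sdev <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  keep <- sdev > 0
  if (any(!keep))
    warnf("%d zero-variance gene(s) dropped before z-transformation",
          sum(!keep))
  if (!any(keep)) stopf("all genes have zero variance")
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  expression_matrix(z, expr$class_labels)
}

#' Assign up/down direction to every subnetwork member
#'
#' Each member gene is labelled by the sign of its training-data class-mean
#' difference: up if the case mean exceeds the control mean, down if below.
#' The rule applies to every member, not only the differentially expressed
#' ones, so expansion-added genes contribute to the score too. Exact ties
#' are excluded from both sets; members absent from the expression matrix
#' are excluded with a warning and reported through the per-subnetwork
#' `coverage` field (scorable members / all members).
#'
#' @param subnets List of subnetworks from [filter_subnetworks()].
#' @param expr Training [expression_matrix()] with class labels.
#' @return The subnetwork list with `up_set`, `down_set` and `coverage`
#'   filled in.
#' @export
assign_directions <- function(subnets, expr) {
  if (is.null(expr$class_labels))
    stopf("direction assignment needs class labels")
  labs <- expr$class_labels
  x <- expr$values[, names(labs), drop = FALSE]
  m1 <- rowMeans(x[, labs == "case", drop = FALSE])
  m0 <- rowMeans(x[, labs == "control", drop = FALSE])
  d <- m1 - m0
  n_missing <- 0L
  out <- lapply(subnets, function(s) {
    present <- intersect(s$members, rownames(x))
    n_missing <<- n_missing + (length(s$members) - length(present))
    s$up_set <- sort(present[d[present] > 0])
    s$down_set <- sort(present[d[present] < 0])
    s$coverage <- length(present) / length(s$members)
    if (!length(s$up_set) && !length(s$down_set))
      stopf("subnetwork %d has no scorable gene (all members tied or missing)",
            s$id)
    s
  })
  if (n_missing > 0L)
    warnf("%d subnetwork member(s) absent from the expression matrix excluded",
          n_missing)
  out
}

#' Per-sample subnetwork activity scores
#'
#' The activity score of subnetwork i in sample s is the mean z-score of
#' its up-regulated members minus the mean z-score of its down-regulated
#' members:
#' `SS_i(s) = mean(z[up_set, s]) - mean(z[down_set, s])`.
#' An empty up or down set contributes 0 for its term. Directions are
#' frozen at training time, so scoring a validation cohort re-standardized
#' within itself reuses the training up/down assignments; members missing
#' from the validation matrix are dropped from their sets, a per-subnetwork
#' coverage fraction is attached, and coverage below 50% is flagged with a
#' warning.
#'
#' @param subnets Subnetworks with directions assigned
#'   ([assign_directions()]).
#' @param zexpr A standardized [expression_matrix()] (see [zscore()]).
#' @return Numeric matrix, rows = `subnetwork_<id>`, columns = samples,
#'   with attribute `coverage` (named fraction of direction-assigned
#'   members present in `zexpr`).
#' @export
activity_scores <- function(subnets, zexpr) {
  z <- zexpr$values
  ids <- vapply(subnets, function(s) s$id, numeric(1))
  scores <- matrix(0, length(subnets), ncol(z),
                   dimnames = list(paste0("subnetwork_", ids), colnames(z)))
  coverage <- numeric(length(subnets))
  for (i in seq_along(subnets)) {
    s <- subnets[[i]]
    up <- intersect(s$up_set, rownames(z))
    dn <- intersect(s$down_set, rownames(z))
    n_assigned <- length(s$up_set) + length(s$down_set)
    coverage[i] <- if (n_assigned) (length(up) + length(dn)) / n_assigned else 0
    up_term <- if (length(up)) colMeans(z[up, , drop = FALSE]) else 0
    dn_term <- if (length(dn)) colMeans(z[dn, , drop = FALSE]) else 0
    scores[i, ] <- up_term - dn_term
  }
  names(coverage) <- rownames(scores)
  low <- coverage < 0.5
  if (any(low))
    warnf("low cross-platform coverage (<50%%) for: %s",
          paste(names(coverage)[low], collapse = ", "))
  attr(scores, "coverage") <- coverage
  scores
}

#' Score a raw cohort against frozen subnetwork definitions
#'
#' Convenience wrapper for validation cohorts: z-transforms the cohort
#' within itself and applies [activity_scores()] with the training-time
#' up/down assignments.
#'
#' @param subnets Direction-assigned subnetworks.
#' @param expr Raw (log2) [expression_matrix()] for the cohort.
#' @return Score matrix as in [activity_scores()].
#' @export
score_cohort <- function(subnets, expr) {
  activity_scores(subnets, zscore(expr))
}
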