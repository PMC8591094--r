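# SVM classification on subnetwork scores, evaluation metrics and PCA QC.

#' Train a linear SVM on subnetwork scores
#'
#' Fits a maximum-margin linear classifier using the subnetwork activity
#' scores as features. Features are used as-is (no internal rescaling:
#' activity scores are already on a z-score scale), so the fit is
#' deterministic given fixed inputs. The positive class is `case`.
#'
#' @param scores Numeric matrix, rows = subnetworks, columns = samples.
#' @param labels Named character vector (sample -> `case`/`control`)
#'   covering the score columns.
#' @param cost Soft-margin regularization constant C (default 1).
#' @return Object of class `subnet_svm` wrapping the fitted model and the
#'   feature (subnetwork) ids.
#' @export
train_svm <- function(scores, labels, cost = 1) {
  labels <- labels[colnames(scores)]
  if (anyNA(labels)) stopf("labels missing for some scored samples")
  if (length(unique(labels)) < 2L)
    stopf("training labels contain a single class")
  if (min(table(labels)) < 2L)
    stopf("each class needs >= 2 training samples")
  y <- factor(labels, levels = c("control", "case"))
  fit <- e1071::svm(x = t(scores), y = y, kernel = "linear", cost = cost,
                    scale = FALSE, probability = FALSE)
  structure(list(model = fit, feature_ids = rownames(scores),
                 positive = "case"),
            class = "subnet_svm")
}

#' Decision values of a trained subnetwork SVM
#'
#' Returns the signed distances to the separating hyperplane, oriented so
#' that larger values favor the `case` class.
#'
#' @param model A `subnet_svm`.
#' @param scores Score matrix with the training subnetwork rows.
#' @return Named numeric vector of decision values per sample.
#' @export
svm_decision_values <- function(model, scores) {
  miss <- setdiff(model$feature_ids, rownames(scores))
  if (length(miss))
    stopf("score matrix is missing subnetwork rows: %s",
          paste(miss, collapse = ", "))
  x <- t(scores[model$feature_ids, , drop = FALSE])
  pred <- stats::predict(model$model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  d <- dv[, 1]
  # e1071 orients the decision value toward the first class in the colname
  if (!grepl("^case/", colnames(dv)[1])) d <- -d
  stats::setNames(as.numeric(d), rownames(x))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TP + TN) / (TP + FN + FP + TN); sensitivity = TP / (TP + FN);
#' specificity = TN / (FP + TN). A metric with a zero denominator (a class
#' absent from the evaluation set) is returned as `NA`, not 0.
#'
#' @param tp,fn,fp,tn Non-negative integer counts; `case` is the positive
#'   class.
#' @return List with the four counts and `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
classification_metrics <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stopf("confusion counts must be >= 0")
  n <- tp + fn + fp + tn
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       accuracy = if (n > 0) (tp + tn) / n else NA_real_,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_)
}

#' Evaluate a classifier on labelled samples
#'
#' Predicts each sample's class, tabulates the confusion matrix with
#' `case` as the positive class, and computes accuracy, sensitivity and
#' specificity, plus the AUC of the decision values (the rank statistic)
#' with a DeLong 95% confidence interval.
#'
#' @param model A `subnet_svm` from [train_svm()].
#' @param scores Score matrix for the evaluation samples.
#' @param labels Named character vector (sample -> `case`/`control`).
#' @return Object of class `classifier_eval`: the confusion counts, the
#'   three metrics, `auc`, `auc_ci` (length-2), and `decision_values`.
#'   Metrics undefined because a class is absent are `NA`.
#' @export
evaluate <- function(model, scores, labels) {
  labels <- labels[colnames(scores)]
  if (anyNA(labels)) stopf("labels missing for some scored samples")
  d <- svm_decision_values(model, scores)
  predicted <- ifelse(d > 0, "case", "control")
  tp <- sum(predicted == "case" & labels == "case")
  fn <- sum(predicted == "control" & labels == "case")
  fp <- sum(predicted == "case" & labels == "control")
  tn <- sum(predicted == "control" & labels == "control")
  out <- classification_metrics(tp, fn, fp, tn)
  if (length(unique(labels)) == 2L) {
    roc <- pROC::roc(response = factor(labels, levels = c("control", "case")),
                     predictor = d, levels = c("control", "case"),
                     direction = "<", quiet = TRUE)
    out$auc <- as.numeric(pROC::auc(roc))
    # an AUC of exactly 1 yields a degenerate (1, 1) DeLong interval
    ci <- tryCatch(suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong"))),
                   error = function(e) c(NA_real_, out$auc, NA_real_))
    out$auc_ci <- c(ci[1], ci[3])
  } else {
    out$auc <- NA_real_
    out$auc_ci <- c(NA_real_, NA_real_)
  }
  out$decision_values <- d
  class(out) <- "classifier_eval"
  out
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc,
              x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  tp=%d fn=%d fp=%d tn=%d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Unsupervised PCA projection of samples
#'
#' Centered (not rescaled) principal components of the samples in
#' subnetwork-score space, for visual QC of class separation.
#'
#' @param scores Score matrix, rows = subnetworks, columns = samples
#'   (>= 3 samples).
#' @param n_components Number of components to return (2 or 3).
#' @return List with `coords` (samples x components) and `var_explained`
#'   (fraction per returned component, non-increasing).
#' @export
pca_project <- function(scores, n_components = 2L) {
  if (ncol(scores) < 3L) stopf("PCA projection needs >= 3 samples")
  n_components <- min(n_components, nrow(scores), ncol(scores) - 1L)
  pc <- stats::prcomp(t(scores), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = ve[seq_len(n_components)])
}
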