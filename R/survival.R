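# Cox regression, the subnetwork risk score, median-split stratification,
# Kaplan-Meier curves and the log-rank test.

#' Binary clinical design matrix
#'
#' Encodes the clinical covariates as the standard binary contrasts:
#' age `>=50` vs `<50`, gender `female` vs `male`, stage `III-IV` vs
#' `I-II`, lymphatic invasion `yes` vs `no` (the second level is the
#' reference, coded 0). Unknown levels are `NA`.
#'
#' @param clinical A [clinical_table()].
#' @return Data frame of 0/1 covariates aligned to `clinical$sample`.
#' @export
clinical_design <- function(clinical) {
  data.frame(
    age_group = as.integer(clinical$age_group == ">=50"),
    gender = as.integer(clinical$gender == "female"),
    stage_group = as.integer(clinical$stage_group == "III-IV"),
    lymphatic_invasion = as.integer(clinical$lymphatic_invasion == "yes"),
    row.names = clinical$sample)
}

#' Cox proportional-hazards fits
#'
#' Fits either one multivariate Cox model over all supplied covariates or
#' a series of univariate models (one per covariate). Partial-likelihood
#' estimation uses the Efron approximation for tied event times; hazard
#' ratios carry Wald 95% confidence intervals.
#'
#' @param clinical A [clinical_table()] supplying `time` and `event`.
#' @param covariates Data frame of covariates (numeric, or 0/1 contrasts
#'   from [clinical_design()]), rows aligned to `clinical` (by row name
#'   when present, else by position).
#' @param model `"multivariate"` (one joint fit) or `"univariate"` (one
#'   fit per covariate).
#' @return Data frame with one row per covariate: `covariate`, `beta`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`, `model_tag`.
#' @export
cox_fit <- function(clinical, covariates, model = c("multivariate", "univariate")) {
  model <- match.arg(model)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(clinical))
    stopf("covariates (%d rows) do not match clinical table (%d rows)",
          nrow(covariates), nrow(clinical))
  if (!is.null(rownames(covariates)) &&
      all(clinical$sample %in% rownames(covariates)))
    covariates <- covariates[clinical$sample, , drop = FALSE]
  if (sum(clinical$event) == 0L) stopf("no events: Cox model is not estimable")
  const <- vapply(covariates, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) < 2L
  }, logical(1))
  if (any(const))
    stopf("constant covariate(s) not identifiable: %s",
          paste(names(covariates)[const], collapse = ", "))
  fit_one <- function(dat, tag) {
    df <- cbind(data.frame(.time = clinical$time, .event = clinical$event),
                dat)
    fit <- survival::coxph(
      survival::Surv(.time, .event) ~ .,
      data = df, ties = "efron")
    s <- summary(fit)
    beta <- s$coefficients[, "coef"]
    if (any(!is.finite(beta)) || any(abs(beta) > 20))
      stopf("Cox fit diverged (complete separation?) for: %s",
            paste(rownames(s$coefficients)[!is.finite(beta) | abs(beta) > 20],
                  collapse = ", "))
    data.frame(covariate = rownames(s$coefficients),
               beta = unname(beta),
               hr = unname(s$coefficients[, "exp(coef)"]),
               ci_low = unname(s$conf.int[, "lower .95"]),
               ci_high = unname(s$conf.int[, "upper .95"]),
               p_value = unname(s$coefficients[, "Pr(>|z|)"]),
               model_tag = tag, row.names = NULL,
               stringsAsFactors = FALSE)
  }
  if (model == "multivariate") {
    fit_one(covariates, "multivariate")
  } else {
    do.call(rbind, lapply(names(covariates), function(nm) {
      fit_one(covariates[, nm, drop = FALSE], "univariate")
    }))
  }
}

#' Fit the subnetwork risk model
#'
#' Fits a multivariate Cox model with the subnetwork activity scores as
#' continuous covariates; the resulting per-subnetwork coefficients define
#' the prognostic risk score, and the median of the training risk scores
#' defines the high/low threshold.
#'
#' @param scores Subnetwork score matrix (rows `subnetwork_<id>`), columns
#'   covering `clinical$sample`.
#' @param clinical A [clinical_table()] for the scored samples.
#' @return Object of class `risk_model`: list with `subnetwork_ids`,
#'   `betas` (full precision, aligned), `threshold` (training median risk
#'   score) and the Cox `fit_table`.
#' @export
fit_risk_model <- function(scores, clinical) {
  miss <- setdiff(clinical$sample, colnames(scores))
  if (length(miss))
    stopf("score matrix is missing samples: %s", paste(miss, collapse = ", "))
  x <- t(scores[, clinical$sample, drop = FALSE])
  tab <- cox_fit(clinical, as.data.frame(x), model = "multivariate")
  model <- risk_model(subnetwork_ids = rownames(scores),
                      betas = tab$beta[match(rownames(scores), tab$covariate)],
                      threshold = NA_real_)
  rs <- risk_score(scores[, clinical$sample, drop = FALSE], model)
  model$threshold <- stats::median(rs)
  model$fit_table <- tab
  model
}

#' Construct a risk model
#'
#' @param subnetwork_ids Ordered subnetwork identifiers (matching score
#'   matrix row names).
#' @param betas Cox regression coefficients aligned to the ids.
#' @param threshold Median training risk score (the high/low split point).
#' @return Object of class `risk_model`.
#' @export
risk_model <- function(subnetwork_ids, betas, threshold = NA_real_) {
  if (length(subnetwork_ids) != length(betas))
    stopf("subnetwork ids and betas differ in length")
  if (!all(is.finite(betas))) stopf("betas must be finite")
  structure(list(subnetwork_ids = as.character(subnetwork_ids),
                 betas = as.numeric(betas), threshold = threshold),
            class = "risk_model")
}

#' Prognostic risk score
#'
#' The weighted sum of subnetwork activity scores:
#' `risk(s) = sum_i SS_i(s) * beta_i`, with the Cox coefficients of the
#' risk model as weights.
#'
#' @param scores Score matrix whose rows cover `model$subnetwork_ids`.
#' @param model A [risk_model()].
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(scores, model) {
  miss <- setdiff(model$subnetwork_ids, rownames(scores))
  if (length(miss))
    stopf("score matrix is missing subnetwork row(s): %s",
          paste(miss, collapse = ", "))
  colSums(scores[model$subnetwork_ids, , drop = FALSE] * model$betas)
}

#' Median-split risk stratification
#'
#' Samples with risk score strictly above the median are `high` risk;
#' scores at or below the median (including median ties) are `low`.
#'
#' @param risk Named numeric vector of risk scores (>= 2 samples).
#' @param threshold Split point; defaults to `median(risk)`.
#' @return Named character vector (`high`/`low`) with attribute
#'   `threshold`.
#' @export
stratify_median <- function(risk, threshold = NULL) {
  if (length(risk) < 2L) stopf("stratification needs >= 2 samples")
  if (length(unique(risk)) == 1L)
    stopf("degenerate stratification: all risk scores identical")
  threshold <- threshold %||% stats::median(risk)
  groups <- ifelse(risk > threshold, "high", "low")
  attr(groups, "threshold") <- threshold
  groups
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit survival estimates per risk group plus the 1-df log-rank
#' chi-square comparing them.
#'
#' @param clinical A [clinical_table()].
#' @param groups Named character vector (sample -> `high`/`low`) covering
#'   the clinical samples; both groups must be non-empty and at least one
#'   event must be present.
#' @return Object of class `km_result`: `curves` (data.frame: group, time,
#'   n_risk, n_event, survival), `chisq`, `df`, `p_value`, `n_per_group`.
#' @export
km_logrank <- function(clinical, groups) {
  g <- groups[clinical$sample]
  if (anyNA(g)) stopf("group assignment missing for some clinical samples")
  if (length(unique(g)) < 2L) stopf("both risk groups must be non-empty")
  if (sum(clinical$event) == 0L) stopf("no events: log-rank test undefined")
  df <- data.frame(time = clinical$time, event = clinical$event,
                   group = factor(g, levels = c("low", "high")))
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata_names <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(group = strata_names, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       survival = sf$surv, row.names = NULL,
                       stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chisq <- as.numeric(sd$chisq)
  if (!is.finite(chisq)) chisq <- 0
  structure(list(curves = curves, chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 n_per_group = table(df$group)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("log-rank chi-square %.3f (df=%d), p = %.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' External-cohort validation of a frozen risk model
#'
#' Applies the training-cohort coefficients unchanged to an external
#' cohort's subnetwork scores, recomputes the median threshold within the
#' external cohort, and runs the Kaplan-Meier / log-rank comparison.
#'
#' @param scores_ext External-cohort score matrix.
#' @param model A frozen [risk_model()].
#' @param clinical_ext External [clinical_table()].
#' @return List with `risk`, `groups`, `threshold` and `km`
#'   (a `km_result`).
#' @export
external_validation <- function(scores_ext, model, clinical_ext) {
  rs <- risk_score(scores_ext, model)
  groups <- stratify_median(rs)
  list(risk = rs, groups = groups,
       threshold = attr(groups, "threshold"),
       km = km_logrank(clinical_ext, groups))
}
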