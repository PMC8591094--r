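# Cox fits, risk score, stratification, Kaplan-Meier and log-rank.

sim_binary_cohort <- function(n, beta, censor = 0.2, h0 = 0.1) {
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = h0 * exp(beta * x))
  if (censor > 0) {
    t_cens <- rexp(n, rate = h0 * censor / (1 - censor))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event; event <- rep(1L, n)
  }
  list(clin = clinical_table(sample = sprintf("p%03d", 1:n),
                             time = time, event = event),
       x = data.frame(x = x))
}

test_that("Cox regression recovers a known binary-covariate effect", {
  set.seed(31)
  co <- sim_binary_cohort(300, beta = 0.7)
  fit <- cox_fit(co$clin, co$x)
  expect_gt(fit$beta, 0.5)
  expect_lt(fit$beta, 0.9)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-9)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("constant covariates and event-free data are rejected", {
  set.seed(32)
  co <- sim_binary_cohort(50, beta = 0)
  expect_error(cox_fit(co$clin, data.frame(x = rep(1, 50))), "constant")
  clin0 <- co$clin; clin0$event <- 0L
  expect_error(cox_fit(clin0, co$x), "no events")
})

test_that("a null covariate is called null in most replicates", {
  set.seed(33)
  res <- replicate(100, {
    co <- sim_binary_cohort(300, beta = 0)
    f <- cox_fit(co$clin, co$x)
    c(abs(f$beta) < 0.25, f$p_value > 0.05)
  })
  expect_gte(mean(res[1, ] & res[2, ]), 0.9)
})

test_that("univariate and multivariate clinical fits use Table-style contrasts", {
  set.seed(34)
  n <- 200
  stage <- sample(c("III-IV", "I-II"), n, TRUE)
  lam <- 0.1 * exp(1.0 * (stage == "III-IV"))
  clin <- clinical_table(sample = sprintf("p%03d", 1:n),
                         time = rexp(n, lam), event = 1L,
                         age_group = sample(c(">=50", "<50"), n, TRUE),
                         gender = sample(c("female", "male"), n, TRUE),
                         stage_group = stage,
                         lymphatic_invasion = sample(c("yes", "no"), n, TRUE))
  design <- clinical_design(clin)
  expect_true(all(unlist(design) %in% c(0, 1)))
  uni <- cox_fit(clin, design, model = "univariate")
  expect_equal(nrow(uni), 4L)
  expect_true(all(uni$model_tag == "univariate"))
  multi <- cox_fit(clin, design, model = "multivariate")
  b <- multi$beta[multi$covariate == "stage_group"]
  expect_gt(b, 0.5); expect_lt(b, 1.5)
})

test_that("risk score is the coefficient-weighted sum of activity scores", {
  coefs <- reference_risk_coefficients()
  model <- risk_model(coefs$subnetwork, coefs$beta)
  ones <- matrix(1, 15, 3, dimnames = list(coefs$subnetwork, paste0("s", 1:3)))
  expect_equal(unname(risk_score(ones, model)), rep(-5.4, 3))
  expect_equal(unname(risk_score(ones * 0, model)), rep(0, 3))
  expect_equal(risk_score(ones * 2, model), 2 * risk_score(ones, model))
  # row order does not matter as long as ids align
  shuf <- ones[sample(15), , drop = FALSE]
  expect_equal(risk_score(shuf, model), risk_score(ones, model))
  expect_error(risk_score(ones[-1, , drop = FALSE], model), "subnetwork_1")
})

test_that("median stratification sends ties low and rejects degenerate input", {
  g <- stratify_median(setNames(c(1, 2, 3, 4), paste0("s", 1:4)))
  expect_equal(attr(g, "threshold"), 2.5)
  expect_equal(sum(g == "high"), 2L)
  expect_setequal(names(g)[g == "high"], c("s3", "s4"))
  # odd n: the sample sitting exactly at the median goes low
  g2 <- stratify_median(setNames(c(1, 2, 3), paste0("s", 1:3)))
  expect_equal(unname(g2["s2"]), "low")
  expect_error(stratify_median(c(5, 5, 5)), "degenerate")
})

test_that("Kaplan-Meier matches the hand product-limit and empirical survival", {
  clin <- clinical_table(sample = c("a", "b"), time = c(1, 2), event = c(1, 1))
  km <- km_logrank(rbind(clin, clinical_table(sample = c("c", "d"),
                                              time = c(5, 6), event = c(1, 1))),
                   setNames(c("high", "high", "low", "low"),
                            c("a", "b", "c", "d")))
  gA <- km$curves[km$curves$group == "high", ]
  expect_equal(gA$survival[gA$time == 1], 0.5)
  expect_equal(gA$survival[gA$time == 2], 0)

  # with no censoring the product-limit equals the empirical survival
  set.seed(36)
  t1 <- rexp(40); grp <- setNames(rep(c("high", "low"), 20), sprintf("q%02d", 1:40))
  clin2 <- clinical_table(sample = names(grp), time = t1, event = 1L)
  km2 <- km_logrank(clin2, grp)
  for (g in c("high", "low")) {
    cur <- km2$curves[km2$curves$group == g, ]
    tg <- t1[grp == g]
    emp <- vapply(cur$time, function(tt) mean(tg > tt), numeric(1))
    expect_equal(cur$survival, emp, tolerance = 1e-12)
  }
})

test_that("identical groups give a null log-rank; real effects are detected", {
  times <- c(1, 3, 4, 7); events <- c(1, 0, 1, 1)
  clin <- clinical_table(sample = sprintf("p%d", 1:8),
                         time = rep(times, 2), event = rep(events, 2))
  groups <- setNames(rep(c("high", "low"), each = 4), clin$sample)
  km <- km_logrank(clin, groups)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1)

  set.seed(37)
  n <- 100
  grp <- setNames(rep(c("high", "low"), each = n), sprintf("r%03d", 1:(2 * n)))
  lam <- ifelse(grp == "high", 0.3, 0.1)
  clin2 <- clinical_table(sample = names(grp), time = rexp(2 * n, lam),
                          event = 1L)
  expect_lt(km_logrank(clin2, grp)$p_value, 0.05)
})

test_that("log-rank equals the explicit 2x2-table computation", {
  set.seed(38)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    time <- round(rexp(n, 0.2), 2)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1L
    grp <- setNames(sample(c("high", "low"), n, TRUE), sprintf("s%02d", 1:n))
    if (length(unique(grp)) < 2) grp[1] <- setdiff(c("high", "low"), grp[1])
    clin <- clinical_table(sample = names(grp), time = time, event = event)
    km <- km_logrank(clin, grp)
    expect_equal(km$chisq, brute_logrank(time, event, unname(grp)),
                 tolerance = 1e-8)
  }
})

test_that("frozen-coefficient external validation behaves under signal and null", {
  set.seed(39)
  n <- 200
  scores <- matrix(rnorm(2 * n), 2, n,
                   dimnames = list(c("subnetwork_1", "subnetwork_2"),
                                   sprintf("e%03d", 1:n)))
  model <- risk_model(rownames(scores), c(1.2, -0.8))
  true_risk <- risk_score(scores, model)
  spec <- synthetic_spec(survival_beta = 1.2, censor_rate = 0.2,
                         rng_seed = 40)
  clin <- gen_survival(true_risk, spec)
  out <- external_validation(scores, model, clin)
  expect_lt(out$km$p_value, 0.05)
  expect_equal(out$threshold, median(true_risk))

  # permuted survival times carry no signal: p should rarely be small
  ps <- vapply(1:20, function(k) {
    set.seed(400 + k)
    perm <- sample(nrow(clin))
    clin_p <- clin; clin_p$time <- clin$time[perm]; clin_p$event <- clin$event[perm]
    external_validation(scores, model, clin_p)$km$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.25)

  zero <- risk_model(rownames(scores), c(0, 0))
  expect_error(external_validation(scores, zero, clin), "degenerate")
})
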