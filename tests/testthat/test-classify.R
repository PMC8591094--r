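# SVM training, evaluation metrics, AUC and PCA projection.

make_toy_scores <- function(n_per_class = 20, shift = 2, sd = 0.1,
                            seed = 12, prefix = "s") {
  set.seed(seed)
  samples <- paste0(prefix, seq_len(2 * n_per_class))
  labels <- setNames(rep(c("case", "control"), each = n_per_class), samples)
  x <- rbind(f1 = c(rnorm(n_per_class, shift, sd),
                    rnorm(n_per_class, -shift, sd)),
             f2 = rnorm(2 * n_per_class, 0, sd))
  colnames(x) <- samples
  list(scores = x, labels = labels)
}

test_that("a linearly separable toy problem is fit perfectly", {
  toy <- make_toy_scores()
  model <- train_svm(toy$scores, toy$labels)
  ev <- evaluate(model, toy$scores, toy$labels)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$auc, 1.0)
  expect_error(train_svm(toy$scores,
                         setNames(rep("case", ncol(toy$scores)),
                                  colnames(toy$scores))),
               "single class")
})

test_that("randomly permuted labels give chance-level cross-validation", {
  toy <- make_toy_scores(n_per_class = 30)
  set.seed(99)
  folds <- split(colnames(toy$scores), rep(1:5, length.out = ncol(toy$scores)))
  # average the cross-validated accuracy over several label permutations
  cv_acc <- replicate(5, {
    perm <- setNames(sample(toy$labels), names(toy$labels))
    mean(vapply(folds, function(test_ids) {
      train_ids <- setdiff(colnames(toy$scores), test_ids)
      m <- train_svm(toy$scores[, train_ids], perm[train_ids])
      evaluate(m, toy$scores[, test_ids, drop = FALSE],
               perm[test_ids])$accuracy
    }, numeric(1)))
  })
  expect_lt(abs(mean(cv_acc) - 0.5), 0.15)
})

test_that("metric identities hold over random confusion matrices", {
  expect_equal(classification_metrics(8, 2, 1, 9)[c("accuracy", "sensitivity",
                                                    "specificity")],
               list(accuracy = 0.85, sensitivity = 0.80, specificity = 0.90))
  set.seed(13)
  for (i in 1:500) {
    v <- sample(0:1000, 4, replace = TRUE)
    m <- classification_metrics(v[1], v[2], v[3], v[4])
    expect_equal(m$accuracy, (v[1] + v[4]) / sum(v))
    if (v[1] + v[2] > 0) expect_equal(m$sensitivity, v[1] / (v[1] + v[2]))
    else expect_true(is.na(m$sensitivity))
    if (v[3] + v[4] > 0) expect_equal(m$specificity, v[4] / (v[3] + v[4]))
    else expect_true(is.na(m$specificity))
  }
})

test_that("AUC is a rank statistic: tie and monotone-transform behavior", {
  toy <- make_toy_scores(n_per_class = 15, shift = 0.8, sd = 1, seed = 14)
  model <- train_svm(toy$scores, toy$labels)
  d <- svm_decision_values(model, toy$scores)
  ev <- evaluate(model, toy$scores, toy$labels)
  expect_equal(ev$auc, rank_auc(toy$labels[names(d)], d))
  # strictly monotone transform of the decision values leaves AUC unchanged
  expect_equal(rank_auc(toy$labels[names(d)], exp(3 * d)), ev$auc)
  # all-tied decision values mean no ranking information
  expect_equal(rank_auc(toy$labels, rep(0, length(toy$labels))), 0.5)
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])
})

test_that("evaluation with a class absent reports NA, not zero", {
  toy <- make_toy_scores()
  model <- train_svm(toy$scores, toy$labels)
  case_only <- names(toy$labels)[toy$labels == "case"]
  ev <- evaluate(model, toy$scores[, case_only], toy$labels[case_only])
  expect_true(is.na(ev$specificity))
  expect_true(is.na(ev$auc))
  expect_equal(ev$sensitivity, 1.0)
})

test_that("PCA projection is centered with non-increasing variance", {
  rank1 <- outer(c(f1 = 1, f2 = 2, f3 = -1), seq(-2, 2, length.out = 6))
  colnames(rank1) <- paste0("s", 1:6)
  p <- pca_project(rank1)
  expect_equal(p$var_explained[1], 1.0, tolerance = 1e-12)
  # duplicated samples project to coincident points
  dup <- cbind(rank1, rank1[, 3, drop = FALSE])
  colnames(dup) <- c(colnames(rank1), "s3dup")
  pd <- pca_project(dup)
  expect_equal(unname(pd$coords["s3", ]), unname(pd$coords["s3dup", ]),
               tolerance = 1e-12)
  # isotropic noise spreads variance across components
  set.seed(15)
  iso <- matrix(rnorm(5 * 400), 5, 400,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:400)))
  pi_ <- pca_project(iso, n_components = 3)
  expect_lt(pi_$var_explained[1] / pi_$var_explained[3], 3)
  expect_true(all(diff(pi_$var_explained) <= 1e-12))
})

test_that("end-to-end synthetic classification reaches high accuracy", {
  spec <- synthetic_spec(n_genes = 400, n_case = 30, n_control = 30,
                         de_fraction = 0.1, effect_log2 = 2.0,
                         noise_sd = 0.5, rng_seed = 301)
  train <- gen_expression(spec, cohort = "train")
  valid <- gen_expression(spec, de_truth = train$de_truth, cohort = "valid")
  ppi <- gen_ppi(spec, train$de_truth)
  res <- differential_expression(train$expr)
  seeds <- suppressMessages(intersect_seeds(select_degs(res), ppi$cna_genes))
  g <- expand_network(seeds, ppi$edges)
  subnets <- filter_subnetworks(mcl_cluster(g), seeds)
  subnets <- assign_directions(subnets, train$expr)
  model <- train_svm(score_cohort(subnets, train$expr),
                     train$expr$class_labels)
  ev <- evaluate(model, score_cohort(subnets, valid$expr),
                 valid$expr$class_labels)
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$auc, 0.95)
})
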