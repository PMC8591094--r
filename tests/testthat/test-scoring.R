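# z-transformation, direction assignment and activity scores.

test_that("z-transformation standardizes rows and drops constants", {
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(-1, 0, 1))
  colnames(vals) <- paste0("s", 1:3)
  expect_warning(z <- zscore(expression_matrix(vals)), "zero-variance")
  expect_equal(unname(z$values["g1", ]), c(-1, 0, 1))
  expect_false("g2" %in% rownames(z$values))
  # idempotence on an already-standardized row
  expect_equal(zscore(z)$values["g3", ], z$values["g3", ], tolerance = 1e-12)
  expect_error(zscore(expression_matrix(vals[, 1, drop = FALSE])),
               ">= 2 samples")
})

test_that("direction assignment follows the training class-mean sign", {
  expr <- make_expr(c(A = 4, B = 1, C = 3, D = 2),
                    c(A = 2, B = 3, C = 3, D = 1))
  subnets <- list(list(id = 1L, members = c("A", "B", "C", "D", "MISSING"),
                       seed_members = "A",
                       up_set = character(0), down_set = character(0)))
  expect_warning(out <- assign_directions(subnets, expr), "absent")
  expect_equal(out[[1]]$up_set, c("A", "D"))
  expect_equal(out[[1]]$down_set, "B")         # C is an exact tie: excluded
  expect_equal(out[[1]]$coverage, 4 / 5)

  tied <- list(list(id = 1L, members = "C", seed_members = "C",
                    up_set = character(0), down_set = character(0)))
  expect_error(assign_directions(tied, expr), "no scorable gene")
})

test_that("activity score is mean(up) minus mean(down), empty terms 0", {
  zvals <- matrix(c(1.0, 0.6, -0.8), 3, 1,
                  dimnames = list(c("u1", "u2", "d1"), "s1"))
  zexpr <- expression_matrix(zvals)
  sn <- list(list(id = 1L, members = c("u1", "u2", "d1"), seed_members = "u1",
                  up_set = c("u1", "u2"), down_set = "d1"))
  expect_equal(unname(activity_scores(sn, zexpr)[1, 1]), 1.6)

  sn_empty_up <- list(list(id = 1L, members = "d1", seed_members = "d1",
                           up_set = character(0), down_set = "d1"))
  # empty up term contributes 0: score = 0 - (-0.8)
  expect_equal(unname(activity_scores(sn_empty_up, zexpr)[1, 1]), 0.8)
})

test_that("swapping up and down sets negates every score exactly", {
  set.seed(5)
  zvals <- matrix(rnorm(60), 6, 10,
                  dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  zexpr <- expression_matrix(zvals)
  sn <- list(list(id = 1L, members = paste0("g", 1:6), seed_members = "g1",
                  up_set = paste0("g", 1:3), down_set = paste0("g", 4:6)))
  sw <- list(modifyList(sn[[1]], list(up_set = sn[[1]]$down_set,
                                      down_set = sn[[1]]$up_set)))
  expect_equal(activity_scores(sw, zexpr), -activity_scores(sn, zexpr),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("scores are invariant to location and positive scale of raw rows", {
  set.seed(6)
  vals <- matrix(rnorm(80, 7), 8, 10,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  labels <- setNames(rep(c("case", "control"), each = 5), paste0("s", 1:10))
  expr <- expression_matrix(vals, labels)
  sn <- assign_directions(list(list(id = 1L, members = paste0("g", 1:8),
                                    seed_members = "g1",
                                    up_set = character(0),
                                    down_set = character(0))), expr)
  base <- activity_scores(sn, zscore(expr))
  shifted <- vals
  shifted[3, ] <- shifted[3, ] * 2.5 + 11   # positive affine on one gene
  sc2 <- activity_scores(sn, zscore(expression_matrix(shifted, labels)))
  expect_equal(base, sc2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a planted discriminative module separates cases from controls", {
  spec <- synthetic_spec(n_genes = 300, n_case = 30, n_control = 30,
                         de_fraction = 0.1, effect_log2 = 2.0,
                         noise_sd = 0.5, rng_seed = 77)
  sim <- gen_expression(spec)
  tr <- sim$de_truth
  sn <- list(list(id = 1L, members = tr$gene, seed_members = tr$gene[1],
                  up_set = character(0), down_set = character(0)))
  sn <- assign_directions(sn, sim$expr)
  sc <- activity_scores(sn, zscore(sim$expr))[1, ]
  labs <- sim$expr$class_labels[names(sc)]
  tt <- t.test(sc[labs == "case"], sc[labs == "control"])
  expect_gt(mean(sc[labs == "case"]), mean(sc[labs == "control"]))
  expect_lt(tt$p.value, 1e-6)
})

test_that("validation scoring reuses frozen directions and reports coverage", {
  expr <- make_expr(c(A = 5, B = 1, C = 4), c(A = 3, B = 3, C = 3),
                    sd = 0.1, seed = 8)
  sn <- assign_directions(list(list(id = 1L, members = c("A", "B", "C"),
                                    seed_members = "A",
                                    up_set = character(0),
                                    down_set = character(0))), expr)
  # validation platform missing gene C
  vvals <- expr$values[c("A", "B"), ]
  vexpr <- expression_matrix(vvals)
  sc <- score_cohort(sn, vexpr)
  expect_equal(unname(attr(sc, "coverage")), 2 / 3)
  # dropping below 50% coverage warns
  wvals <- expr$values["A", , drop = FALSE]
  expect_warning(score_cohort(sn, expression_matrix(wvals)),
                 "low cross-platform coverage")
})
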