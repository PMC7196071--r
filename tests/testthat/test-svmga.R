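test_that("AUC equals pair counting, including tie handling", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(compute_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")

  # exhaustive pair-counting oracle over random small inputs
  set.seed(13)
  for (n in 2:12) {
    for (rep in 1:8) {
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))[sample.int(n)]
      expect_equal(compute_auc(scores, labels),
                   oracle_auc_pairs(scores, labels))
    }
  }
})

test_that("stratified folds are balanced, deterministic and seed-sensitive", {
  labels <- rep(c(TRUE, FALSE), c(12, 18))
  ids <- sprintf("s%02d", 1:30)
  f1 <- actbenefit:::make_cv_folds(labels, ids, 5, seed = 3)
  f2 <- actbenefit:::make_cv_folds(labels, ids, 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, actbenefit:::make_cv_folds(labels, ids, 5, seed = 4)))
  for (k in 1:5) expect_true(any(labels[f1 == k]) && any(!labels[f1 == k]))
  expect_error(actbenefit:::make_cv_folds(c(TRUE, rep(FALSE, 20)),
                                          sprintf("s%02d", 1:21), 5, 1),
               "stratify")
})

test_that("cv fitness separates planted signal from permuted labels", {
  sim <- simulate_labeled_cohort(n = 100, g = 10, planted = 2,
                                 label_noise = 0.2, seed = 2)
  y <- sim$labels == "benefit"
  feats <- build_feature_matrix(sim$expression, sim$clinical,
                                sim$planted_genes, include_stage = FALSE)
  fit <- cv_fitness(feats, y, cost = 1, gamma = 0.5, seed = 7)
  expect_gt(fit, 0.9)
  expect_identical(fit, cv_fitness(feats, y, cost = 1, gamma = 0.5, seed = 7))

  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    cv_fitness(feats, sample(y), cost = 1, gamma = 0.5, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.1)
})

test_that("hyperparameter tuning maximizes CV AUC with deterministic ties", {
  sim <- simulate_labeled_cohort(n = 80, g = 6, planted = 2,
                                 label_noise = 0.2, seed = 4)
  y <- sim$labels == "benefit"
  feats <- build_feature_matrix(sim$expression, sim$clinical,
                                sim$planted_genes, include_stage = FALSE)
  one <- tune_hyperparams(feats, y, grid = data.frame(cost = 2, gamma = 0.1),
                          seed = 1)
  expect_equal(c(one$cost, one$gamma), c(2, 0.1))
  t1 <- tune_hyperparams(feats, y, seed = 9)
  t2 <- tune_hyperparams(feats, y, seed = 9)
  expect_identical(t1[c("cost", "gamma")], t2[c("cost", "gamma")])
  expect_gte(t1$cv_auc, 0.95)
})

test_that("GA contract: iterations 0, elitism monotonicity, determinism", {
  sim <- simulate_labeled_cohort(n = 60, g = 12, planted = 2,
                                 label_noise = 0.3, seed = 6)
  y <- sim$labels == "benefit"
  feats <- build_feature_matrix(sim$expression, sim$clinical,
                                rownames(sim$expression), include_stage = FALSE)
  g0 <- ga_select(feats, y, 1, 1 / 12, config = ga_config(iterations = 0, seed = 2))
  expect_equal(nrow(g0$trace), 1L)
  expect_equal(g0$best_fitness, max(g0$trace$best_fitness))

  g1 <- ga_select(feats, y, 1, 1 / 12, config = ga_config(iterations = 30, seed = 2))
  expect_false(is.unsorted(g1$trace$best_fitness))
  expect_gte(g1$best_fitness, g0$best_fitness)
  g2 <- ga_select(feats, y, 1, 1 / 12, config = ga_config(iterations = 30, seed = 2))
  expect_identical(g1, g2)  # trace reproduced bit-for-bit
  expect_true(any(g1$best))
})

test_that("initial-population null fitness stays within the overfit guard", {
  fits <- vapply(1:10, function(s) {
    sim <- simulate_labeled_cohort(n = 120, g = 30, planted = 0,
                                   label_noise = 1, seed = s)
    feats <- build_feature_matrix(sim$expression, sim$clinical,
                                  rownames(sim$expression),
                                  include_stage = FALSE)
    ga_select(feats, sim$labels == "benefit", 1, 1 / 30,
              config = ga_config(iterations = 0, seed = s + 50))$best_fitness
  }, numeric(1))
  expect_gte(sum(fits <= 0.65), 9)
})

test_that("final model training is deterministic and separates the toy", {
  sim <- simulate_labeled_cohort(n = 80, g = 8, planted = 2,
                                 label_noise = 0.1, seed = 12)
  y <- sim$labels == "benefit"
  m1 <- train_final_model(sim$expression, sim$clinical, sim$labels,
                          sim$planted_genes, cost = 4, gamma = 0.5, seed = 3)
  m2 <- train_final_model(sim$expression, sim$clinical, sim$labels,
                          sim$planted_genes, cost = 4, gamma = 0.5, seed = 3)
  expect_identical(m1$selected_genes, m2$selected_genes)
  s1 <- predict_scores(m1, sim$expression, sim$clinical)
  s2 <- predict_scores(m2, sim$expression, sim$clinical)
  expect_lt(max(abs(s1 - s2)), 1e-9)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_gt(compute_auc(s1, y), 0.95)
  # deep-benefit training points score above 1/2
  expect_gt(median(s1[y]), 0.5)
})

test_that("score prediction demands model genes and respects ordering", {
  sim <- simulate_labeled_cohort(n = 40, g = 6, planted = 2, seed = 8)
  m <- train_final_model(sim$expression, sim$clinical, sim$labels,
                         sim$planted_genes, cost = 1, gamma = 0.3, seed = 1)
  expr_missing <- expression_matrix(
    sim$expression[setdiff(rownames(sim$expression), sim$planted_genes[1]), ],
    "log2")
  expect_error(predict_scores(m, expr_missing, sim$clinical),
               sim$planted_genes[1])
  set.seed(2)
  perm <- sample(ncol(sim$expression))
  sp <- predict_scores(m, expression_matrix(sim$expression[, perm], "log2"),
                       sim$clinical[perm, ])
  s <- predict_scores(m, sim$expression, sim$clinical)
  expect_equal(sp, s[perm])
})
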