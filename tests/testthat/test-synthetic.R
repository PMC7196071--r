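test_that("generation is deterministic and validates its config", {
  cfg <- synthetic_config(n_patients = 80, n_genes = 20)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(generate_cohort(cfg, seed = 6)$expression,
                         a$expression))
  expect_error(synthetic_config(n_predictive = 30, n_genes = 20))
  expect_error(synthetic_config(censor_max = 30))
  expect_error(synthetic_config(treat_fraction = 1.2))
})

test_that("planted structure is consistent with the truth record", {
  cfg <- synthetic_config(n_patients = 300, n_genes = 40)
  sim <- generate_cohort(cfg, seed = 9)
  expect_length(sim$truth$predictive_genes, cfg$n_predictive)
  expect_length(intersect(sim$truth$predictive_genes,
                          sim$truth$prognostic_genes), 0L)
  expect_equal(unname(mean(sim$truth$true_benefit)), 1 - cfg$tau,
               tolerance = 0.02)
  expect_identical(colnames(sim$expression), sim$clinical$sample_id)
  expect_identical(expr_scale(sim$expression), "log2")
})

test_that("censoring fraction matches the analytic expectation at null", {
  # with all effects off, T ~ Exp(h0) independent of C ~ U(a, b):
  # P(censored) = E[exp(-h0 C)] = (exp(-h0 a) - exp(-h0 b)) / (h0 (b - a))
  cfg <- synthetic_config(n_patients = 5000, n_genes = 5, n_predictive = 1,
                          n_prognostic = 1, beta_stage = 0, beta_prog = 0,
                          alpha_treat = 0, gamma_interaction = 0)
  sim <- generate_cohort(cfg, seed = 3)
  h <- cfg$h0; a <- cfg$censor_min; b <- cfg$censor_max
  expected <- (exp(-h * a) - exp(-h * b)) / (h * (b - a))
  expect_lt(abs(mean(!sim$clinical$relapse_event) - expected), 0.05)
})

test_that("treatment assignment reproduces the stage odds multiplier", {
  cfg <- synthetic_config(n_patients = 4000, n_genes = 5, n_predictive = 1,
                          n_prognostic = 1)
  sim <- generate_cohort(cfg, seed = 11)
  tab <- table(sim$clinical$tnm_stage, sim$clinical$act)
  or <- (tab["III", "TRUE"] / tab["III", "FALSE"]) /
    (tab["II", "TRUE"] / tab["II", "FALSE"])
  expect_equal(or, cfg$stage_treat_or, tolerance = 0.25 * cfg$stage_treat_or)
  expect_equal(mean(sim$clinical$act), cfg$treat_fraction, tolerance = 0.03)
})

test_that("null treatment effect gives calibrated log-rank rejections", {
  # a clean null: no treatment effect and no stage->treatment confounding
  cfg <- synthetic_config(n_patients = 150, n_genes = 4, n_predictive = 1,
                          n_prognostic = 1, alpha_treat = 0,
                          gamma_interaction = 0, stage_treat_or = 1)
  rej <- vapply(1:200, function(s) {
    sim <- generate_cohort(cfg, seed = 1000 + s)
    cl <- sim$clinical
    logrank_test(cl$rfs_months, cl$relapse_event, cl$act)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("planted interaction concentrates the ACT benefit where designed", {
  cfg <- synthetic_config(n_patients = 600, n_genes = 10)
  helped <- 0; null_rej <- 0
  for (s in 1:25) {
    sim <- generate_cohort(cfg, seed = 200 + s)
    cl <- sim$clinical; tb <- sim$truth$true_benefit
    cx <- cox_fit(cl$rfs_months[tb], cl$relapse_event[tb],
                  data.frame(act = cl$act[tb]))
    helped <- helped + (cx$hr < 1 && cx$p < 0.05)
    cx0 <- cox_fit(cl$rfs_months[!tb], cl$relapse_event[!tb],
                   data.frame(act = cl$act[!tb]))
    null_rej <- null_rej + (cx0$hr < 1 && cx0$p < 0.05)
  }
  expect_gte(helped, 22)     # >= ~90%: treatment clearly helps true-benefit patients
  expect_lte(null_rej, 3)    # protective effect essentially never seen elsewhere
})

test_that("directly-labelled fixture plants recoverable gene signal", {
  sim <- simulate_labeled_cohort(n = 100, g = 10, planted = 2,
                                 label_noise = 0.3, seed = 15)
  expect_identical(sim, simulate_labeled_cohort(n = 100, g = 10, planted = 2,
                                                label_noise = 0.3, seed = 15))
  y <- sim$labels == "benefit"
  signal <- colMeans(sim$expression[sim$planted_genes, ])
  expect_gt(compute_auc(signal, y), 0.8)
})
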