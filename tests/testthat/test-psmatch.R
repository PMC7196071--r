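make_ps_clinical <- function(n, seed, beta_age = 0.8, beta_noise = 0) {
  set.seed(seed)
  age <- rnorm(n)
  noise <- rnorm(n)
  act <- runif(n) < plogis(-0.3 + beta_age * age + beta_noise * noise)
  toy_clinical(n, act = act, ids = sprintf("p%04d", seq_len(n)),
               age_years = round(65 + 8 * age),
               extra_cov = round(noise, 2))
}

test_that("covariate screening keeps real treatment predictors only", {
  incl <- 0; excl <- 0
  for (s in 1:50) {
    cl <- make_ps_clinical(500, seed = s, beta_age = 1.0)
    sel <- suppressWarnings(select_ps_covariates(cl, c("age_years", "extra_cov")))
    incl <- incl + ("age_years" %in% sel)
    excl <- excl + !("extra_cov" %in% sel)
  }
  expect_gte(incl, 48)  # planted log-odds 1.0 essentially always found
  expect_gte(excl, 44)  # independent covariate excluded ~95% of the time
  expect_error(select_ps_covariates(make_ps_clinical(50, 1), character(0)),
               "empty")
})

test_that("propensity model recovers planted coefficients", {
  cl <- make_ps_clinical(2000, seed = 77, beta_age = 0.8)
  ps <- fit_propensity(cl, "age_years")
  expect_true(all(ps > 0 & ps < 1))
  fit <- glm(cl$act ~ scale(cl$age_years), family = binomial())
  expect_lt(abs(coef(fit)[2] - 0.8), 0.15)
  # permutation of patients permutes the scores identically
  set.seed(1); perm <- sample(nrow(cl))
  ps2 <- fit_propensity(cl[perm, ], "age_years")
  expect_equal(ps2[names(ps)], ps)
  expect_error(fit_propensity(within(cl, age_years <- 60), "age_years"),
               "constant")
})

test_that("1:1.5 quota matching reproduces the 29-to-44 arithmetic", {
  # 29 treated and ample controls with overlapping scores
  set.seed(5)
  n_t <- 29; n_c <- 120
  ps <- c(runif(n_t, 0.3, 0.7), runif(n_c, 0.3, 0.7))
  names(ps) <- sprintf("m%03d", seq_along(ps))
  treated <- rep(c(TRUE, FALSE), c(n_t, n_c))
  mr <- match_nearest(ps, treated, ratio = 1.5, caliper_sd = Inf)
  expect_length(mr$matched_treated, 29L)
  expect_length(mr$matched_controls, 44L)
  expect_false(anyDuplicated(mr$matched_controls) > 0)

  # ratio 1 with identical scores: all treated matched, deterministically
  ps2 <- setNames(rep(0.5, 8), letters[1:8])
  mr2 <- match_nearest(ps2, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                       ratio = 1)
  expect_length(mr2$matched_treated, 3L)
  expect_length(mr2$matched_controls, 3L)
  mr2b <- match_nearest(ps2, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                        ratio = 1)
  expect_identical(mr2$pairs, mr2b$pairs)

  # treated far outside control support stay unmatched
  ps3 <- setNames(c(0.95, 0.1, 0.12, 0.11), c("t1", "c1", "c2", "c3"))
  expect_warning(
    mr3 <- match_nearest(ps3, c(TRUE, FALSE, FALSE, FALSE), ratio = 1,
                         caliper_sd = 0.2),
    "no treated")
  expect_identical(mr3$unmatched_treated, "t1")
  expect_equal(nrow(mr3$pairs), 0L)
})

test_that("matching improves covariate balance on confounded cohorts", {
  worse <- 0
  for (s in 1:25) {
    cl <- make_ps_clinical(400, seed = 100 + s, beta_age = 1.2)
    ps <- fit_propensity(cl, "age_years")
    mr <- match_nearest(ps, cl$act[match(names(ps), cl$sample_id)])
    matched <- cl[cl$sample_id %in% c(mr$matched_treated, mr$matched_controls), ]
    smd <- function(df) {
      a <- df$age_years[df$act]; b <- df$age_years[!df$act]
      abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
    }
    worse <- worse + (smd(matched) > smd(cl) + 0.05)
  }
  expect_equal(worse, 0)
})

test_that("balance table mirrors before/after chi-square comparisons", {
  set.seed(9)
  n <- 300
  stage <- sample(c("II", "III"), n, TRUE)
  act <- runif(n) < ifelse(stage == "III", 0.7, 0.25)
  cl <- toy_clinical(n, act = act, stage = stage,
                     ids = sprintf("b%03d", seq_len(n)))
  ps <- fit_propensity(cl, "tnm_stage")
  mr <- match_nearest(ps, cl$act[match(names(ps), cl$sample_id)])
  bt <- balance_table(cl, mr, "tnm_stage")
  expect_identical(bt$covariate, "tnm_stage")
  expect_lt(bt$p_before, 0.001)
  expect_gt(bt$p_after, bt$p_before)

  # a perfectly balanced match has p ~ 1
  cl2 <- toy_clinical(8, act = rep(c(TRUE, FALSE), 4),
                      stage = rep(c("II", "II", "III", "III"), 2),
                      ids = letters[1:8])
  mr2 <- structure(list(matched_treated = cl2$sample_id[cl2$act],
                        matched_controls = cl2$sample_id[!cl2$act]),
                   class = "match_result")
  bt2 <- balance_table(cl2, mr2, "tnm_stage")
  expect_equal(bt2$p_after, 1)
})
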