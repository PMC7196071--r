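test_that("quantile normalization matches the mean-of-sorted oracle", {
  m <- toy_expr(matrix(c(1, 2, 3, 4, 5, 6), 3, 2), scale = "raw")
  qn <- quantile_normalize(m)
  expect_equal(unname(unclass(qn))[, 1], c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(qn))[, 2], c(2.5, 3.5, 4.5))

  set.seed(41)
  big <- toy_expr(matrix(rnorm(50 * 6, 8), 50, 6), scale = "raw")
  qn2 <- quantile_normalize(big)
  expect_equal(unname(unclass(qn2)), oracle_quantile_normalize(unclass(big)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # sorted columns identical across samples, and idempotent
  sorted <- apply(qn2, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(unclass(quantile_normalize(qn2)), unclass(qn2),
               tolerance = 1e-9, ignore_attr = TRUE)
  # identical columns unchanged
  same <- toy_expr(matrix(c(5, 1, 3, 5, 1, 3), 3, 2), scale = "raw")
  expect_equal(unclass(quantile_normalize(same)), unclass(same),
               ignore_attr = TRUE)
  expect_warning(quantile_normalize(toy_expr(matrix(1:3, 3, 1), scale = "raw")),
                 "single sample")
})

test_that("log2 transform applies the offset and guards its domain", {
  m <- toy_expr(matrix(c(7, 0, 1, 3), 2, 2), scale = "raw")
  lt <- log2_transform(m, offset = 1)
  expect_equal(lt["g01", "s01"], 3)
  expect_equal(lt["g02", "s01"], 0)
  expect_identical(expr_scale(lt), "log2")
  expect_error(log2_transform(m, offset = 0), "zero")
  expect_error(log2_transform(lt), "already")
  expect_error(log2_transform(toy_expr(matrix(-1, 1, 2), scale = "raw")),
               "negative")
})

test_that("probe collapsing averages multi-probe genes and drops unmapped", {
  x <- toy_expr(matrix(c(2, 4, 9, 4, 6, 9), 3, 2),
                genes = c("P1", "P2", "P3"))
  pm <- c(P1 = "G", P2 = "G")
  cp <- collapse_probes(x, pm)
  expect_identical(rownames(cp), "G")
  expect_equal(unname(unclass(cp))[1, ], c(3, 5))
  # one-probe gene unchanged; probe order irrelevant
  pm2 <- c(P1 = "G", P2 = "G", P3 = "H")
  cp2 <- collapse_probes(x, pm2)
  expect_equal(cp2["H", ], setNames(c(9, 9), c("s01", "s02")))
  shuffled <- set_scale(x[c(3, 1, 2), ], "log2")
  expect_equal(unclass(collapse_probes(shuffled, pm2)), unclass(cp2),
               ignore_attr = TRUE)
  expect_error(collapse_probes(x, c(Q9 = "Z")), "no probes")
})

test_that("low-expression filter removes genes by exact-zero proportion", {
  vals <- rbind(c(rep(0, 5), rep(2, 5)),   # 50% zeros -> removed
                c(rep(0, 4), rep(2, 6)),   # 40% zeros -> kept
                rep(1, 10))
  x <- toy_expr(vals, scale = "raw")
  expect_message(f <- filter_low_expression(x), "removed 1 of 3")
  expect_identical(rownames(f), c("g02", "g03"))
  allpos <- toy_expr(matrix(1, 3, 4), scale = "raw")
  expect_identical(rownames(suppressMessages(filter_low_expression(allpos))),
                   rownames(allpos))
})

test_that("batch correction removes the common shift, keeps grand means", {
  set.seed(7)
  half <- matrix(rnorm(200 * 20, 8), 200, 20)
  x <- toy_expr(cbind(half, half + 2), scale = "log2")
  batch <- rep(c("A", "B"), each = 20)
  adj <- combat_adjust(x, batch)
  diffs <- rowMeans(adj[, 1:20]) - rowMeans(adj[, 21:40])
  # the across-gene common batch effect is removed
  expect_lt(abs(mean(diffs)), 0.05)
  # ... and the residual per-gene differences shrink far below the planted 2.0
  expect_lt(mean(abs(diffs)), 0.5)
  # per-gene grand means are preserved by the back-transform
  expect_lt(max(abs(rowMeans(adj) - rowMeans(x))), 1e-6)
})

test_that("batch correction near-identity on identical batch distributions", {
  set.seed(8)
  half <- matrix(rnorm(150 * 15, 8), 150, 15)
  x <- toy_expr(cbind(half, half), scale = "log2")
  adj <- combat_adjust(x, rep(c("A", "B"), each = 15))
  # location is exact; empirical-Bayes variance scaling leaves a small
  # dof-convention wobble
  expect_lt(max(abs(adj - x)), 0.15)
  expect_lt(mean(abs(adj - x)), 0.05)
})

test_that("batch correction input contracts", {
  x <- toy_expr(matrix(rnorm(40), 10, 4), scale = "log2")
  expect_warning(out <- combat_adjust(x, rep("A", 4)), "single batch")
  expect_equal(unclass(out), unclass(x), ignore_attr = TRUE)
  expect_error(combat_adjust(x, c("A", "A", "A", "B")), "fewer than 2")
})
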