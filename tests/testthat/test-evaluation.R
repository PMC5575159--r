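# VAF, fold geometry, repeated-measures ANOVA and pairwise comparisons.

test_that("VAF matches its definition and invariances", {
  m <- c(0, 1, 2, 3)
  expect_equal(vaf(m, m), 100)
  expect_equal(vaf(m, rep(mean(m), 4)), 0)
  # hand-worked example: population variances 0.1875 / 1.25
  expect_equal(vaf(m, c(0, 1, 2, 2)), 85.0)

  # invariant to a constant offset in the prediction and to common scaling
  emgnarx:::with_seed(1, {
    x <- stats::rnorm(50)
    p <- x + stats::rnorm(50, sd = 0.2)
    expect_equal(vaf(x, p + 5), vaf(x, p))
    expect_equal(vaf(3 * x, 3 * p), vaf(x, p))
  })

  expect_error(vaf(rep(1, 10), stats::rnorm(10)),
               class = "emgnarx_metric_error")
  expect_error(vaf(1:3, 1:4), class = "emgnarx_input_error")
})

test_that("contiguous folds partition the samples with the remainder rule", {
  f <- make_folds(100, 5)
  starts <- vapply(f, function(x) x$validation[1], numeric(1))
  expect_equal(starts, c(1, 21, 41, 61, 81))
  expect_true(all(vapply(f, function(x) length(x$validation), 1L) == 20L))
  # each training set is exactly 80% when k divides n
  expect_true(all(vapply(f, function(x) length(x$train), 1L) == 80L))

  # union of validation blocks is everything, pairwise disjoint
  all_val <- unlist(lapply(f, `[[`, "validation"))
  expect_identical(sort(all_val), 1:100)
  expect_identical(anyDuplicated(all_val), 0L)

  f2 <- make_folds(101, 5)
  expect_equal(vapply(f2, function(x) length(x$validation), 1L),
               c(20L, 20L, 20L, 20L, 21L))
  expect_error(make_folds(8, 5), class = "emgnarx_partition_error")
})

# definitional oracle: explicit sums over the data layout
rm_anova_oracle <- function(x) {
  n <- nrow(x); cc <- ncol(x); grand <- mean(x)
  ss_cond <- 0
  for (j in seq_len(cc)) ss_cond <- ss_cond + n * (mean(x[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + cc * (mean(x[i, ]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(cc))
    ss_tot <- ss_tot + (x[i, j] - grand)^2
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- cc - 1; df2 <- (cc - 1) * (n - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE),
       peta = ss_cond / (ss_cond + ss_err))
}

test_that("repeated-measures ANOVA matches the definitional oracle and aov", {
  x <- matrix(c(85, 90, 88,
                92, 91, 89,
                78, 84, 80,
                88, 86, 91), 4, 3, byrow = TRUE)
  got <- rm_anova(x)
  want <- rm_anova_oracle(x)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$partial_eta_sq, want$peta, tolerance = 1e-10)
  expect_identical(c(got$df1, got$df2), c(2L, 6L))

  # independent route: aov with an Error stratum
  df <- data.frame(y = as.vector(x),
                   cond = factor(rep(seq_len(3), each = 4)),
                   subj = factor(rep(seq_len(4), 3)))
  fit <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df))
  tab <- fit[["Error: subj:cond"]][[1]]
  expect_equal(got$F, tab["cond", "F value"], tolerance = 1e-10)
  expect_equal(got$p, tab["cond", "Pr(>F)"], tolerance = 1e-10)

  # identical columns: no condition variance at all
  same <- matrix(rep(c(1, 5, 3, 2), 3), 4, 3)
  z <- rm_anova(same)
  expect_equal(z$F, 0)
  expect_equal(z$p, 1)
})

test_that("partial eta squared identity holds for random tables", {
  emgnarx:::with_seed(99, {
    for (rep in 1:20) {
      x <- matrix(stats::rnorm(5 * 4, mean = 90, sd = 3), 5, 4)
      a <- rm_anova(x)
      expect_equal(a$partial_eta_sq,
                   a$F * a$df1 / (a$F * a$df1 + a$df2),
                   tolerance = 1e-10)
    }
  })
})

test_that("Bonferroni pairwise comparisons multiply and cap", {
  emgnarx:::with_seed(2, {
    x <- matrix(stats::rnorm(8 * 3, mean = 95), 8, 3)
    pw <- bonferroni_pairwise(x)
    expect_identical(nrow(pw), 3L)
    expect_equal(pw$p_adj, pmin(1, pw$p * 3))
    # raw p recomputed independently per pair
    p12 <- stats::t.test(x[, 1] - x[, 2])$p.value
    expect_equal(pw$p[1], p12, tolerance = 1e-12)
  })
  # identical conditions are degenerate with p_adj = 1
  same <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  pw0 <- bonferroni_pairwise(same)
  expect_true(all(pw0$degenerate))
  expect_true(all(pw0$p_adj == 1))
})

test_that("cross-validation produces a well-formed, reproducible report", {
  cfg <- narx_config()
  trial <- preprocess_trial(generate_trial(short_plant(duration_s = 40)))
  opts <- fast_opts(seed = 1)
  cv <- cross_validate(cfg, trial, opts, mode = "teacher_forced")
  expect_identical(dim(cv$vaf_table), c(5L, 3L))
  expect_true(all(cv$vaf_table <= 100))
  expect_false(anyNA(cv$vaf_table))
  cv2 <- cross_validate(cfg, trial, opts, mode = "teacher_forced")
  expect_identical(cv$vaf_table, cv2$vaf_table)
})

test_that("prediction interval grid maps onto embedding lags", {
  trial <- preprocess_trial(generate_trial(short_plant(duration_s = 40)))
  expect_error(
    sweep_prediction_interval(narx_config(), trial, intervals_ms = 75,
                              options = fast_opts()),
    class = "emgnarx_parameter_error")
})
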