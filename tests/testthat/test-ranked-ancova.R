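test_that("quartile groups share ties and label low adherence as 1", {
  g <- quartile_groups(2:25)
  expect_equal(sort(unique(g)), 1:4)
  expect_true(all(diff(g[order(2:25)]) >= 0))  # monotone labelling
  # heavy ties at a cut-point stay together
  scores <- c(rep(10, 6), rep(12, 10), rep(14, 4))
  g2 <- quartile_groups(scores)
  expect_true(all(tapply(g2, scores, function(x) length(unique(x))) == 1L))
  expect_gt(max(table(g2)), min(table(g2)))  # unequal sizes
  expect_error(quartile_groups(integer(0)), "empty")
})

test_that("all-equal scores collapse to one group and the ANCOVA refuses it", {
  g <- quartile_groups(rep(14, 40))
  expect_identical(unique(g), 4L)
  d <- make_analysis_frame(y = withr_seed(1, rnorm(40)), g = g)
  expect_error(quade_ancova(d, "model1"), "fewer than 2 occupied groups")
})

test_that("identical outcome and covariate multisets across groups give F = 0", {
  y <- rep(c(3, 1, 4, 1, 5, 9), 2)
  covars <- data.frame(age = rep(c(42, 48, 54, 60, 42, 48), 2),
                       exam_year = rep(c(1984, 1985, 1986, 1987, 1988, 1989), 2),
                       energy_kj = rep(c(9000, 9500, 10000, 8000, 8500, 9200), 2))
  d <- make_analysis_frame(y, g = rep(1:2, each = 6), covars = covars)
  out <- quade_ancova(d, "model1")
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)
})

test_that("without covariates the statistic equals one-way ANOVA on ranks", {
  y <- c(7, 3, 9, 5, 4, 8, 2, 6, 10, 12, 1, 11)
  g <- rep(1:3, each = 4)
  d <- make_analysis_frame(y, g)
  ours <- quade_ancova(d, model = "none")
  ref <- anova(lm(rank(y) ~ factor(g)))
  expect_equal(ours$statistic, ref[["F value"]][1], tolerance = 1e-12)
  expect_equal(ours$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-12)
  expect_equal(ours$df, c(2L, 9L))
})

test_that("the 16-observation instance reproduces the brute-force oracle value", {
  # frozen from an independent step-by-step computation (explicit
  # mid-ranks, normal equations, residual ANOVA) of this exact dataset
  y <- c(7, 3, 9, 5, 4, 8, 2, 6, 10, 12, 1, 11, 14, 13, 16, 15)
  x <- c(2.0, 1.5, 3.0, 2.5, 1.0, 4.0, 0.5, 3.5, 5.0, 6.0, 0.2, 5.5,
         7.0, 6.5, 8.0, 7.5)
  g <- rep(1:4, each = 4)
  d <- data.frame(hpl_total = y, hnds_quartile = g, activity = x)
  ours <- quade_ancova(d, covariates = "activity")
  expect_equal(ours$statistic, 0.619210318824, tolerance = 1e-10)
  expect_equal(ours$p_value, 0.615836205030, tolerance = 1e-10)
  expect_equal(ours$df, c(3L, 12L))
})

test_that("constant covariates are reported as collinear", {
  y <- withr_seed(2, rnorm(24))
  d <- make_analysis_frame(y, g = rep(1:4, each = 6))
  d$energy_kj <- 9500  # constant -> collinear with the intercept
  expect_error(quade_ancova(d, "model1"), "energy_kj")
})

test_that("the rank test is invariant to strictly monotone outcome transforms", {
  coh <- score_cohort(generate_cohort(synthetic_config(300, seed = 14)))
  base <- quade_ancova(coh, "model1")
  for (f in list(function(y) exp(y / 4), function(y) 3 * y + 11,
                 function(y) y^3)) {
    tr <- coh
    tr$hpl_total <- f(as.numeric(coh$hpl_total))
    out <- quade_ancova(tr, "model1")
    expect_equal(out$statistic, base$statistic, tolerance = 1e-12)
  }
})

test_that("adjusted means equal raw means under an orthogonal design", {
  base_cov <- data.frame(age = c(42, 48, 54, 60, 42, 48),
                         exam_year = c(1984, 1985, 1986, 1987, 1988, 1989),
                         energy_kj = c(9000, 9500, 10000, 8000, 8500, 9200))
  covars <- base_cov[rep(1:6, times = 4), ]   # identical per group
  y <- withr_seed(3, rnorm(24, mean = rep(c(2, 1.5, 1.2, 1), each = 6)))
  d <- make_analysis_frame(y, g = rep(1:4, each = 6), covars = covars)
  out <- adjusted_means(d, "model1")
  raw <- tapply(y, rep(1:4, each = 6), mean)
  expect_equal(out$adjusted_means$estimate, as.numeric(raw), tolerance = 1e-10)
})

test_that("adjusted means agree with emmeans on a noisy unbalanced instance", {
  skip_if_not_installed("emmeans")
  n <- 160
  g <- withr_seed(8, sample(1:4, n, TRUE, prob = c(0.4, 0.25, 0.2, 0.15)))
  y <- withr_seed(9, rnorm(n, mean = 2 - 0.2 * g))
  d <- make_analysis_frame(y, g, seed = 10)
  ours <- adjusted_means(d, "model1")
  fit <- lm(hpl_total ~ factor(hnds_quartile) + age + exam_year + energy_kj,
            data = d)
  em <- as.data.frame(emmeans::emmeans(fit, "hnds_quartile"))
  expect_equal(ours$adjusted_means$estimate, em$emmean, tolerance = 1e-8)
  expect_equal(ours$adjusted_means$ci_low, em$lower.CL, tolerance = 1e-8)
})

test_that("the extreme-quartile difference is antisymmetric in group order", {
  coh <- score_cohort(generate_cohort(synthetic_config(500, seed = 16)))
  a <- adjusted_means(coh, "model1")
  rev_coh <- coh
  rev_coh$hnds_quartile <- 5L - coh$hnds_quartile
  b <- adjusted_means(rev_coh, "model1")
  expect_equal(a$extreme_diff$estimate, -b$extreme_diff$estimate,
               tolerance = 1e-10)
})

test_that("the extreme-quartile contrast recovers a built-in effect", {
  n <- 20000
  g <- withr_seed(20, sample(1:4, n, TRUE))
  offsets <- c(0.4, 0.2, 0.1, 0)
  y <- withr_seed(21, offsets[g] + rnorm(n))
  d <- make_analysis_frame(y, g, seed = 22)
  out <- adjusted_means(d, "model1")
  se <- (out$extreme_diff$ci_high - out$extreme_diff$ci_low) / (2 * 1.96)
  expect_lt(abs(out$extreme_diff$estimate - 0.4), 3 * se)
  # and the trend test flags the monotone gradient decisively
  expect_lt(trend_test(d, "model1")$p_value, 0.001)
})

test_that("a perfect linear gradient gives an extreme trend p-value", {
  n <- 80
  g <- rep(1:4, each = 20)
  covars <- make_analysis_frame(rep(0, n), g, seed = 23)[, -(1:2)]
  y <- g + withr_seed(24, rnorm(n, sd = 0.01))
  d <- cbind(data.frame(hpl_total = y, hnds_quartile = g), covars)
  out <- trend_test(d, model = "none")
  expect_gt(out$slope, 0)
  expect_lt(out$p_value, 1e-20)
})

test_that("covariate imputation follows the cohort rules and logs counts", {
  d <- data.frame(ltpa_kj = c(100, 200, NA),
                  marital = c("couple", "couple", "other"),
                  age = 1:3, exam_year = 1984:1986,
                  energy_kj = c(1, 2, 3), ses = c(1, 2, 3),
                  smoking = rep("never", 3))
  out <- impute_covariates(d)
  expect_equal(out$data$ltpa_kj[3], 150)
  expect_equal(out$log$ltpa_imputed, 1L)

  d2 <- data.frame(ltpa_kj = 1:4,
                   marital = c("couple", "couple", "other", NA),
                   age = 1:4, exam_year = rep(1984, 4),
                   energy_kj = 1:4, ses = 1:4, smoking = rep("never", 4))
  out2 <- impute_covariates(d2)
  expect_equal(out2$data$marital[4], "couple")
  expect_equal(out2$log$marital_imputed, 1L)

  # identity when complete
  out3 <- impute_covariates(out2$data)
  expect_identical(out3$data, out2$data)
  expect_equal(out3$log$ltpa_imputed + out3$log$marital_imputed, 0L)

  # covariates without a stated rule must not be silently imputed
  d4 <- d2
  d4$ses[1] <- NA
  expect_error(impute_covariates(d4), "ses")
})
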