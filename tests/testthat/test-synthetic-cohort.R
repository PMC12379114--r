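test_that("zero participants give an empty cohort without error", {
  coh <- generate_cohort(synthetic_config(n_participants = 0, seed = 1))
  expect_s3_class(coh, "data.frame")
  expect_identical(nrow(coh), 0L)
  expect_true(all(hnds:::hnds_intake_cols() %in% names(coh)))
})

test_that("the same seed and config reproduce a bit-identical cohort", {
  cfg <- synthetic_config(n_participants = 250, seed = 77)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- synthetic_config(n_participants = 250, seed = 78)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(synthetic_config(n_participants = -1), "n_participants")
  expect_error(synthetic_config(age_weights = c(0.5, 0.5, 0.2, 0.2)),
               "age_weights")
  expect_error(synthetic_config(age_levels = c(42, 50, 54, 60)), "age_levels")
  expect_error(synthetic_config(effect_size = 2), "effect_size")
  expect_error(synthetic_config(item_difficulties = rep(0, 17)),
               "item_difficulties")
  bad <- default_intake_distributions()
  bad$fish$sdlog <- -1
  expect_error(synthetic_config(intake_distributions = bad),
               "intake_distributions\\$fish")
  expect_error(synthetic_config(missingness_rates = list(ltpa = 1.2,
                                                         marital = 0, block = 0)),
               "missingness_rates\\$ltpa")
})

test_that("generated marginals match the configured ones at n = 5000", {
  cfg <- synthetic_config(n_participants = 5000, seed = 31)
  coh <- generate_cohort(cfg)
  n <- nrow(coh)
  cp <- cfg$covariate_params
  # continuous covariates: mean within 3 standard errors
  expect_lt(abs(mean(coh$ltpa_kj) - cp$ltpa$mean), 3 * cp$ltpa$sd / sqrt(n))
  expect_lt(abs(mean(coh$ses) - cp$ses$mean), 3 * cp$ses$sd / sqrt(n))
  expect_lt(abs(sd(coh$ses) - cp$ses$sd), 0.15)
  # categorical marginals within 3 binomial standard errors
  for (lev in names(cp$smoking$probs)) {
    p <- cp$smoking$probs[[lev]]
    expect_lt(abs(mean(coh$smoking == lev) - p), 3 * sqrt(p * (1 - p) / n))
  }
  p <- cp$marital$probs[["couple"]]
  expect_lt(abs(mean(coh$marital == "couple") - p), 3 * sqrt(p * (1 - p) / n))
  # all intakes positive, fat E% inside [0, 100]
  expect_true(all(as.matrix(coh[, hnds:::hnds_intake_cols()]) >= 0))
  expect_true(all(coh$total_fat > 0 & coh$total_fat < 100))
  expect_true(all(coh$age %in% c(42, 48, 54, 60)))
  expect_true(all(coh$exam_year %in% 1984:1989))
})

test_that("a zero effect size leaves diet factor and HPL total uncorrelated", {
  cfg <- synthetic_config(n_participants = 5000, seed = 13, effect_size = 0)
  coh <- score_hpl(generate_cohort(cfg))
  r <- cor(coh$diet_factor, coh$hpl_total)
  # null sampling band for a correlation at this n, plus a permutation check
  expect_lt(abs(r), 3 / sqrt(nrow(coh)))
  perm <- withr_seed(99, replicate(200, cor(coh$diet_factor,
                                            sample(coh$hpl_total))))
  expect_gt(mean(abs(perm) >= abs(r)), 0.01)
})

test_that("a negative effect size gives non-increasing HPL means across quartiles", {
  cfg <- synthetic_config(n_participants = 20000, seed = 21)
  coh <- score_cohort(generate_cohort(cfg))
  m <- tapply(coh$hpl_total, coh$hnds_quartile, mean)
  expect_true(all(diff(m) <= 0.05))  # Monte-Carlo tolerance
  expect_lt(m[[4]], m[[1]])
})

test_that("missingness injection honours its rates", {
  cfg <- synthetic_config(n_participants = 300, seed = 3,
                          missingness_rates = list(ltpa = 0, marital = 0,
                                                   block = 0))
  coh <- generate_cohort(cfg)
  expect_identical(inject_missingness(coh, cfg), coh)

  cfg_all <- synthetic_config(n_participants = 300, seed = 3,
                              missingness_rates = list(ltpa = 1, marital = 0,
                                                       block = 0))
  expect_true(all(is.na(inject_missingness(coh, cfg_all)$ltpa_kj)))

  bad <- cfg
  bad$missingness_rates$block <- 1.5
  expect_error(inject_missingness(coh, bad), "\\[0, 1\\]")
})

test_that("block missingness excludes about 79 of 2682 as configured", {
  counts <- vapply(1:3, function(s) {
    cfg <- synthetic_config(n_participants = 2682, seed = s)
    raw <- inject_missingness(generate_cohort(cfg), cfg)
    apply_exclusions(raw)$excluded
  }, numeric(1))
  # binomial Monte-Carlo band: 79 +- 3 * sqrt(2682 * p * (1 - p)) ~ +- 26
  expect_true(all(abs(counts - 79) <= 26))
})

test_that("cohort CSV round-trips including missing cells", {
  cfg <- synthetic_config(n_participants = 40, seed = 12)
  coh <- inject_missingness(generate_cohort(cfg), cfg)
  coh$ltpa_kj[5] <- NA
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$ltpa_kj, coh$ltpa_kj)
  expect_equal(back$smoking, coh$smoking)
  expect_equal(back[, hnds:::hnds_hpl_cols()], coh[, hnds:::hnds_hpl_cols()])
  unlink(path)
})

test_that("config YAML round-trips and validates", {
  cfg <- synthetic_config(n_participants = 123, seed = 5, effect_size = -0.2)
  path <- tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  back <- read_synthetic_config(path)
  expect_equal(back$n_participants, 123)
  expect_equal(back$effect_size, -0.2)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
  unlink(path)
})
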