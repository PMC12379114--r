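# Fixtures built in code: a hand-scored 8-participant cohort and a
# builder for analysis frames with the covariate columns the ANCOVA
# models expect.

# Eight participants whose component ranks are aligned: participant i has
# the i-th smallest value of every positive component, the i-th largest
# of both negative components, and ethanol 25 g/d (i <= 4) or 5 g/d
# (i >= 5). Hand-derived quartile points per component are
# 0,0,1,1,2,2,3,3 for all eight quartile-scored components, so totals are
# 8 * (0,0,1,1,2,2,3,3) + alcohol points.
make_score_fixture <- function() {
  i <- 1:8
  data.frame(
    id = i,
    fruits_berries = 10 * i,
    vegetables = 10 * i,
    cereals = 10 * i,
    lowfat_milk = 10 * i,
    fish = 10 * i,
    meat_products = 90 - 10 * i,
    total_fat = 50 - 2 * i,
    pufa = 2 * i, sfa = rep(10, 8), tfa = rep(2, 8),
    ethanol = c(rep(25, 4), rep(5, 4))
  )
}

score_fixture_expected_totals <- function() c(0L, 0L, 8L, 8L, 17L, 17L, 25L, 25L)

# Analysis frame with outcome, quartile labels and covariates; covariates
# are drawn independently of y and g unless supplied.
make_analysis_frame <- function(y, g, seed = 1, covars = NULL) {
  n <- length(y)
  d <- data.frame(hpl_total = y, hnds_quartile = g)
  if (is.null(covars)) {
    covars <- withr_seed(seed, data.frame(
      age = sample(c(42, 48, 54, 60), n, TRUE),
      exam_year = sample(1984:1989, n, TRUE),
      energy_kj = rlnorm(n, log(9500), 0.2),
      ltpa_kj = rlnorm(n, 7, 0.8),
      ses = rnorm(n, 8.5, 4),
      smoking = sample(c("never", "previous", "current"), n, TRUE),
      marital = sample(c("couple", "other"), n, TRUE, prob = c(0.87, 0.13))
    ))
  }
  cbind(d, covars)
}

# run expr under a local seed without touching the session RNG stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent mid-rank implementation for oracle computations
oracle_midrank <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  r[o] <- seq_along(v)
  for (val in unique(v)) r[v == val] <- mean(r[v == val])
  r
}
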