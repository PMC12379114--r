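#' Default per-component intake distributions
#'
#' Log-normal location/scale parameters (and diet-factor loadings) for the
#' nine score components plus the fatty-acid intakes that form the
#' PUFA/(SFA+TFA) ratio. Units are g/d except `total_fat`, which is a
#' logit-normal fraction of energy intake expressed in E%. Locations are
#' plausible 4-day food-diary means for middle-aged Finnish men of the
#' 1980s; loadings were calibrated once by simulation so that the derived
#' diet score has a standard deviation near 4 points, and are frozen here.
#'
#' @return Named list of parameter lists, one per component.
#' @export
default_intake_distributions <- function() {
  list(
    fruits_berries = list(meanlog = log(120), sdlog = 0.80, loading = 0.31),
    vegetables     = list(meanlog = log(110), sdlog = 0.60, loading = 0.31),
    cereals        = list(meanlog = log(220), sdlog = 0.45, loading = 0.31),
    lowfat_milk    = list(meanlog = log(300), sdlog = 1.00, loading = 0.31),
    fish           = list(meanlog = log(40),  sdlog = 0.90, loading = 0.31),
    meat_products  = list(meanlog = log(130), sdlog = 0.50, loading = -0.31),
    pufa           = list(meanlog = log(11),  sdlog = 0.35, loading = 0.25),
    sfa            = list(meanlog = log(45),  sdlog = 0.30, loading = -0.25),
    tfa            = list(meanlog = log(2.5), sdlog = 0.35, loading = -0.25),
    ethanol        = list(meanlog = log(8),   sdlog = 1.09, loading = -0.30),
    # logit-normal on the E% scale: total_fat = 100 * plogis(mu + sigma * z)
    total_fat      = list(mu = qlogis(0.38), sigma = 0.22, loading = -0.31)
  )
}

#' Default HPL item intercepts
#'
#' Intercepts of the logistic item model on the depression-liability scale,
#' ordered from the most commonly endorsed symptom (e.g. loss of energy) to
#' the rarest. Together with the discrimination they were calibrated once by
#' simulation against the printed marginal HPL summary statistics (mean 1.9,
#' SD 2.1, prevalence of totals >= 5 near 11 %) and then frozen.
#'
#' @return Numeric vector of 18 intercepts.
#' @export
default_item_difficulties <- function() {
  seq(-1.26, -4.71, length.out = 18)
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of the synthetic-cohort model: sample size, the
#' RNG seed, marginal distributions of intakes and covariates, the latent
#' diet-depression effect size, HPL item parameters, and missingness rates.
#' Defaults are calibrated to the cohort the analysis emulates: 2603 men
#' aged 42--60 examined 1984--1989, mean diet score ~12.8 (SD ~4), mean HPL
#' ~1.9 (SD ~2.1), depressive-symptom prevalence ~11 %.
#'
#' @param n_participants Number of men to simulate (>= 0).
#' @param seed Master integer seed; all draws derive substreams from it.
#' @param age_levels Permitted ages at examination (years).
#' @param age_weights Sampling weights for `age_levels` (sum to 1).
#' @param exam_year_range Inclusive integer range of examination years.
#' @param intake_distributions Per-component parameter list, see
#'   [default_intake_distributions()].
#' @param energy_intake Log-normal parameters of total energy intake (kJ/d).
#' @param covariate_params Means/SDs, category probabilities and
#'   diet-factor loadings for the covariates (leisure-time physical
#'   activity in kJ/d, socio-economic status points where higher = lower
#'   status, smoking, marital status, BMI, disease history indicators).
#' @param effect_size Standardised association between the latent diet
#'   factor and depression liability; <= 0 reproduces the direction the
#'   analysis expects (healthier diet, fewer symptoms).
#' @param liability_confounding Named numeric: direct paths from smoking
#'   (current), SES and marital status (other) into the liability, all 0 by
#'   default so that `effect_size = 0` implies independence of diet factor
#'   and symptoms.
#' @param item_difficulties 18 intercepts of the HPL item model.
#' @param item_discrimination Common slope of items on the liability.
#' @param missingness_rates Per-variable missing probabilities: `ltpa`,
#'   `marital` (cell-level) and `block` (joint diet/HPL block missingness,
#'   the exclusion mechanism).
#'
#' @return An object of class `hnds_synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_participants = 200, seed = 42)
#' cohort <- generate_cohort(cfg)
#' @export
synthetic_config <- function(n_participants = 2603L,
                             seed = 1L,
                             age_levels = c(42L, 48L, 54L, 60L),
                             age_weights = c(0.06, 0.29, 0.35, 0.30),
                             exam_year_range = c(1984L, 1989L),
                             intake_distributions = default_intake_distributions(),
                             energy_intake = list(meanlog = log(9500), sdlog = 0.22),
                             covariate_params = list(
                               ltpa    = list(mean = 1300, sd = 1100, loading = 0.25),
                               ses     = list(mean = 8.5, sd = 4.2, loading = -0.20),
                               smoking = list(probs = c(never = 0.350, previous = 0.333,
                                                        current = 0.317),
                                              loading = -0.30),
                               marital = list(probs = c(couple = 0.869, other = 0.131),
                                              loading = 0.25),
                               bmi     = list(mean = 26.8, sd = 3.6),
                               cvd_history    = list(prob = 0.360),
                               mental_illness = list(prob = 0.055)
                             ),
                             effect_size = -0.10,
                             liability_confounding = c(smoking_current = 0,
                                                       ses = 0,
                                                       marital_other = 0),
                             item_difficulties = default_item_difficulties(),
                             item_discrimination = 1.19,
                             missingness_rates = list(ltpa = 8 / 2682,
                                                      marital = 2 / 2682,
                                                      block = 79 / 2682)) {
  cfg <- list(
    n_participants = n_participants, seed = seed,
    age_levels = age_levels, age_weights = age_weights,
    exam_year_range = exam_year_range,
    intake_distributions = intake_distributions,
    energy_intake = energy_intake,
    covariate_params = covariate_params,
    effect_size = effect_size,
    liability_confounding = liability_confounding,
    item_difficulties = item_difficulties,
    item_discrimination = item_discrimination,
    missingness_rates = missingness_rates
  )
  class(cfg) <- "hnds_synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid synthetic config: field '", field, "' ", msg, call. = FALSE)
  }
  if (!is.numeric(cfg$n_participants) || length(cfg$n_participants) != 1L ||
      is.na(cfg$n_participants) || cfg$n_participants < 0 ||
      cfg$n_participants != trunc(cfg$n_participants)) {
    fail("n_participants", "must be a single non-negative integer")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  if (!all(cfg$age_levels %in% c(42L, 48L, 54L, 60L))) {
    fail("age_levels", "must be a subset of {42, 48, 54, 60}")
  }
  if (length(cfg$age_weights) != length(cfg$age_levels) ||
      any(cfg$age_weights < 0) || abs(sum(cfg$age_weights) - 1) > 1e-9) {
    fail("age_weights", "must be non-negative and sum to 1 (within 1e-9)")
  }
  yr <- cfg$exam_year_range
  if (length(yr) != 2L || yr[1] > yr[2] || yr[1] < 1984L || yr[2] > 1989L) {
    fail("exam_year_range", "must be an increasing range within 1984-1989")
  }
  needed <- c(hnds_intake_cols())
  miss <- setdiff(needed, names(cfg$intake_distributions))
  if (length(miss)) {
    fail("intake_distributions", paste("lacks component(s):",
                                       paste(miss, collapse = ", ")))
  }
  for (nm in names(cfg$intake_distributions)) {
    p <- cfg$intake_distributions[[nm]]
    sc <- if (nm == "total_fat") p$sigma else p$sdlog
    if (is.null(sc) || !is.finite(sc) || sc <= 0) {
      fail(paste0("intake_distributions$", nm), "scale parameter must be > 0")
    }
    if (is.null(p$loading) || abs(p$loading) >= 1) {
      fail(paste0("intake_distributions$", nm), "loading must be in (-1, 1)")
    }
  }
  if (!is.finite(cfg$energy_intake$sdlog) || cfg$energy_intake$sdlog <= 0) {
    fail("energy_intake", "sdlog must be > 0")
  }
  for (nm in c("ltpa", "ses")) {
    p <- cfg$covariate_params[[nm]]
    if (is.null(p) || !is.finite(p$sd) || p$sd <= 0) {
      fail(paste0("covariate_params$", nm), "sd must be > 0")
    }
  }
  for (nm in c("smoking", "marital")) {
    pr <- cfg$covariate_params[[nm]]$probs
    if (is.null(pr) || any(pr < 0) || abs(sum(pr) - 1) > 1e-9) {
      fail(paste0("covariate_params$", nm),
           "category probabilities must be non-negative and sum to 1 (within 1e-9)")
    }
  }
  if (!is.finite(cfg$effect_size) || abs(cfg$effect_size) > 1) {
    fail("effect_size", "must be a finite value in [-1, 1]")
  }
  if (length(cfg$item_difficulties) != 18L ||
      any(!is.finite(cfg$item_difficulties))) {
    fail("item_difficulties", "must be 18 finite intercepts")
  }
  if (!is.finite(cfg$item_discrimination) || cfg$item_discrimination < 0) {
    fail("item_discrimination", "must be >= 0")
  }
  for (nm in names(cfg$missingness_rates)) {
    r <- cfg$missingness_rates[[nm]]
    if (!is.finite(r) || r < 0 || r > 1) {
      fail(paste0("missingness_rates$", nm), "must lie in [0, 1]")
    }
  }
  invisible(cfg)
}

#' Read or write a synthetic-cohort configuration
#'
#' Configurations are stored as nested YAML so runs are reproducible from a
#' plain-text file.
#'
#' @param cfg A `hnds_synthetic_config`.
#' @param path File path.
#' @return `read_synthetic_config()` returns a validated
#'   `hnds_synthetic_config`; `write_synthetic_config()` returns `path`
#'   invisibly.
#' @export
write_synthetic_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hnds_synthetic_config"))
  x <- unclass(cfg)
  # yaml drops names of atomic vectors; store named vectors as maps
  x$liability_confounding <- as.list(cfg$liability_confounding)
  for (nm in c("smoking", "marital")) {
    x$covariate_params[[nm]]$probs <- as.list(cfg$covariate_params[[nm]]$probs)
  }
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- synthetic_config()
  cfg <- utils::modifyList(unclass(defaults), raw)
  # yaml drops names of length-one vectors; restore required shapes
  cfg$liability_confounding <- unlist(cfg$liability_confounding)
  for (nm in c("smoking", "marital")) {
    cfg$covariate_params[[nm]]$probs <- unlist(cfg$covariate_params[[nm]]$probs)
  }
  cfg$item_difficulties <- as.numeric(unlist(cfg$item_difficulties))
  class(cfg) <- "hnds_synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}
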