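#' Generate a synthetic cohort
#'
#' Simulates a cross-sectional cohort of middle-aged men with the joint
#' structure the downstream analysis assumes. One standard-normal latent
#' diet-quality factor per participant drives correlated 4-day mean
#' component intakes (positive loadings on fruits/berries, vegetables,
#' cereals, low-fat milk, fish and PUFA; negative on meat products, total
#' fat, SFA, TFA and ethanol). A depression liability equal to
#' `effect_size` times the diet factor plus independent noise drives the
#' 18 HPL items through a logistic item model. Covariates are drawn with
#' their configured marginals; smoking, SES, marital status and physical
#' activity are coupled to the diet factor by Gaussian-copula loadings so
#' the usual confounding gradients appear across diet-score quartiles.
#'
#' All randomness derives from `config$seed` through named substreams, so
#' the same seed and config give a bit-identical cohort and adding a new
#' variable to the generator cannot perturb existing columns.
#'
#' @param config A [synthetic_config()] object.
#' @return A `data.frame` (one row per participant) with columns `id`,
#'   `age`, `exam_year`, `energy_kj`, `ltpa_kj`, `ses`, `smoking`,
#'   `marital`, `bmi`, `cvd_history`, `mental_illness`, the eleven intake
#'   columns (g/d; `total_fat` in E%), `hpl_01` .. `hpl_18`, and the
#'   latent `diet_factor` and `liability` (kept for calibration checks;
#'   an analysis of real data would not have them).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_participants = 100, seed = 7))
#' nrow(cohort)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "hnds_synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  validate_synthetic_config(config)
  n <- as.integer(config$n_participants)
  seed <- config$seed
  if (n == 0L) return(empty_cohort())

  d <- with_substream(seed, "diet_factor", rnorm(n))

  # intakes: lognormal (logit-normal for total fat E%) sharing the factor
  intakes <- lapply(hnds_intake_cols(), function(nm) {
    p <- config$intake_distributions[[nm]]
    lam <- p$loading
    e <- with_substream(seed, paste0("intake_", nm), rnorm(n))
    z <- lam * d + sqrt(1 - lam^2) * e
    if (nm == "total_fat") {
      100 * plogis(p$mu + p$sigma * z)
    } else {
      exp(p$meanlog + p$sdlog * z)
    }
  })
  names(intakes) <- hnds_intake_cols()

  age <- with_substream(seed, "age",
                        sample(config$age_levels, n, replace = TRUE,
                               prob = config$age_weights))
  exam_year <- with_substream(seed, "exam_year",
                              sample(seq(config$exam_year_range[1],
                                         config$exam_year_range[2]),
                                     n, replace = TRUE))
  energy_kj <- with_substream(seed, "energy",
                              rlnorm(n, config$energy_intake$meanlog,
                                     config$energy_intake$sdlog))

  cp <- config$covariate_params
  # LTPA: lognormal moment-matched to the configured mean/SD, coupled to
  # the diet factor (higher adherence, more active leisure time)
  sdl2 <- log(1 + (cp$ltpa$sd / cp$ltpa$mean)^2)
  lam <- cp$ltpa$loading
  e <- with_substream(seed, "ltpa", rnorm(n))
  ltpa_kj <- exp(log(cp$ltpa$mean) - sdl2 / 2 +
                 sqrt(sdl2) * (lam * d + sqrt(1 - lam^2) * e))

  lam <- cp$ses$loading
  e <- with_substream(seed, "ses", rnorm(n))
  ses <- cp$ses$mean + cp$ses$sd * (lam * d + sqrt(1 - lam^2) * e)

  # categorical covariates via a Gaussian copula so marginals match the
  # configured probabilities exactly while correlating with the factor
  smoking <- copula_categorical(seed, "smoking", d, cp$smoking$loading,
                                cp$smoking$probs)
  marital <- copula_categorical(seed, "marital", d, cp$marital$loading,
                                cp$marital$probs)

  bmi <- with_substream(seed, "bmi", rnorm(n, cp$bmi$mean, cp$bmi$sd))
  cvd_history <- with_substream(seed, "cvd", rbinom(n, 1L, cp$cvd_history$prob))
  mental_illness <- with_substream(seed, "mental",
                                   rbinom(n, 1L, cp$mental_illness$prob))

  # depression liability: effect_size * diet factor (+ optional direct
  # confounder paths) + independent noise
  es <- config$effect_size
  gam <- config$liability_confounding
  eps <- with_substream(seed, "liability", rnorm(n))
  liability <- es * d + sqrt(max(0, 1 - es^2)) * eps
  if (any(gam != 0)) {
    liability <- liability +
      gam[["smoking_current"]] * (smoking == "current") +
      gam[["ses"]] * as.numeric(scale(ses)) +
      gam[["marital_other"]] * (marital == "other")
  }

  b <- config$item_discrimination
  a <- config$item_difficulties
  u <- with_substream(seed, "hpl_items", matrix(runif(n * 18L), n, 18L))
  items <- matrix(0L, n, 18L, dimnames = list(NULL, hnds_hpl_cols()))
  for (j in 1:18) {
    items[, j] <- as.integer(u[, j] < plogis(a[j] + b * liability))
  }

  out <- data.frame(id = seq_len(n), age = as.integer(age),
                    exam_year = as.integer(exam_year),
                    energy_kj = energy_kj, ltpa_kj = ltpa_kj, ses = ses,
                    smoking = smoking, marital = marital, bmi = bmi,
                    cvd_history = as.integer(cvd_history),
                    mental_illness = as.integer(mental_illness),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(intakes), as.data.frame(items))
  out$diet_factor <- d
  out$liability <- liability
  out
}

copula_categorical <- function(seed, name, d, loading, probs) {
  n <- length(d)
  e <- with_substream(seed, name, rnorm(n))
  u <- stats::pnorm(loading * d + sqrt(1 - loading^2) * e)
  cuts <- cumsum(probs)[-length(probs)]
  names(probs)[findInterval(u, cuts) + 1L]
}

empty_cohort <- function() {
  tmpl <- generate_template()
  tmpl[0L, , drop = FALSE]
}

generate_template <- function() {
  cols <- c("id", "age", "exam_year", "energy_kj", "ltpa_kj", "ses",
            "smoking", "marital", "bmi", "cvd_history", "mental_illness",
            hnds_intake_cols(), hnds_hpl_cols(), "diet_factor", "liability")
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  out$smoking <- character(0)
  out$marital <- character(0)
  out
}

#' Inject missing values into a cohort
#'
#' Applies the configured missingness mechanism: leisure-time physical
#' activity and marital status cells go missing independently at their
#' rates, and a configured fraction of participants loses the whole diet
#' block or the whole HPL item block jointly (the mechanism behind the
#' roster exclusions the pipeline applies).
#'
#' @param cohort A cohort `data.frame` from [generate_cohort()].
#' @param config A [synthetic_config()]; only `seed` and
#'   `missingness_rates` are used.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, config) {
  if (!inherits(config, "hnds_synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  rates <- config$missingness_rates
  for (nm in names(rates)) {
    if (!is.finite(rates[[nm]]) || rates[[nm]] < 0 || rates[[nm]] > 1) {
      stop("missingness rate '", nm, "' must lie in [0, 1]")
    }
  }
  n <- nrow(cohort)
  if (n == 0L) return(cohort)
  seed <- config$seed

  hit <- with_substream(seed, "miss_ltpa", runif(n)) < rates$ltpa
  cohort$ltpa_kj[hit] <- NA_real_
  hit <- with_substream(seed, "miss_marital", runif(n)) < rates$marital
  cohort$marital[hit] <- NA_character_

  blk <- with_substream(seed, "miss_block", runif(n)) < rates$block
  which_side <- with_substream(seed, "miss_block_side", runif(n)) < 0.5
  diet_rows <- blk & which_side
  hpl_rows <- blk & !which_side
  cohort[diet_rows, hnds_intake_cols()] <- NA_real_
  cohort[hpl_rows, hnds_hpl_cols()] <- NA_integer_
  cohort
}

#' Read or write a cohort CSV
#'
#' One row per participant; HPL items as `hpl_01` .. `hpl_18`; missing
#' values as empty fields.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort()` returns the cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  int_cols <- intersect(c("id", "age", "exam_year", "cvd_history",
                          "mental_illness", hnds_hpl_cols()), names(out))
  for (nm in int_cols) out[[nm]] <- as.integer(out[[nm]])
  out
}
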