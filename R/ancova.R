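#' Quartile exposure groups from diet-score totals
#'
#' Groups participants by within-cohort quartiles of the diet score using
#' the same convention as the component scoring (ties share a group, so
#' sizes are typically unequal because the score takes few integer
#' values). Label 1 is the lowest-adherence quartile.
#'
#' @param scores Integer diet-score totals.
#' @return Integer group labels 1--4.
#' @export
quartile_groups <- function(scores) {
  if (length(scores) == 0L) stop("quartile_groups: empty score vector")
  quartile_assign(scores)
}

# Covariate model matrices for the two adjustment sets. Model 1: age,
# examination year, energy intake. Model 2 adds leisure-time physical
# activity, SES, smoking (never as reference, two indicators) and marital
# status (couple as reference, one indicator).
ancova_covariates <- function(data, model = c("model2", "model1", "none")) {
  model <- match.arg(model)
  if (model == "none") return(NULL)
  require_columns(data, c("age", "exam_year", "energy_kj"), "ancova_covariates")
  X <- cbind(age = as.numeric(data$age),
             exam_year = as.numeric(data$exam_year),
             energy_kj = data$energy_kj)
  if (model == "model2") {
    require_columns(data, c("ltpa_kj", "ses", "smoking", "marital"),
                    "ancova_covariates")
    X <- cbind(X,
               ltpa_kj = data$ltpa_kj,
               ses = data$ses,
               smoking_previous = as.numeric(data$smoking == "previous"),
               smoking_current = as.numeric(data$smoking == "current"),
               marital_other = as.numeric(data$marital == "other"))
  }
  X
}

resolve_covariates <- function(data, model, covariates) {
  if (is.null(covariates)) return(ancova_covariates(data, model))
  require_columns(data, covariates, "ancova covariates")
  as.matrix(data[, covariates, drop = FALSE])
}

check_ancova_inputs <- function(y, g, X) {
  if (anyNA(y)) stop("outcome contains missing values; exclude or impute first")
  if (!is.null(X) && anyNA(X)) {
    stop("covariates contain missing values; run impute_covariates() first")
  }
  k <- length(unique(g))
  if (k < 2L) stop("degenerate design: fewer than 2 occupied groups")
  if (length(unique(y)) == 1L) {
    stop("degenerate design: constant outcome (all ranks tied)")
  }
  k
}

quade_residuals <- function(y, X) {
  ry <- rank(y)                       # mid-ranks for ties
  if (is.null(X) || ncol(X) == 0L) return(ry - mean(ry))
  RX <- apply(X, 2L, rank)
  qrx <- qr(cbind(1, RX))
  if (qrx$rank < ncol(RX) + 1L) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- setdiff(seq_len(ncol(RX) + 1L), keep) - 1L
    stop("rank-deficient ranked covariates; collinear column(s): ",
         paste(colnames(RX)[dropped], collapse = ", "))
  }
  qr.resid(qrx, ry)
}

#' Quade's non-parametric rank ANCOVA
#'
#' Compares an outcome across exposure groups adjusting for covariates
#' without distributional assumptions, appropriate for a right-skewed
#' symptom count. The procedure: (1) rank the outcome over all
#' participants (mid-ranks for ties); (2) rank each covariate the same
#' way; (3) regress outcome ranks on covariate ranks by least squares,
#' pooling all groups; (4) one-way ANOVA F test of the residuals across
#' groups, with (k - 1, N - k) degrees of freedom. With no covariates
#' this reduces exactly to one-way ANOVA on ranks.
#'
#' @param data Scored cohort `data.frame` containing the outcome, the
#'   group column and the covariates of the chosen model.
#' @param model Covariate set: `"model1"` (age, examination year, energy
#'   intake), `"model2"` (model 1 plus leisure-time physical activity,
#'   SES, smoking, marital status; the default), or `"none"`.
#' @param covariates Optional character vector of numeric covariate
#'   columns that overrides `model` (useful for non-standard adjustment
#'   sets).
#' @param outcome,group Column names of the outcome (HPL total) and the
#'   quartile label.
#' @return List with `statistic` (F), `p_value`, `df` (numerator,
#'   denominator) and `n`.
#' @examples
#' cohort <- score_cohort(generate_cohort(synthetic_config(400, seed = 1)))
#' quade_ancova(cohort, model = "model1")$p_value
#' @export
quade_ancova <- function(data, model = c("model2", "model1", "none"),
                         outcome = "hpl_total", group = "hnds_quartile",
                         covariates = NULL) {
  model <- match.arg(model)
  require_columns(data, c(outcome, group), "quade_ancova")
  y <- data[[outcome]]
  g <- data[[group]]
  X <- resolve_covariates(data, model, covariates)
  k <- check_ancova_inputs(y, g, X)
  res <- quade_residuals(y, X)
  quade_f_on_residuals(res, g, k)
}

quade_f_on_residuals <- function(res, g, k) {
  N <- length(res)
  gm <- tapply(res, g, mean)
  gn <- tapply(res, g, length)
  ssb <- sum(gn * (gm - mean(res))^2)
  ssw <- sum((res - gm[as.character(g)])^2)
  df1 <- k - 1L
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), n = N)
}

#' Covariate-adjusted quartile means with confidence intervals
#'
#' Parametric ANCOVA companion to [quade_ancova()]: ordinary least
#' squares of the raw outcome on quartile indicators plus covariates;
#' adjusted means are the fitted values for each quartile with every
#' covariate held at its sample mean, with normal-theory 95% intervals.
#' The extreme-quartile contrast is the adjusted mean of the
#' lowest-adherence quartile minus that of the highest (positive when low
#' adherence goes with more symptoms).
#'
#' @inheritParams quade_ancova
#' @param conf_level Confidence level for the intervals.
#' @return List with `adjusted_means` (data.frame: quartile, n, estimate,
#'   ci_low, ci_high) and `extreme_diff` (estimate, ci_low, ci_high,
#'   p_value).
#' @export
adjusted_means <- function(data, model = c("model2", "model1", "none"),
                           outcome = "hpl_total", group = "hnds_quartile",
                           conf_level = 0.95, covariates = NULL) {
  model <- match.arg(model)
  require_columns(data, c(outcome, group), "adjusted_means")
  y <- data[[outcome]]
  g <- factor(data[[group]])
  X <- resolve_covariates(data, model, covariates)
  check_ancova_inputs(y, g, X)

  M <- cbind(stats::model.matrix(~ g), X)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  fit <- stats::lm.fit(M, y)
  if (fit$rank < ncol(M)) stop("rank-deficient ANCOVA design matrix")
  beta <- fit$coefficients
  dfres <- length(y) - ncol(M)
  sigma2 <- sum(fit$residuals^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(M)))

  levs <- levels(g)
  xbar <- colMeans(X)
  # contrast row for each quartile: intercept + its dummy + covariate means
  rows <- lapply(levs, function(l) {
    z <- setNames(numeric(ncol(M)), colnames(M))
    z["(Intercept)"] <- 1
    dn <- paste0("g", l)
    if (dn %in% names(z)) z[dn] <- 1
    z[names(xbar)] <- xbar
    z
  })
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dfres)
  est <- vapply(rows, function(z) sum(z * beta), numeric(1))
  se <- vapply(rows, function(z) sqrt(sigma2 * drop(t(z) %*% XtXinv %*% z)),
               numeric(1))
  am <- data.frame(quartile = as.integer(levs),
                   n = as.integer(table(g)[levs]),
                   estimate = est, ci_low = est - tcrit * se,
                   ci_high = est + tcrit * se)

  cz <- rows[[1L]] - rows[[length(rows)]]
  cest <- sum(cz * beta)
  cse <- sqrt(sigma2 * drop(t(cz) %*% XtXinv %*% cz))
  tval <- cest / cse
  extreme <- list(estimate = cest,
                  ci_low = cest - tcrit * cse, ci_high = cest + tcrit * cse,
                  p_value = 2 * stats::pt(-abs(tval), dfres))
  list(adjusted_means = am, extreme_diff = extreme, df_residual = dfres)
}

#' Linear trend test across quartiles
#'
#' Within the Quade framework: outcome ranks are regressed on covariate
#' ranks, and the residuals are then regressed on the integer quartile
#' index (1--4); the two-sided t test of that slope is the trend p-value.
#'
#' @inheritParams quade_ancova
#' @return List with `slope`, `statistic` (t), `p_value`, `df`.
#' @export
trend_test <- function(data, model = c("model2", "model1", "none"),
                       outcome = "hpl_total", group = "hnds_quartile",
                       covariates = NULL) {
  model <- match.arg(model)
  require_columns(data, c(outcome, group), "trend_test")
  y <- data[[outcome]]
  g <- as.numeric(data[[group]])
  X <- resolve_covariates(data, model, covariates)
  check_ancova_inputs(y, g, X)
  res <- quade_residuals(y, X)
  fit <- stats::lm(res ~ g)
  s <- summary(fit)$coefficients
  list(slope = s["g", "Estimate"], statistic = s["g", "t value"],
       p_value = s["g", "Pr(>|t|)"], df = fit$df.residual)
}

#' Impute covariates by the cohort rules
#'
#' Missing leisure-time physical activity is replaced by the cohort mean
#' of the observed values; missing marital status by the most common
#' answer. These are the only covariates with an imputation rule; missing
#' values anywhere else in the adjustment sets raise an error. Rows used
#' here must already have complete exposure and outcome (exclusions are
#' the pipeline's job).
#'
#' @param data Cohort `data.frame`.
#' @return List with `data` (imputed) and `log` (named counts of imputed
#'   cells, and the imputed values used).
#' @export
impute_covariates <- function(data) {
  require_columns(data, c("ltpa_kj", "marital"), "impute_covariates")
  n_ltpa <- sum(is.na(data$ltpa_kj))
  ltpa_mean <- mean(data$ltpa_kj, na.rm = TRUE)
  if (n_ltpa > 0L) data$ltpa_kj[is.na(data$ltpa_kj)] <- ltpa_mean

  n_marital <- sum(is.na(data$marital))
  tab <- table(data$marital)
  mode_marital <- if (length(tab)) names(tab)[which.max(tab)] else NA_character_
  if (n_marital > 0L) data$marital[is.na(data$marital)] <- mode_marital

  others <- intersect(c("age", "exam_year", "energy_kj", "ses", "smoking"),
                      names(data))
  bad <- others[vapply(others, function(nm) anyNA(data[[nm]]), logical(1))]
  if (length(bad)) {
    stop("no imputation rule for covariate(s) with missing values: ",
         paste(bad, collapse = ", "))
  }
  list(data = data,
       log = list(ltpa_imputed = n_ltpa, ltpa_value = ltpa_mean,
                  marital_imputed = n_marital, marital_value = mode_marital))
}
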