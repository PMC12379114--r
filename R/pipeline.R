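#' Exclude participants with missing exposure or outcome data
#'
#' Removes records missing any dietary score component or any HPL item
#' (the whole outcome block counts as missing if any item is). Covariate
#' missingness is explicitly not an exclusion criterion: it is handled by
#' [impute_covariates()] downstream.
#'
#' @param cohort Cohort `data.frame`.
#' @return List with `cohort` (retained rows) and `excluded` (count).
#' @examples
#' cfg <- synthetic_config(n_participants = 300, seed = 5)
#' raw <- inject_missingness(generate_cohort(cfg), cfg)
#' apply_exclusions(raw)$excluded
#' @export
apply_exclusions <- function(cohort) {
  require_columns(cohort, c(hnds_intake_cols(), hnds_hpl_cols()),
                  "apply_exclusions")
  keep <- stats::complete.cases(cohort[, c(hnds_intake_cols(), hnds_hpl_cols())])
  list(cohort = cohort[keep, , drop = FALSE],
       excluded = sum(!keep))
}

#' Score a cohort end to end
#'
#' Convenience wrapper that adds the diet-score columns (nine component
#' points and `hnds_total`), the HPL columns (`hpl_total`, `hpl_case`)
#' and the exposure quartile (`hnds_quartile`) to a cohort with complete
#' exposure and outcome data.
#'
#' @param cohort Cohort `data.frame` after exclusions.
#' @return The scored `data.frame`.
#' @export
score_cohort <- function(cohort) {
  scores <- compute_hnds(cohort)
  cohort <- cbind(cohort, scores[, c(hnds_point_cols(), "hnds_total")])
  cohort <- score_hpl(cohort)
  if (anyNA(cohort$hpl_total)) {
    stop("score_cohort: missing HPL outcomes remain; apply exclusions first")
  }
  cohort$hnds_quartile <- quartile_groups(cohort$hnds_total)
  cohort
}

#' Configuration of a full study run
#'
#' @param mode `"synthetic"` (simulate the cohort) or `"csv"` (read it).
#' @param synthetic A [synthetic_config()] for synthetic mode.
#' @param csv_path Input cohort CSV for csv mode.
#' @param models Adjustment sets to fit (`"model1"`, `"model2"`).
#' @param taus Quantile levels for the quantile regression.
#' @param bootstrap_B Bootstrap replicates for quantile-regression CIs.
#' @param seed Seed for the analysis-stage randomness (bootstrap).
#' @param output_dir Directory for report files; created if needed.
#' @return An object of class `hnds_run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       synthetic = synthetic_config(
                         n_participants = 2682L),
                       csv_path = NULL,
                       models = c("model1", "model2"),
                       taus = c(0.33, 0.66),
                       bootstrap_B = 1000L,
                       seed = 1L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "csv" && (is.null(csv_path) || !file.exists(csv_path))) {
    stop("csv mode requires an existing csv_path")
  }
  stopifnot(all(models %in% c("model1", "model2")),
            all(taus > 0 & taus < 1), bootstrap_B >= 1)
  structure(list(mode = mode, synthetic = synthetic, csv_path = csv_path,
                 models = models, taus = taus, bootstrap_B = bootstrap_B,
                 seed = seed, output_dir = output_dir),
            class = "hnds_run_config")
}

#' Run the full study pipeline
#'
#' Executes the whole analysis deterministically given the seeds:
#' generate or read the cohort, inject missingness (synthetic mode),
#' apply exclusions, score the diet index and the HPL scale, impute
#' covariates, produce the descriptive table by quartile, fit Quade
#' ANCOVA / adjusted means / trend test for each requested model, repeat
#' model 2 on complete cases (sensitivity analysis), and fit the
#' quantile regressions on complete cases at each tau. If
#' `config$output_dir` is set, all tables are written as CSV together
#' with a run-metadata JSON and a plain-text log.
#'
#' @param config A [run_config()].
#' @return An object of class `hnds_study_report` (list): `exclusions`,
#'   `n_analysis`, `imputation_log`, `descriptives`, `ancova` (per
#'   model), `sensitivity`, `quantreg` (per tau), `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "hnds_run_config"))
  if (config$mode == "synthetic") {
    raw <- generate_cohort(config$synthetic)
    raw <- inject_missingness(raw, config$synthetic)
  } else {
    raw <- read_cohort(config$csv_path)
  }
  n_roster <- nrow(raw)

  excl <- tryCatch(apply_exclusions(raw),
                   error = function(e) stop("stage [exclusions]: ",
                                            conditionMessage(e), call. = FALSE))
  cohort <- tryCatch(score_cohort(excl$cohort),
                     error = function(e) stop("stage [scoring]: ",
                                              conditionMessage(e), call. = FALSE))
  complete_before <- stats::complete.cases(
    cohort[, c("ltpa_kj", "marital"), drop = FALSE])
  imp <- tryCatch(impute_covariates(cohort),
                  error = function(e) stop("stage [imputation]: ",
                                           conditionMessage(e), call. = FALSE))
  cohort <- imp$data

  desc <- tryCatch(descriptives_by_quartile(cohort),
                   error = function(e) stop("stage [descriptives]: ",
                                            conditionMessage(e), call. = FALSE))

  fit_model <- function(d, model) {
    list(model = model,
         quade = quade_ancova(d, model),
         means = adjusted_means(d, model),
         trend = trend_test(d, model))
  }
  ancova <- tryCatch(
    setNames(lapply(config$models, fit_model, d = cohort), config$models),
    error = function(e) stop("stage [ancova]: ", conditionMessage(e),
                             call. = FALSE))

  cc <- cohort[complete_before, , drop = FALSE]
  sensitivity <- tryCatch(
    fit_model(cc, "model2"),
    error = function(e) stop("stage [sensitivity]: ", conditionMessage(e),
                             call. = FALSE))
  sensitivity$n <- nrow(cc)

  quantreg <- tryCatch(
    setNames(lapply(config$taus, function(tau) {
      fit_quantile(cc, tau = tau, model = "model2",
                   B = config$bootstrap_B, seed = config$seed)
    }), paste0("tau_", config$taus)),
    error = function(e) stop("stage [quantreg]: ", conditionMessage(e),
                             call. = FALSE))
  fitted_q <- tryCatch(fitted_quantiles_at_means(quantreg, cc),
                       warning = function(w) {
                         suppressWarnings(fitted_quantiles_at_means(quantreg, cc))
                       })

  report <- list(
    exclusions = list(n_roster = n_roster, excluded = excl$excluded,
                      n_analysis = nrow(cohort)),
    n_analysis = nrow(cohort),
    quartile_sizes = as.integer(table(cohort$hnds_quartile)),
    imputation_log = imp$log,
    descriptives = desc,
    ancova = ancova,
    sensitivity = sensitivity,
    quantreg = quantreg,
    fitted_quantiles = fitted_q,
    provenance = list(seed = config$seed,
                      synthetic_seed = if (config$mode == "synthetic")
                        config$synthetic$seed else NA,
                      mode = config$mode,
                      config_hash = config_fingerprint(config),
                      package_version = as.character(
                        utils::packageVersion("hnds")))
  )
  class(report) <- "hnds_study_report"
  if (!is.null(config$output_dir)) write_report(report, cohort, config)
  report
}

config_fingerprint <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL   # where results land does not alter what they are
  txt <- yaml::as.yaml(lapply(x, function(el)
    if (inherits(el, "hnds_synthetic_config")) unclass(el) else el))
  sprintf("%08x", as.integer(fnv1a32(txt) %% 2147483648))
}

write_report <- function(report, cohort, config) {
  dir <- config$output_dir
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory ", dir)
  written <- character(0)
  emit <- function(obj, name) {
    path <- file.path(dir, name)
    utils::write.csv(obj, path, row.names = FALSE, na = "")
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    unlink(written)
    stop("stage [report]: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    emit(report$descriptives, "table2_descriptives.csv")
    for (m in names(report$ancova)) {
      a <- report$ancova[[m]]
      emit(a$means$adjusted_means, sprintf("table3_adjusted_means_%s.csv", m))
      emit(ancova_summary_row(a), sprintf("table3_summary_%s.csv", m))
    }
    emit(ancova_summary_row(report$sensitivity), "sensitivity_model2.csv")
    qr_tab <- do.call(rbind, lapply(report$quantreg, function(f) {
      cbind(tau = attr(f, "tau"), as.data.frame(f))
    }))
    emit(qr_tab, "figure1_quantile_regression.csv")
    meta <- report[c("exclusions", "quartile_sizes", "imputation_log",
                     "fitted_quantiles", "provenance")]
    json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
    writeLines(json, file.path(dir, "run_metadata.json"))
    writeLines(report_log_lines(report), file.path(dir, "run_log.txt"))
  }, error = on_fail)
  invisible(dir)
}

ancova_summary_row <- function(a) {
  data.frame(model = a$model,
             quade_F = a$quade$statistic, quade_p = a$quade$p_value,
             df1 = a$quade$df[1], df2 = a$quade$df[2],
             extreme_diff = a$means$extreme_diff$estimate,
             ci_low = a$means$extreme_diff$ci_low,
             ci_high = a$means$extreme_diff$ci_high,
             extreme_p = a$means$extreme_diff$p_value,
             p_trend = a$trend$p_value)
}

report_log_lines <- function(report) {
  ex <- report$exclusions
  c(sprintf("roster n = %d; excluded (missing diet or HPL block) = %d; analysis n = %d",
            ex$n_roster, ex$excluded, ex$n_analysis),
    sprintf("quartile sizes: %s", paste(report$quartile_sizes, collapse = ", ")),
    sprintf("imputed: leisure-time physical activity n = %d (cohort mean %.1f kJ/d); marital status n = %d (mode '%s')",
            report$imputation_log$ltpa_imputed, report$imputation_log$ltpa_value,
            report$imputation_log$marital_imputed,
            report$imputation_log$marital_value),
    sprintf("sensitivity (complete cases) n = %d", report$sensitivity$n),
    sprintf("seed = %s, config = %s", format(report$provenance$seed),
            report$provenance$config_hash))
}

#' @export
print.hnds_study_report <- function(x, ...) {
  ex <- x$exclusions
  cat(sprintf("Study run: %d of %d retained (%d excluded)\n",
              ex$n_analysis, ex$n_roster, ex$excluded))
  for (m in names(x$ancova)) {
    a <- x$ancova[[m]]
    cat(sprintf("%s: Quade F = %.2f (p = %.4g); extreme-quartile diff = %.3f [%.3f, %.3f], p = %.4g; p trend = %.4g\n",
                m, a$quade$statistic, a$quade$p_value,
                a$means$extreme_diff$estimate, a$means$extreme_diff$ci_low,
                a$means$extreme_diff$ci_high, a$means$extreme_diff$p_value,
                a$trend$p_value))
  }
  for (nm in names(x$quantreg)) {
    f <- x$quantreg[[nm]]
    b <- f[f$term == "hnds_total", ]
    cat(sprintf("quantile tau = %.2f: beta(HNDS) = %.4f [%.4f, %.4f], p = %.4g\n",
                attr(f, "tau"), b$estimate, b$ci_low, b$ci_high, b$p_value))
  }
  invisible(x)
}
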