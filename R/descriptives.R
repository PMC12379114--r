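# Mantel-Haenszel linear-by-linear association statistic for an ordered
# r x c table with integer scores: M^2 = (N - 1) r^2 on 1 df, where r is
# the Pearson correlation of the row/column scores.
linear_by_linear <- function(row_scores, col_scores) {
  ok <- !is.na(row_scores) & !is.na(col_scores)
  u <- as.numeric(row_scores[ok])
  v <- as.numeric(col_scores[ok])
  if (length(u) < 3L || stats::sd(u) == 0 || stats::sd(v) == 0) {
    return(NA_real_)
  }
  m2 <- (length(u) - 1) * stats::cor(u, v)^2
  stats::pchisq(m2, df = 1, lower.tail = FALSE)
}

#' Sample characteristics by diet-score quartile
#'
#' Descriptive table across quartiles of the healthy Nordic diet score:
#' means and SDs per quartile for continuous variables with a linear
#' regression p-value for the univariate association with the quartile
#' index, and percentages for categorical variables with chi-squared and
#' Mantel--Haenszel (linear-by-linear) p-values.
#'
#' @param data Scored cohort `data.frame` with an `hnds_quartile` column.
#' @param continuous,categorical Character vectors naming the variables
#'   to summarise (defaults cover the generated cohort).
#' @return A long `data.frame`: `variable`, `level` (categorical only),
#'   `quartile`, `n`, `mean`/`sd` or `pct`, and per-variable `p_linear`
#'   or `p_chisq`/`p_mh` repeated across its rows.
#' @export
descriptives_by_quartile <- function(data,
                                     continuous = c("age", "bmi", "energy_kj",
                                                    "ltpa_kj", "ses", "ethanol",
                                                    "hpl_total", "hnds_total"),
                                     categorical = c("smoking", "marital",
                                                     "cvd_history",
                                                     "mental_illness",
                                                     "hpl_case")) {
  require_columns(data, "hnds_quartile", "descriptives_by_quartile")
  q <- data$hnds_quartile
  occupied <- sort(unique(q))
  if (length(occupied) < 2L) {
    warning("fewer than 2 occupied quartiles; association tests skipped")
  }
  continuous <- intersect(continuous, names(data))
  categorical <- intersect(categorical, names(data))
  rows <- list()
  for (v in continuous) {
    x <- as.numeric(data[[v]])
    p <- if (length(occupied) >= 2L && stats::sd(x, na.rm = TRUE) > 0) {
      f <- stats::lm(x ~ q)
      stats::coef(summary(f))["q", "Pr(>|t|)"]
    } else NA_real_
    for (qq in occupied) {
      xi <- x[q == qq]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, quartile = qq,
        n = sum(!is.na(xi)), mean = mean(xi, na.rm = TRUE),
        sd = stats::sd(xi, na.rm = TRUE), pct = NA_real_,
        p_linear = p, p_chisq = NA_real_, p_mh = NA_real_)
    }
  }
  for (v in categorical) {
    x <- data[[v]]
    lev <- sort(unique(x[!is.na(x)]))
    tab <- table(factor(x), factor(q, levels = occupied))
    p_chi <- if (length(occupied) >= 2L && nrow(tab) >= 2L) {
      suppressWarnings(stats::chisq.test(tab)$p.value)
    } else NA_real_
    # ordinal row scores: category rank (binary variables: 0/1 as coded)
    p_mh <- if (length(occupied) >= 2L && length(lev) >= 2L) {
      linear_by_linear(as.integer(factor(x, levels = lev)), q)
    } else NA_real_
    for (l in lev) {
      for (qq in occupied) {
        xi <- x[q == qq]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = as.character(l), quartile = qq,
          n = sum(!is.na(xi)), mean = NA_real_, sd = NA_real_,
          pct = 100 * mean(xi == l, na.rm = TRUE),
          p_linear = NA_real_, p_chisq = p_chi, p_mh = p_mh)
      }
    }
  }
  do.call(rbind, rows)
}
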