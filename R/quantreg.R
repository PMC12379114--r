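# Quantile regression by iteratively reweighted least squares on the
# asymmetric absolute (check) loss, with a decreasing smoothing floor.
# The IRLS step minimises the quadratic majoriser of the eps-smoothed
# check loss, so the objective is non-increasing within each eps stage.

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

rq_fit <- function(X, y, tau, tol = 1e-9, max_iter = 60L, start = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (tau <= 0 || tau >= 1) stop("tau must lie strictly inside (0, 1)")
  if (anyNA(X) || anyNA(y)) stop("rq_fit: missing values in design or outcome")
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient quantile-regression design matrix")
  }
  # Smoothed check loss: |r| is replaced by a Huber-type quadratic below
  # eps. The weighted least-squares step with weights c_i / max(|r_i|, eps)
  # is an MM update for this objective, so it decreases monotonically and
  # the stage converges; eps is then tightened towards the exact loss.
  smooth_loss <- function(r, eps, tau) {
    c_i <- ifelse(r >= 0, tau, 1 - tau)
    a <- abs(r)
    sum(c_i * ifelse(a <= eps, a^2 / (2 * eps) + eps / 2, a))
  }
  beta <- if (is.null(start)) qr.solve(X, y) else start
  best <- beta
  best_obj <- check_loss(y - drop(X %*% beta), tau)
  iters <- 0L
  for (eps in c(1e-2, 1e-4, 1e-6)) {
    prev <- smooth_loss(y - drop(X %*% beta), eps, tau)
    for (it in seq_len(max_iter)) {
      iters <- iters + 1L
      r <- drop(y - X %*% beta)
      w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
      beta <- stats::lm.wfit(X, y, w)$coefficients
      obj <- check_loss(y - drop(X %*% beta), tau)
      if (obj < best_obj) {
        best <- beta
        best_obj <- obj
      }
      cur <- smooth_loss(y - drop(X %*% beta), eps, tau)
      if (prev - cur <= tol * (1 + abs(cur))) break
      prev <- cur
    }
  }
  # The IRLS limit can approach the minimiser slowly on heavily tied
  # (integer) outcomes, so finish on the exact loss: an optimal solution
  # interpolates ncol(X) observations, and the objective is convex, so a
  # basis-exchange descent over the near-zero-residual observations
  # reaches a vertex no adjacent exchange can improve.
  pol <- rq_polish(X, y, tau, best, best_obj)
  if (is.null(pol)) {
    stop("quantile regression did not converge (", iters,
         " IRLS iterations and no full-rank interpolation basis found)")
  }
  names(pol$coefficients) <- colnames(X)
  list(coefficients = pol$coefficients, objective = pol$objective,
       iterations = iters, polish_passes = pol$passes)
}

rq_polish <- function(X, y, tau, beta, obj0, max_passes = 30L) {
  n <- nrow(X)
  p <- ncol(X)
  objective <- function(b) check_loss(y - drop(X %*% b), tau)
  solve_basis <- function(act) {
    Xa <- X[act, , drop = FALSE]
    b <- tryCatch(solve(Xa, y[act]), error = function(e) NULL)
    if (!is.null(b) && all(is.finite(b))) b else NULL
  }
  if (n < p) return(NULL)
  # initial basis: greedily take small-|residual| rows that keep full rank
  r <- y - drop(X %*% beta)
  active <- integer(0)
  for (i in order(abs(r))) {
    trial <- c(active, i)
    if (qr(X[trial, , drop = FALSE])$rank == length(trial)) active <- trial
    if (length(active) == p) break
  }
  if (length(active) < p) return(NULL)
  best <- beta
  best_obj <- obj0
  b <- solve_basis(active)
  if (!is.null(b)) {
    o <- objective(b)
    if (o <= best_obj) {
      best <- b
      best_obj <- o
    }
  }
  m <- min(n, 3L * p + 12L)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    r <- y - drop(X %*% best)
    cand <- setdiff(order(abs(r))[seq_len(m)], active)
    for (j in cand) {
      for (k in seq_len(p)) {
        act2 <- active
        act2[k] <- j
        b2 <- solve_basis(act2)
        if (is.null(b2)) next
        o2 <- objective(b2)
        if (o2 < best_obj - 1e-12 * (1 + abs(best_obj))) {
          best <- b2
          best_obj <- o2
          active <- act2
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(coefficients = best, objective = best_obj, passes = pass)
}

#' Quantile regression of depressive symptoms on the diet score
#'
#' Estimates the association between the healthy Nordic diet score and a
#' chosen conditional quantile of the HPL total (default analysis uses
#' the 0.33 and 0.66 quantiles, below and above the score's centre of
#' mass), adjusting for covariates. Coefficients minimise the asymmetric
#' absolute (check) loss by iteratively reweighted least squares;
#' confidence intervals come from a seeded participant-resampling (pairs)
#' bootstrap, percentile method, and p-values from a normal approximation
#' using the bootstrap standard error. Requires complete cases (the
#' analysis uses records with no missing covariates).
#'
#' @param data Scored cohort `data.frame` (needs `hnds_total`,
#'   `hpl_total` and the model-2 covariates unless `model = "model1"`).
#' @param tau Quantile level in (0, 1).
#' @param model Covariate set, as in [quade_ancova()]; may also be
#'   `"none"` for the unadjusted fit.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf_level Confidence level.
#' @return An object of class `hnds_quantreg`: data.frame of terms with
#'   `estimate`, `ci_low`, `ci_high`, `se_boot`, `p_value`; attributes
#'   `tau`, `n`, `B`, `objective`.
#' @examples
#' cohort <- score_cohort(generate_cohort(synthetic_config(500, seed = 2)))
#' fit <- fit_quantile(cohort, tau = 0.5, model = "model1", B = 50, seed = 9)
#' fit[fit$term == "hnds_total", ]
#' @export
fit_quantile <- function(data, tau = 0.33, model = c("model2", "model1", "none"),
                         B = 1000L, seed = 1L, conf_level = 0.95) {
  model <- match.arg(model)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must lie strictly inside (0, 1)")
  }
  require_columns(data, c("hnds_total", "hpl_total"), "fit_quantile")
  X <- cbind("(Intercept)" = 1, hnds_total = as.numeric(data$hnds_total))
  if (model != "none") X <- cbind(X, ancova_covariates(data, model))
  y <- as.numeric(data$hpl_total)
  if (anyNA(X) || anyNA(y)) {
    stop("fit_quantile requires complete cases; drop or impute missing values")
  }
  fit <- rq_fit(X, y, tau)

  n <- length(y)
  boot <- with_substream(seed, paste0("rq_boot_tau", tau), {
    t(vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rq_fit(X[idx, , drop = FALSE], y[idx], tau,
             start = fit$coefficients)$coefficients
    }, numeric(ncol(X))))
  })
  alpha <- 1 - conf_level
  ci <- apply(boot, 2L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              type = 8)
  se <- apply(boot, 2L, stats::sd)
  z <- fit$coefficients / se
  out <- data.frame(term = colnames(X),
                    estimate = unname(fit$coefficients),
                    ci_low = unname(ci[1L, ]), ci_high = unname(ci[2L, ]),
                    se_boot = unname(se),
                    p_value = unname(2 * stats::pnorm(-abs(z))),
                    row.names = NULL)
  attr(out, "tau") <- tau
  attr(out, "n") <- n
  attr(out, "B") <- B
  attr(out, "objective") <- fit$objective
  class(out) <- c("hnds_quantreg", "data.frame")
  out
}

#' Fitted conditional quantiles at the covariate means
#'
#' Evaluates a set of quantile fits at the sample means of all predictors
#' and warns if the fitted quantiles cross (a lower tau giving a larger
#' fitted value), which on well-behaved data indicates an unstable fit.
#'
#' @param fits List of `hnds_quantreg` objects for increasing `tau`.
#' @param data The data they were fitted on.
#' @return Named numeric vector of fitted values, one per tau.
#' @export
fitted_quantiles_at_means <- function(fits, data) {
  vals <- vapply(fits, function(f) {
    x <- vapply(f$term, function(tm) {
      if (tm == "(Intercept)") return(1)
      if (grepl("^smoking_", tm)) {
        return(mean(data$smoking == sub("^smoking_", "", tm)))
      }
      if (grepl("^marital_", tm)) {
        return(mean(data$marital == sub("^marital_", "", tm)))
      }
      mean(as.numeric(data[[tm]]))
    }, numeric(1))
    sum(x * f$estimate)
  }, numeric(1))
  taus <- vapply(fits, function(f) attr(f, "tau"), numeric(1))
  names(vals) <- paste0("tau_", taus)
  if (is.unsorted(taus)) {
    o <- order(taus)
    taus <- taus[o]; vals <- vals[o]
  }
  if (any(diff(vals) < 0)) {
    warning("fitted quantiles cross at the covariate means")
  }
  vals
}

#' @export
print.hnds_quantreg <- function(x, ...) {
  cat(sprintf("Quantile regression at tau = %.2f (n = %d, %d bootstrap reps)\n",
              attr(x, "tau"), attr(x, "n"), attr(x, "B")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
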