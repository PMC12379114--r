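#' Quartile points for one score component
#'
#' Assigns 0--3 points from within-cohort quartiles of consumption.
#' Cut-points are the empirical 25th/50th/75th percentiles
#' (median-unbiased estimator); comparison is half-open (`x < Q1` is
#' quartile 1, `[Q1, Q2)` quartile 2, `[Q2, Q3)` quartile 3, `>= Q3`
#' quartile 4), so tied values always share a quartile and group sizes
#' may be unequal. Positive components score quartile minus one (lowest
#' quartile 0, highest 3); negative components score in the opposite
#' order. If every value is identical all participants fall in quartile 4.
#'
#' @param values Component intakes across the whole cohort (>= 0, finite).
#' @param direction `"positive"` (more is better: fruits and berries,
#'   vegetables, cereals, low-fat milk, fish, fat ratio) or `"negative"`
#'   (less is better: meat products, total fat).
#' @return Integer vector of points in 0..3, same length as `values`.
#' @examples
#' component_quartile_points(1:8, "positive")   # 0 0 1 1 2 2 3 3
#' component_quartile_points(1:8, "negative")   # 3 3 2 2 1 1 0 0
#' @export
component_quartile_points <- function(values, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) stop("component values must be non-empty")
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    stop("invalid component value (negative or non-finite) at index ",
         paste(bad[seq_len(min(5, length(bad)))], collapse = ", "))
  }
  q <- quartile_assign(values)
  if (direction == "positive") q - 1L else 4L - q
}

#' Alcohol component points
#'
#' The alcohol component is binary rather than quartile-based: 0 points
#' for ethanol intake >= 20 g/d, 1 point below 20 g/d.
#'
#' @param ethanol Ethanol intake, g/d (>= 0). Vectorised.
#' @return Integer 0/1 per value.
#' @examples
#' alcohol_points(c(0, 19.9, 20, 25))  # 1 1 0 0
#' @export
alcohol_points <- function(ethanol) {
  bad <- which(!is.finite(ethanol) | ethanol < 0)
  if (length(bad)) {
    stop("ethanol intake must be finite and >= 0 (offending index ",
         paste(bad[seq_len(min(5, length(bad)))], collapse = ", "), ")")
  }
  as.integer(ethanol < 20)
}

#' Dietary fat-quality ratio
#'
#' PUFA divided by the sum of saturated and trans fatty acids, from gram
#' intakes. Undefined when `sfa + tfa` is zero.
#'
#' @param pufa,sfa,tfa Fatty-acid intakes, g/d (>= 0). Vectorised.
#' @param ids Optional participant identifiers used in error messages.
#' @return Numeric ratio (dimensionless).
#' @examples
#' fat_ratio(6, 10, 2)  # 0.5
#' @export
fat_ratio <- function(pufa, sfa, tfa, ids = seq_along(pufa)) {
  if (any(!is.finite(pufa) | pufa < 0) || any(!is.finite(sfa) | sfa < 0) ||
      any(!is.finite(tfa) | tfa < 0)) {
    stop("fatty-acid intakes must be finite and >= 0")
  }
  den <- sfa + tfa
  if (any(den == 0)) {
    stop("fat ratio undefined (SFA + TFA = 0) for participant(s): ",
         paste(ids[den == 0][seq_len(min(5, sum(den == 0)))], collapse = ", "))
  }
  pufa / den
}

#' Compute the healthy Nordic diet score for a cohort
#'
#' Applies the nine-component scoring to every participant: quartile
#' points (within the supplied cohort only) for the six positive
#' components (fruits and berries, vegetables, cereals, low-fat milk,
#' fish, PUFA/(SFA+TFA) ratio) and the two negative components (meat
#' products, total fat as E%), plus the binary alcohol component. The
#' total ranges 0--25; higher means closer adherence to a healthy Nordic
#' diet. Exclusions must have been applied upstream: any missing
#' component is an error, not a silent drop.
#'
#' @param cohort A cohort `data.frame` with the eleven intake columns
#'   (see [generate_cohort()]) and optionally `id`.
#' @return A `data.frame` with `id`, the nine `*_points` columns and
#'   `hnds_total`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_participants = 50, seed = 3))
#' scores <- compute_hnds(cohort)
#' range(scores$hnds_total)
#' @export
compute_hnds <- function(cohort) {
  require_columns(cohort, hnds_intake_cols(), "compute_hnds")
  if (nrow(cohort) == 0L) stop("compute_hnds: empty cohort")
  ids <- if ("id" %in% names(cohort)) cohort$id else seq_len(nrow(cohort))
  incomplete <- !stats::complete.cases(cohort[, hnds_intake_cols()])
  if (any(incomplete)) {
    stop("compute_hnds: missing dietary components for participant(s): ",
         paste(ids[incomplete][seq_len(min(10, sum(incomplete)))],
               collapse = ", "),
         " (apply exclusions before scoring)")
  }
  ratio <- fat_ratio(cohort$pufa, cohort$sfa, cohort$tfa, ids)
  out <- data.frame(
    id = ids,
    fruits_berries_points = component_quartile_points(cohort$fruits_berries, "positive"),
    vegetables_points     = component_quartile_points(cohort$vegetables, "positive"),
    cereals_points        = component_quartile_points(cohort$cereals, "positive"),
    lowfat_milk_points    = component_quartile_points(cohort$lowfat_milk, "positive"),
    fish_points           = component_quartile_points(cohort$fish, "positive"),
    fat_ratio_points      = component_quartile_points(ratio, "positive"),
    meat_products_points  = component_quartile_points(cohort$meat_products, "negative"),
    total_fat_points      = component_quartile_points(cohort$total_fat, "negative"),
    alcohol_points        = alcohol_points(cohort$ethanol)
  )
  pts <- out[, grep("_points$", names(out))]
  out$hnds_total <- as.integer(rowSums(pts))
  out
}

hnds_point_cols <- function() {
  c("fruits_berries_points", "vegetables_points", "cereals_points",
    "lowfat_milk_points", "fish_points", "fat_ratio_points",
    "meat_products_points", "total_fat_points", "alcohol_points")
}
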