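#' Total score of the 18-item HPL depression scale
#'
#' One point per answer indicating a depressive symptom; range 0--18.
#' Any missing item makes the whole outcome missing (`NA`), the
#' conservative rule the exclusion step relies on.
#'
#' @param items Vector of exactly 18 responses coded 0/1 (1 = symptom),
#'   `NA` allowed.
#' @return Integer total 0--18, or `NA_integer_` if any item is missing.
#' @examples
#' hpl_total(c(rep(1, 5), rep(0, 13)))  # 5
#' @export
hpl_total <- function(items) {
  if (length(items) != 18L) {
    stop("hpl_total: expected exactly 18 item responses, got ", length(items))
  }
  ok <- is.na(items) | items %in% c(0, 1)
  if (!all(ok)) {
    stop("hpl_total: non-binary response at item ",
         paste(which(!ok), collapse = ", "))
  }
  if (anyNA(items)) return(NA_integer_)
  as.integer(sum(items))
}

#' Clinically significant depressive symptoms
#'
#' The scale's clinical cut-off: a total of 5 or more indicates
#' clinically significant depression.
#'
#' @param total Integer HPL total in 0..18 (vectorised; `NA` passes
#'   through).
#' @return Logical.
#' @examples
#' classify_depression(c(4, 5))  # FALSE TRUE
#' @export
classify_depression <- function(total) {
  bad <- !is.na(total) & (total < 0 | total > 18 | total != trunc(total))
  if (any(bad)) {
    stop("classify_depression: totals must be integers in 0..18")
  }
  total >= 5
}

#' Score the HPL scale for a whole cohort
#'
#' Adds `hpl_total` and the clinical-significance flag `hpl_case` from the
#' item columns `hpl_01` .. `hpl_18`. Rows with any missing item get a
#' missing total and flag.
#'
#' @param cohort A `data.frame` with the 18 HPL item columns.
#' @return `cohort` with `hpl_total` (integer) and `hpl_case` (logical)
#'   appended.
#' @export
score_hpl <- function(cohort) {
  require_columns(cohort, hnds_hpl_cols(), "score_hpl")
  items <- as.matrix(cohort[, hnds_hpl_cols()])
  vals <- items[!is.na(items)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("score_hpl: HPL items must be coded 0/1")
  }
  tot <- as.integer(rowSums(items))
  tot[apply(items, 1L, anyNA)] <- NA_integer_
  cohort$hpl_total <- tot
  cohort$hpl_case <- classify_depression(tot)
  cohort
}
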