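#' Tidy a two-way ANOVA table
#'
#' @param x A `cr_anova` object.
#' @param ... Unused.
#' @return The effect and error rows as a tibble (`source`, `df`, `ss`,
#'   `ms`, `f`, `p`).
#' @export
tidy.cr_anova <- function(x, ...) {
  dplyr::filter(x$table, .data$source != "total")
}

#' One-row summary of a two-way ANOVA
#'
#' @param x A `cr_anova` object.
#' @param ... Unused.
#' @return A tibble with `nobs`, `ss_total`, `df_total`, `ms_error`.
#' @export
glance.cr_anova <- function(x, ...) {
  tot <- dplyr::filter(x$table, .data$source == "total")
  err <- dplyr::filter(x$table, .data$source == "error")
  tibble::tibble(nobs = x$nobs, ss_total = tot$ss, df_total = tot$df,
                 ms_error = err$ms)
}

#' Tidy a cohort analysis into its panel table
#'
#' @param x A `cr_cohort_analysis` object.
#' @param ... Unused.
#' @return The subject-by-phase panel tibble.
#' @export
tidy.cr_cohort_analysis <- function(x, ...) x$panels

#' One-row summary of a cohort analysis
#'
#' @param x A `cr_cohort_analysis` object.
#' @param ... Unused.
#' @return A tibble with subject counts, exclusions and classification
#'   agreement (share of analyzed subjects whose assigned class equals the
#'   generating type, when both are present).
#' @export
glance.cr_cohort_analysis <- function(x, ...) {
  sr <- dplyr::filter(x$panels, .data$phase == "SR")
  agree <- if (all(c("type", "hrr_class") %in% names(sr))) {
    mean(sr$hrr_class == sr$type)
  } else {
    NA_real_
  }
  tibble::tibble(
    n_subjects = dplyr::n_distinct(x$panels$subject_id),
    n_excluded = sum(x$qc$verdict == "exclude"),
    class_agreement = agree
  )
}
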