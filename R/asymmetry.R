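# Index of Asymmetry and feature prevalence counting.

#' Index of Asymmetry (IoA)
#'
#' `IoA = |(L - R) / (L + R)| * 2 * 100`: the absolute left-right length
#' difference expressed as a percentage of the pair's average. Ranges from 0
#' (perfect symmetry) to 200 (one limb absent in length). Scale-invariant, so
#' identical whether computed on pixel or cm lengths.
#'
#' A pair with both lengths zero carries no asymmetry information and yields
#' `NA` rather than fabricating symmetry; `NA` inputs propagate.
#'
#' @param left,right Non-negative lengths (vectorised).
#' @return IoA percentage(s) in `[0, 200]`.
#' @export
index_of_asymmetry <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    abort("limb lengths must be non-negative")
  }
  total <- left + right
  out <- abs((left - right) / total) * 2 * 100
  out[!is.na(total) & total == 0] <- NA_real_
  out
}

#' Per-subject limb asymmetry
#'
#' Computes arm and leg IoA for each row of a measurement table. An IoA is
#' `NA` whenever either of the pair's lengths is missing or both are zero —
#' missingness propagates, it is never coerced to 0.
#'
#' @param measurements A tibble with columns `arm_left_cm`, `arm_right_cm`,
#'   `leg_left_cm`, `leg_right_cm` (e.g. from [measure_sessions()]); any
#'   identifier columns (`drawing_id`, `subject_id`, `group`, `rater_id`)
#'   are carried through.
#' @return A tibble with the carried identifier columns plus `arm_ioa_pct`
#'   and `leg_ioa_pct`.
#' @export
cohort_asymmetry <- function(measurements) {
  stopifnot(all(c("arm_left_cm", "arm_right_cm",
                  "leg_left_cm", "leg_right_cm") %in% names(measurements)))
  keep <- intersect(c("subject_id", "drawing_id", "group", "rater_id"),
                    names(measurements))
  dplyr::bind_cols(
    measurements[keep],
    tibble(
      arm_ioa_pct = index_of_asymmetry(measurements$arm_left_cm,
                                       measurements$arm_right_cm),
      leg_ioa_pct = index_of_asymmetry(measurements$leg_left_cm,
                                       measurements$leg_right_cm)
    )
  )
}

#' @rdname cohort_asymmetry
#' @param measurement_row A one-row measurement tibble.
#' @export
subject_asymmetry <- function(measurement_row) {
  stopifnot(nrow(measurement_row) == 1L)
  cohort_asymmetry(measurement_row)
}

#' Feature prevalence counts per group
#'
#' Counts, for every body feature, how many control and patient drawings
#' include it. Counts are invariant to subject ordering.
#'
#' @param features A tibble with one row per subject x feature: columns
#'   `subject_id`, `group` (exactly two groups, `"control"` and
#'   `"patient"`), `feature`, `present` (logical).
#' @return A tibble with one row per feature: `feature`,
#'   `n_present_controls`, `n_controls`, `n_present_patients`, `n_patients`.
#' @export
feature_prevalence_counts <- function(features) {
  stopifnot(all(c("subject_id", "group", "feature", "present") %in% names(features)))
  if (nrow(features) == 0L) abort("empty cohort: no feature records")
  groups <- sort(unique(features$group))
  if (!setequal(groups, c("control", "patient"))) {
    abort(paste0("cohort must contain both a 'control' and a 'patient' group; got: ",
                 paste(groups, collapse = ", ")))
  }
  features |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_present_controls = sum(.data$present[.data$group == "control"], na.rm = TRUE),
      n_controls = sum(.data$group == "control"),
      n_present_patients = sum(.data$present[.data$group == "patient"], na.rm = TRUE),
      n_patients = sum(.data$group == "patient"),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$feature, feature_vocabulary()))
}
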