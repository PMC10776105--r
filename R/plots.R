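# ggplot2 summaries of asymmetry and prevalence results.

#' Plot arm vs leg asymmetry distributions
#'
#' Distributional summary of arm and leg IoA per group: one-sided density
#' (violin), boxplot, and jittered subject points — the standard way this
#' contrast is displayed.
#'
#' @param asymmetry A tibble from [cohort_asymmetry()] with `arm_ioa_pct`,
#'   `leg_ioa_pct` and optionally `group`.
#' @return A ggplot object.
#' @export
plot_limb_asymmetry <- function(asymmetry) {
  stopifnot(all(c("arm_ioa_pct", "leg_ioa_pct") %in% names(asymmetry)))
  if (!"group" %in% names(asymmetry)) asymmetry$group <- "all"
  long <- asymmetry |>
    tidyr::pivot_longer(cols = c("arm_ioa_pct", "leg_ioa_pct"),
                        names_to = "limb", values_to = "ioa_pct") |>
    dplyr::mutate(limb = ifelse(.data$limb == "arm_ioa_pct", "arm", "leg")) |>
    dplyr::filter(!is.na(.data$ioa_pct))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$limb, y = .data$ioa_pct,
                                     fill = .data$limb)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA, trim = TRUE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, alpha = 0.8) +
    ggplot2::geom_jitter(width = 0.08, size = 0.8, alpha = 0.5) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_manual(values = c(arm = "#2a9d8f", leg = "#e76f51"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "Index of Asymmetry (%)",
                  title = "Arm vs leg length asymmetry")
}

#' Plot feature prevalence by group
#'
#' @param prevalence A tibble from [prevalence_comparison()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence) {
  long <- prevalence |>
    dplyr::mutate(control = .data$n_present_controls / .data$n_controls,
                  patient = .data$n_present_patients / .data$n_patients) |>
    tidyr::pivot_longer(cols = c("control", "patient"),
                        names_to = "group", values_to = "prevalence")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = 100 * .data$prevalence,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = dplyr::filter(long, .data$significant_after_fdr, .data$group == "control"),
      ggplot2::aes(y = 104), shape = 8, show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Prevalence (%)",
                  title = "Body feature prevalence by group",
                  subtitle = "* significant after FDR correction")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a synthetic cohort
#'
#' Shows the arm-vs-leg asymmetry summary of the first rater's measurements.
#'
#' @param object A `drawing_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drawing_cohort <- function(object, ...) {
  plot_limb_asymmetry(cohort_asymmetry(cohort_measurements(object)))
}
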