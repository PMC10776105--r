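# Cohort-level statistical analyses: arm-vs-leg asymmetry comparison,
# group prevalence comparison with FDR, and inter-rater reliability.

#' Arm-vs-leg asymmetry comparison
#'
#' Tests, within one group, whether arm IoA exceeds leg IoA — legs act as
#' the within-subject control body part. Subjects with either IoA missing
#' are dropped pairwise (`n_effective` reports what remains) and a Wilcoxon
#' signed-rank test (see [wilcoxon_signed_rank()]) is run on the (arm, leg)
#' pairs. The significance threshold is Bonferroni-corrected for running
#' the comparison in each of `comparisons` groups:
#' `bonferroni_threshold(family_alpha, comparisons)`, 0.025 by default.
#'
#' @param asymmetry A tibble with columns `arm_ioa_pct`, `leg_ioa_pct` and
#'   optionally `group` (from [cohort_asymmetry()]).
#' @param group If given, restrict to rows with this `group` value.
#' @param family_alpha Family-wise alpha shared across the group analyses.
#' @param comparisons Number of groups in the family (default 2: patients
#'   and controls).
#' @return A `drawmetry_test` with fields `group`, `n_effective`,
#'   `n_dropped`, `statistic` (W), `z`, `p_value`, `alpha_threshold`,
#'   `significant`, `method`.
#' @export
compare_limb_asymmetry <- function(asymmetry, group = NULL,
                                   family_alpha = 0.05, comparisons = 2L) {
  stopifnot(all(c("arm_ioa_pct", "leg_ioa_pct") %in% names(asymmetry)))
  if (!is.null(group)) {
    if (!"group" %in% names(asymmetry)) abort("no 'group' column to filter on")
    asymmetry <- asymmetry[asymmetry$group == group, ]
  }
  ok <- complete.cases(asymmetry$arm_ioa_pct, asymmetry$leg_ioa_pct)
  n_dropped <- sum(!ok)
  arm <- asymmetry$arm_ioa_pct[ok]
  leg <- asymmetry$leg_ioa_pct[ok]
  if (length(arm) < 1L) {
    not_testable("no subjects with both arm and leg IoA defined")
  }
  alpha <- bonferroni_threshold(family_alpha, comparisons)
  wt <- wilcoxon_signed_rank(arm, leg, alpha = alpha)
  new_drawmetry_test(
    "arm_vs_leg_asymmetry",
    group = group %||% "all",
    n_effective = wt$n_effective, n_dropped = n_dropped,
    statistic = wt$statistic, z = wt$z, p_value = wt$p_value,
    alpha_threshold = alpha, significant = wt$significant, method = wt$method
  )
}

#' Group prevalence comparison with FDR correction
#'
#' For every body feature, tests whether its prevalence differs between
#' controls and patients with a one-tailed Fisher's exact test (default
#' direction: higher prevalence in controls), then adjusts the whole family
#' of p-values jointly with the Benjamini-Hochberg step-up procedure.
#'
#' @param features Long feature table as for [feature_prevalence_counts()].
#' @param direction `"greater"` tests controls > patients; `"less"` the
#'   reverse.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return A tibble with one row per feature: the prevalence counts,
#'   `fisher_p`, `fdr_adjusted_p`, `significant_after_fdr`.
#' @export
prevalence_comparison <- function(features, direction = c("greater", "less"),
                                  alpha = 0.05) {
  direction <- match.arg(direction)
  counts <- feature_prevalence_counts(features)
  fisher_p <- purrr::pmap_dbl(counts, function(feature, n_present_controls,
                                               n_controls, n_present_patients,
                                               n_patients) {
    tab <- matrix(c(n_present_controls, n_controls - n_present_controls,
                    n_present_patients, n_patients - n_present_patients),
                  nrow = 2, byrow = TRUE)
    fisher_exact_one_tailed(tab, direction)
  })
  counts |>
    dplyr::mutate(
      fisher_p = fisher_p,
      fdr_adjusted_p = bh_adjust(fisher_p),
      significant_after_fdr = .data$fdr_adjusted_p < alpha
    )
}

#' Inter-rater reliability report
#'
#' Spearman correlation per metric parameter between two raters' measurement
#' tables, matched by `drawing_id` and computed over pairwise-complete
#' values. Parameters with fewer than `min_pairs` complete pairs are skipped;
#' the skip reasons are attached as the `"skipped"` attribute and reported
#' via a message.
#'
#' @param measurements_a,measurements_b Measurement tibbles (one row per
#'   drawing, see [measure_sessions()]) from two raters.
#' @param parameters Which metric parameters to correlate.
#' @param min_pairs Minimum complete pairs per parameter (default 3).
#' @return A tibble `parameter`, `rho`, `p_value`, `n_pairs`, `method`.
#' @export
reliability_report <- function(measurements_a, measurements_b,
                               parameters = metric_parameters(),
                               min_pairs = 3L) {
  stopifnot("drawing_id" %in% names(measurements_a),
            "drawing_id" %in% names(measurements_b))
  joined <- dplyr::inner_join(
    measurements_a[c("drawing_id", intersect(parameters, names(measurements_a)))],
    measurements_b[c("drawing_id", intersect(parameters, names(measurements_b)))],
    by = "drawing_id", suffix = c("_a", "_b")
  )
  skipped <- tibble(parameter = character(), reason = character())
  rows <- purrr::map(parameters, function(p) {
    a <- joined[[paste0(p, "_a")]]
    b <- joined[[paste0(p, "_b")]]
    if (is.null(a) || is.null(b)) {
      skipped <<- dplyr::add_row(skipped, parameter = p,
                                 reason = "parameter absent from input")
      return(NULL)
    }
    n_ok <- sum(complete.cases(a, b))
    if (n_ok < min_pairs) {
      skipped <<- dplyr::add_row(
        skipped, parameter = p,
        reason = sprintf("only %d complete pairs (need %d)", n_ok, min_pairs))
      return(NULL)
    }
    res <- tryCatch(spearman_corr(a, b),
                    drawmetry_not_testable = function(e) NULL)
    if (is.null(res)) {
      skipped <<- dplyr::add_row(skipped, parameter = p,
                                 reason = "correlation not testable (constant values)")
      return(NULL)
    }
    tibble(parameter = p, rho = res$rho, p_value = res$p_value,
           n_pairs = res$n_pairs, method = res$method)
  })
  proto <- tibble(parameter = character(), rho = double(),
                  p_value = double(), n_pairs = integer(), method = character())
  out <- dplyr::bind_rows(proto, rows)
  if (nrow(skipped) > 0L) {
    inform(paste0("reliability_report skipped: ",
                  paste(sprintf("%s (%s)", skipped$parameter, skipped$reason),
                        collapse = "; ")))
  }
  attr(out, "skipped") <- skipped
  out
}
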