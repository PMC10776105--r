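test_that("arm-vs-leg comparison applies pairwise deletion and the 0.025 threshold", {
  asym <- tibble::tibble(subject_id = sprintf("s%d", 1:6),
                         arm_ioa_pct = c(15, 22, 9, 30, 12, 18),
                         leg_ioa_pct = c(15, 22, 9, 30, 12, 18) - 10)
  res <- compare_limb_asymmetry(asym)
  expect_equal(res$n_effective, 6)
  expect_equal(res$p_value, 2 / 64)          # all six differences positive
  expect_equal(res$alpha_threshold, 0.025)
  expect_false(res$significant)              # 0.03125 > 0.025

  asym10 <- tibble::tibble(arm_ioa_pct = runif(10, 5, 20),
                           leg_ioa_pct = c(runif(9, 1, 4), NA))
  res <- compare_limb_asymmetry(asym10)
  expect_equal(res$n_effective, 9)
  expect_equal(res$n_dropped, 1)

  tied <- tibble::tibble(arm_ioa_pct = c(4, 7, 9), leg_ioa_pct = c(4, 7, 9))
  expect_error(compare_limb_asymmetry(tied), class = "drawmetry_not_testable")
})

test_that("tidy and glance return one-row summaries of test objects", {
  asym <- tibble::tibble(arm_ioa_pct = c(15, 22, 9, 30),
                         leg_ioa_pct = c(5, 2, 1, 3))
  res <- compare_limb_asymmetry(asym)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_true(all(c("test", "n_effective", "statistic", "p_value",
                    "significant") %in% names(td)))
  expect_equal(glance(res)$p_value, res$p_value)
})

test_that("prevalence comparison combines exact Fisher tests with joint FDR", {
  make_feats <- function(pres_c, pres_p, n_c = 5, n_p = 5,
                         features = c("hair", "nose")) {
    tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n_c + n_p)),
                       feature = features) |>
      dplyr::mutate(group = rep(c("control", "patient"), c(n_c, n_p))[
                      match(subject_id, sprintf("s%02d", seq_len(n_c + n_p)))],
                    present = ifelse(group == "control",
                                     match(subject_id, unique(subject_id)) <= pres_c,
                                     match(subject_id, unique(subject_id)) - n_c <= pres_p))
  }
  # feature present in all controls, no patients, tested alone
  feats <- make_feats(5, 0, features = "hair")
  res <- prevalence_comparison(feats)
  expect_equal(res$fisher_p, 1 / choose(10, 5))   # = 1/252 by enumeration
  expect_equal(res$fdr_adjusted_p, res$fisher_p)  # family of one
  expect_true(res$significant_after_fdr)

  # identical prevalence in both groups: nothing significant
  feats <- make_feats(3, 3)
  res <- prevalence_comparison(feats)
  expect_true(all(!res$significant_after_fdr))
  expect_true(all(res$fdr_adjusted_p >= res$fisher_p))

  # BH bound holds when the family grows
  set.seed(88)
  wide <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:20),
                             feature = feature_vocabulary()) |>
    dplyr::mutate(group = ifelse(subject_id <= "s10", "control", "patient"),
                  present = runif(dplyr::n()) < ifelse(group == "control", 0.8, 0.5))
  res <- prevalence_comparison(wide)
  expect_true(all(res$fdr_adjusted_p >= res$fisher_p))
  expect_true(all(res$fdr_adjusted_p <= 1))
})

test_that("reliability report recovers monotone agreement and skips sparse parameters", {
  cfg <- synth_config(n_patients = 10, n_controls = 0, seed = 31,
                      rater_noise_sd_px = 0, raters = "a")
  ms <- cohort_measurements(generate_cohort(cfg), "a") |>
    dplyr::mutate(drawing_id = subject_id)

  rel <- reliability_report(ms, ms)
  expect_equal(rel$rho, rep(1, nrow(rel)))

  scaled <- dplyr::mutate(ms, dplyr::across(dplyr::all_of(metric_parameters()),
                                            ~ .x * 1.1))
  rel <- reliability_report(ms, scaled)
  expect_equal(rel$rho, rep(1, nrow(rel)))    # rank-preserving transform

  sparse <- ms
  sparse$arm_left_cm[-1] <- NA
  expect_message(rel <- reliability_report(ms, sparse), "arm_left_cm")
  expect_false("arm_left_cm" %in% rel$parameter)
  expect_match(attr(rel, "skipped")$reason[
    attr(rel, "skipped")$parameter == "arm_left_cm"], "complete pairs")
})

test_that("simulated raters with 2-px noise agree strongly on limb lengths", {
  cfg <- synth_config(n_patients = 50, n_controls = 0, seed = 314,
                      rater_noise_sd_px = 2)
  co <- generate_cohort(cfg)
  ma <- cohort_measurements(co, cfg$raters[1]) |>
    dplyr::mutate(drawing_id = subject_id)
  mb <- cohort_measurements(co, cfg$raters[2]) |>
    dplyr::mutate(drawing_id = subject_id)
  rel <- reliability_report(ma, mb)
  limbs <- c("arm_left_cm", "arm_right_cm", "leg_left_cm", "leg_right_cm")
  expect_true(all(rel$rho[rel$parameter %in% limbs] >= 0.9))
})
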