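no_omission <- function() {
  p <- default_omission_probabilities()
  p$control[] <- 0
  p$patient[] <- 0
  p
}

test_that("skeleton ground truth obeys the asymmetry model exactly", {
  # deterministic shortening of 0.2 on one arm, no jitter
  cfg <- synth_config(seed = 5, side_jitter_sd = 0,
                      arm_asymmetry = list(mean = 0.2, sd = 0),
                      omission_probabilities = no_omission())
  set.seed(5)
  sk <- sample_skeleton(cfg, "patient")
  expect_equal(sk$truth$arm_ioa_pct, abs(1 - 0.8) / 1.8 * 200)  # ~22.22
  expect_equal(sk$truth$leg_ioa_pct, 0)

  cfg0 <- synth_config(seed = 5, side_jitter_sd = 0,
                       arm_asymmetry = list(mean = 0, sd = 0),
                       omission_probabilities = no_omission())
  set.seed(5)
  sk0 <- sample_skeleton(cfg0, "patient")
  expect_equal(sk0$truth$arm_ioa_pct, 0)

  # landmarks are geometrically consistent and on the page
  expect_identical(validate_session(sk$session), character())
  lm <- sk$session$landmarks
  y <- function(n) lm$y_px[lm$name == n]
  expect_lt(y("head_top"), y("shoulder_left"))
  expect_lt(y("shoulder_left"), y("hip_left"))
})

test_that("impossible figure dimensions raise a config error naming the culprit", {
  cfg <- synth_config(seed = 1, part_means_cm = list(
    head_size = 3, torso_length = 6.5, shoulders_width = 6, hips_width = 4.5,
    arm_length = 7, leg_length = 40))
  set.seed(1)
  expect_error(sample_skeleton(cfg, "control"), "leg_length")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- synth_config(n_patients = 5, n_controls = 4, seed = 2024)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(a$truth, b$truth)
  expect_equal(a$sessions$session, b$sessions$session)
  # and the population is untouched by adding a third rater
  cfg3 <- synth_config(n_patients = 5, n_controls = 4, seed = 2024,
                       raters = c("sim_rater_1", "sim_rater_2", "extra"))
  c3 <- generate_cohort(cfg3)
  expect_equal(c3$truth, a$truth)
  expect_equal(c3$sessions$session[c3$sessions$rater_id == "sim_rater_1"],
               a$sessions$session[a$sessions$rater_id == "sim_rater_1"])
})

test_that("default cohort reproduces the study group sizes", {
  co <- generate_cohort(synth_config(seed = 8))
  expect_equal(sum(co$truth$group == "patient"), 56)
  expect_equal(sum(co$truth$group == "control"), 46)
  expect_equal(nrow(co$sessions), 102 * 2)
})

test_that("rater noise has folded-normal magnitude and is independent across raters", {
  cfg <- synth_config(n_patients = 60, n_controls = 0, seed = 61,
                      rater_noise_sd_px = 3,
                      omission_probabilities = no_omission())
  co <- generate_cohort(cfg)
  err <- function(rid) {
    unlist(purrr::map2(co$skeletons,
                       co$sessions$session[co$sessions$rater_id == rid],
                       function(sk, se) {
                         c(se$landmarks$x_px - sk$landmarks$x_px,
                           se$landmarks$y_px - sk$landmarks$y_px)
                       }))
  }
  e1 <- err("sim_rater_1"); e2 <- err("sim_rater_2")
  expect_equal(mean(abs(e1)), 3 * sqrt(2 / pi), tolerance = 0.05)
  expect_lt(abs(cor(e1, e2)), 0.08)

  # zero noise reproduces the skeleton exactly
  set.seed(1)
  sk <- sample_skeleton(cfg, "control")$session
  quiet <- simulate_rater(sk, "q", noise_sd_px = 0)
  expect_identical(quiet$landmarks, sk$landmarks)
})

test_that("measured arm IoA tracks the shortening distribution at cohort scale", {
  cfg <- synth_config(n_patients = 150, n_controls = 0, seed = 17,
                      side_jitter_sd = 0, rater_noise_sd_px = 2,
                      omission_probabilities = no_omission())
  co <- generate_cohort(cfg)
  asym <- cohort_asymmetry(cohort_measurements(co))
  implied <- mean(200 * co$truth$arm_shortening / (2 - co$truth$arm_shortening))
  expect_equal(mean(asym$arm_ioa_pct), implied, tolerance = 0.02)
})

test_that("rendering is deterministic, sized to the page, and feature-gated", {
  set.seed(3)
  cfg <- synth_config(seed = 3, omission_probabilities = no_omission())
  sk <- sample_skeleton(cfg, "control")
  img1 <- render_figure(sk$session)
  img2 <- render_figure(sk$session)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(ceiling(sk$session$height_px),
                            ceiling(sk$session$width_px)))
  expect_gt(sum(img1), 0)

  bald <- sk$session
  bald$features$present[bald$features$feature == "hair"] <- FALSE
  img_bald <- render_figure(bald)
  diff_px <- which(img1 != img_bald, arr.ind = TRUE)
  expect_gt(nrow(diff_px), 0)
  head_top_row <- min(sk$session$landmarks$y_px[
    sk$session$landmarks$name == "head_top"]) + 1
  expect_true(all(diff_px[, "row"] <= head_top_row + 1))  # hair sits above the crown
})
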