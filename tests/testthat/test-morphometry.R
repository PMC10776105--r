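test_that("segment lengths and unit conversion follow direct arithmetic", {
  lm <- tibble::tibble(name = c("hip_left", "hip_right", "shoulder_left",
                                "wrist_left"),
                       x_px = c(0, 3, 30, 30), y_px = c(0, 4, 60, 210))
  expect_equal(segment_length_px(lm, "hip_left", "hip_right"), 5)
  expect_equal(segment_length_px(lm, "hip_left", "hip_left"), 0)
  expect_equal(segment_length_px(lm, "shoulder_left", "wrist_left"), 150)
  expect_true(is.na(segment_length_px(lm, "hip_left", "ankle_left")))

  expect_equal(px_to_cm(0, 72), 0)
  expect_equal(px_to_cm(150, 150), 2.54)
  expect_equal(px_to_cm(300, 150), 5.08)
  expect_error(px_to_cm(10, 0), "dpi")
  expect_error(px_to_cm(10, -150), "dpi")
  expect_error(px_to_cm(-5, 150), "non-negative")

  # conversion linearity: doubling dpi halves every value
  set.seed(1)
  px <- runif(50, 0, 2000)
  expect_equal(px_to_cm(px, 300), px_to_cm(px, 150) / 2)
})

test_that("extract_measurements reproduces the worked skeleton and propagates missingness", {
  ms <- extract_measurements(make_worked_session(wrist_y = 210))
  expect_equal(ms$arm_left_cm, 2.54)
  expect_equal(ms$total_height_cm, 5.08)  # vertical extent 300 px
  ms2 <- extract_measurements(make_worked_session(wrist_y = 240))
  expect_equal(ms2$arm_left_cm, 3.048)

  full <- extract_measurements(make_full_session())
  expect_true(all(!is.na(full[c("total_height_cm", "head_size_cm",
                                "shoulders_width_cm", "hips_width_cm",
                                "torso_length_cm", "arm_left_cm",
                                "arm_right_cm", "leg_left_cm", "leg_right_cm")])))

  # dropping one limb's feature only blanks that limb
  s <- make_full_session()
  s$features$present[s$features$feature == "arm_right"] <- FALSE
  part <- extract_measurements(s)
  expect_true(is.na(part$arm_right_cm))
  other <- setdiff(metric_parameters(), "arm_right_cm")
  expect_equal(part[other], full[other])
})

test_that("Euclidean parameters are rigid-motion invariant; total height is a vertical extent", {
  s <- make_full_session()
  base <- extract_measurements(s)
  euclid <- c("head_size_cm", "shoulders_width_cm", "hips_width_cm",
              "torso_length_cm", "arm_left_cm", "arm_right_cm",
              "leg_left_cm", "leg_right_cm")

  translate <- function(s, dx, dy) {
    s$landmarks$x_px <- s$landmarks$x_px + dx
    s$landmarks$y_px <- s$landmarks$y_px + dy
    s
  }
  shifted <- extract_measurements(translate(s, 100, -50))
  expect_equal(shifted[euclid], base[euclid])
  # horizontal translation leaves total height unchanged too
  expect_equal(extract_measurements(translate(s, 150, 0))$total_height_cm,
               base$total_height_cm)

  rotate <- function(s, theta) {
    cx <- mean(s$landmarks$x_px); cy <- mean(s$landmarks$y_px)
    x <- s$landmarks$x_px - cx; y <- s$landmarks$y_px - cy
    s$landmarks$x_px <- cx + x * cos(theta) - y * sin(theta)
    s$landmarks$y_px <- cy + x * sin(theta) + y * cos(theta)
    s
  }
  rot_s <- rotate(s, 20 * pi / 180)
  rot <- extract_measurements(rot_s)
  expect_equal(rot[euclid], base[euclid])
  # total height is the vertical extent of the rotated extremes, not the
  # (rotation-invariant) Euclidean span between them
  ylm <- function(ss, n) ss$landmarks$y_px[ss$landmarks$name == n]
  expect_equal(rot$total_height_cm,
               px_to_cm(abs(ylm(rot_s, "figure_bottommost") -
                              ylm(rot_s, "figure_topmost")), 150))
  expect_false(isTRUE(all.equal(rot$total_height_cm, base$total_height_cm)))
})

test_that("measurements recover generator ground truth exactly at zero noise", {
  cfg <- synth_config(n_patients = 8, n_controls = 6, seed = 99,
                      rater_noise_sd_px = 0)
  co <- generate_cohort(cfg)
  ms <- cohort_measurements(co)
  for (p in metric_parameters()) {
    expect_identical(is.na(ms[[p]]), is.na(co$truth[[p]]))
    rel <- abs(ms[[p]] - co$truth[[p]]) / pmax(abs(co$truth[[p]]), 1e-12)
    expect_lt(max(rel, na.rm = TRUE), 1e-9)
  }
})
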