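# Synthetic cohort generator: figure skeletons with known ground truth,
# simulated raters, and whole patient/control cohorts.

#' Synthetic cohort configuration
#'
#' Collects every knob of the generator. Defaults emulate the study design
#' the package targets: 56 chronic stroke patients and 46 healthy controls
#' drawing on an A4 sheet scanned at 150 dpi, patients shortening one arm by
#' a multiplicative factor `delta ~ N(0.15, 0.05)` (legs symmetric), both
#' groups drawing limbs with a small per-side length jitter, patients
#' omitting facial and appearance features more often than controls, and two
#' independent raters placing landmarks with 2 px noise per coordinate.
#'
#' All randomness flows from `seed` through named substreams (population,
#' then one per rater), so adding a rater never perturbs the cohort itself.
#'
#' @param n_patients,n_controls Group sizes.
#' @param seed Integer seed fixing all downstream randomness.
#' @param dpi Scan density (dots per inch).
#' @param page_width_cm,page_height_cm Page size (A4 portrait by default).
#' @param raters Character vector of simulated rater ids.
#' @param rater_noise_sd_px Per-coordinate landmark noise SD, in pixels.
#' @param part_means_cm,part_sds_cm Named lists of population mean/SD for
#'   `head_size`, `torso_length`, `shoulders_width`, `hips_width`,
#'   `arm_length`, `leg_length` (cm). Draws are truncated to mean +/- 2.5 SD
#'   (people scale their figure to the sheet), which also guarantees that
#'   default-parameter figures always fit an A4 page.
#' @param side_jitter_sd SD of the multiplicative per-side limb length
#'   jitter applied to both arms and both legs in both groups.
#' @param arm_asymmetry List `(mean, sd)` of the multiplicative shortening
#'   `delta` applied to one (randomly chosen) arm of each patient.
#' @param leg_asymmetry Same for legs; defaults to zero.
#' @param omission_probabilities List with elements `control` and `patient`,
#'   each a named numeric vector of per-feature omission probabilities.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 56L, n_controls = 46L, seed = 1905L,
                         dpi = 150, page_width_cm = 21.0, page_height_cm = 29.7,
                         raters = c("sim_rater_1", "sim_rater_2"),
                         rater_noise_sd_px = 2,
                         part_means_cm = list(head_size = 3.0, torso_length = 6.5,
                                              shoulders_width = 6.0, hips_width = 4.5,
                                              arm_length = 7.0, leg_length = 8.0),
                         part_sds_cm = list(head_size = 0.5, torso_length = 1.0,
                                            shoulders_width = 1.0, hips_width = 0.8,
                                            arm_length = 1.0, leg_length = 1.2),
                         side_jitter_sd = 0.03,
                         arm_asymmetry = list(mean = 0.15, sd = 0.05),
                         leg_asymmetry = list(mean = 0, sd = 0),
                         omission_probabilities = default_omission_probabilities()) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    seed = as.integer(seed), dpi = dpi,
    page_width_cm = page_width_cm, page_height_cm = page_height_cm,
    raters = raters, rater_noise_sd_px = rater_noise_sd_px,
    part_means_cm = part_means_cm, part_sds_cm = part_sds_cm,
    side_jitter_sd = side_jitter_sd,
    arm_asymmetry = arm_asymmetry, leg_asymmetry = leg_asymmetry,
    omission_probabilities = omission_probabilities
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_omission_probabilities <- function() {
  vocab <- feature_vocabulary()
  control <- setNames(rep(0.02, length(vocab)), vocab)
  control[c("hair", "clothes", "nose", "mouth")] <- c(0.05, 0.10, 0.10, 0.05)
  control[c("ear_left", "ear_right")] <- 0.30
  control[c("hand_left", "hand_right", "foot_left", "foot_right")] <- 0.10
  control["head"] <- 0
  # patients omit appearance/face features more often and limbs somewhat more
  patient <- setNames(rep(0.07, length(vocab)), vocab)
  patient[c("hair", "clothes", "nose", "mouth")] <- c(0.30, 0.35, 0.35, 0.25)
  patient[c("eye_left", "eye_right")] <- 0.15
  patient[c("ear_left", "ear_right")] <- 0.60
  patient[c("hand_left", "hand_right", "foot_left", "foot_right")] <- 0.30
  patient["head"] <- 0
  list(control = control, patient = patient)
}

validate_synth_config <- function(cfg) {
  if (cfg$n_patients < 0L || cfg$n_controls < 0L) {
    abort("group sizes must be non-negative")
  }
  if (cfg$rater_noise_sd_px < 0) abort("rater_noise_sd_px must be >= 0")
  if (cfg$side_jitter_sd < 0) abort("side_jitter_sd must be >= 0")
  for (grp in c("control", "patient")) {
    p <- cfg$omission_probabilities[[grp]]
    if (is.null(p) || !all(feature_vocabulary() %in% names(p))) {
      abort(sprintf("omission_probabilities$%s must name every feature", grp))
    }
    if (any(p < 0 | p > 1)) {
      abort(sprintf("omission_probabilities$%s must lie in [0, 1]", grp))
    }
  }
  for (nm in names(cfg$part_sds_cm)) {
    if (cfg$part_sds_cm[[nm]] < 0) abort(sprintf("part_sds_cm$%s must be >= 0", nm))
  }
  if (cfg$arm_asymmetry$sd < 0 || cfg$leg_asymmetry$sd < 0) {
    abort("asymmetry sd must be >= 0")
  }
  invisible(cfg)
}

# truncated-normal draw by rejection; degenerate sd returns the clamped mean
rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  x <- rnorm(n, mean, sd)
  while (any(bad <- (x < lo | x > hi))) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

ARM_ANGLE <- 35 * pi / 180  # from vertical, downward-outward
LEG_ANGLE <- 12 * pi / 180
NECK_CM <- 0.5

#' Sample one synthetic figure skeleton
#'
#' Draws one subject's figure geometry on the configured page and returns
#' the noiseless annotation session (rater id `"ground_truth"`), the true
#' measurement/asymmetry values, and the feature presence record. Uses the
#' RNG state in effect at the call (callers seed it; [generate_cohort()]
#' manages substreams).
#'
#' Geometry: head crown at the top, shoulders a short neck below the chin,
#' hips one torso length below the shoulders, arms from the shoulders and
#' legs from the hips angled downward-outward; the figure is centred on the
#' page. For patients one arm (side chosen at random) is scaled by
#' `1 - delta` with `delta` drawn from `arm_asymmetry`. Landmarks exist only
#' for parts drawn present; hands require their arm, feet their leg.
#'
#' @param config A [synth_config()].
#' @param group `"patient"` or `"control"`.
#' @param drawing_id Identifier stored in the session.
#' @return A list with elements `session`, `truth` (one-row tibble of true
#'   cm values, IoA and the shortening applied), `features`.
#' @export
sample_skeleton <- function(config, group = c("patient", "control"),
                            drawing_id = "synthetic") {
  group <- match.arg(group)
  mu <- config$part_means_cm
  sg <- config$part_sds_cm
  # population draws truncated to mean +/- 2.5 sd (floored at 20% of the
  # mean): drawers scale their figure to the sheet, so absurd tail values
  # are not part of the population model and every figure fits the page
  draw <- function(nm) {
    rtrunc(1, mu[[nm]], sg[[nm]],
           lo = max(0.2 * mu[[nm]], mu[[nm]] - 2.5 * sg[[nm]]),
           hi = mu[[nm]] + 2.5 * sg[[nm]])
  }
  head_cm <- draw("head_size")
  torso_cm <- draw("torso_length")
  shoulders_cm <- draw("shoulders_width")
  hips_cm <- draw("hips_width")
  arm_cm <- draw("arm_length")
  leg_cm <- draw("leg_length")

  jit <- rtrunc(4, 1, config$side_jitter_sd,
                lo = max(0.05, 1 - 2.5 * config$side_jitter_sd),
                hi = 1 + 2.5 * config$side_jitter_sd)
  # asymmetry draws are always consumed so the stream is group-independent
  delta_arm <- rtrunc(1, config$arm_asymmetry$mean, config$arm_asymmetry$sd,
                      lo = 0, hi = 0.9)
  delta_leg <- rtrunc(1, config$leg_asymmetry$mean, config$leg_asymmetry$sd,
                      lo = 0, hi = 0.9)
  affected_left <- runif(1) < 0.5
  if (group == "control") {
    delta_arm <- 0
    delta_leg <- 0
  }
  arm_l <- arm_cm * jit[1] * (1 - if (affected_left) delta_arm else 0)
  arm_r <- arm_cm * jit[2] * (1 - if (affected_left) 0 else delta_arm)
  leg_l <- leg_cm * jit[3] * (1 - if (affected_left) delta_leg else 0)
  leg_r <- leg_cm * jit[4] * (1 - if (affected_left) 0 else delta_leg)

  vocab <- feature_vocabulary()
  omit_p <- config$omission_probabilities[[group]][vocab]
  present <- runif(length(vocab)) >= omit_p
  names(present) <- vocab
  # dependent parts cannot outlive their parent limb
  present["hand_left"] <- present["hand_left"] && present["arm_left"]
  present["hand_right"] <- present["hand_right"] && present["arm_right"]
  present["foot_left"] <- present["foot_left"] && present["leg_left"]
  present["foot_right"] <- present["foot_right"] && present["leg_right"]

  leg_drop <- c(if (present["leg_left"]) leg_l * cos(LEG_ANGLE),
                if (present["leg_right"]) leg_r * cos(LEG_ANGLE), 0)
  figure_h <- head_cm + NECK_CM + torso_cm + max(leg_drop)
  if (figure_h > config$page_height_cm) {
    abort(sprintf(paste0("figure height %.1f cm exceeds the %.1f cm page; ",
                         "reduce head_size/torso_length/leg_length"),
                  figure_h, config$page_height_cm))
  }
  half_w <- max(shoulders_cm / 2 + max(arm_l, arm_r) * sin(ARM_ANGLE),
                hips_cm / 2 + max(leg_l, leg_r) * sin(LEG_ANGLE))
  if (half_w > config$page_width_cm / 2) {
    abort(sprintf(paste0("figure half-width %.1f cm exceeds the page; ",
                         "reduce shoulders_width/arm_length"), half_w))
  }

  cx <- config$page_width_cm / 2
  y0 <- (config$page_height_cm - figure_h) / 2
  y_sh <- y0 + head_cm + NECK_CM
  y_hp <- y_sh + torso_cm
  pts <- list(
    head_top = c(cx, y0),
    head_bottom = c(cx, y0 + head_cm),
    shoulder_left = c(cx - shoulders_cm / 2, y_sh),
    shoulder_right = c(cx + shoulders_cm / 2, y_sh),
    hip_left = c(cx - hips_cm / 2, y_hp),
    hip_right = c(cx + hips_cm / 2, y_hp)
  )
  if (present["arm_left"]) {
    pts$wrist_left <- pts$shoulder_left +
      c(-arm_l * sin(ARM_ANGLE), arm_l * cos(ARM_ANGLE))
  }
  if (present["arm_right"]) {
    pts$wrist_right <- pts$shoulder_right +
      c(arm_r * sin(ARM_ANGLE), arm_r * cos(ARM_ANGLE))
  }
  if (present["leg_left"]) {
    pts$ankle_left <- pts$hip_left +
      c(-leg_l * sin(LEG_ANGLE), leg_l * cos(LEG_ANGLE))
  }
  if (present["leg_right"]) {
    pts$ankle_right <- pts$hip_right +
      c(leg_r * sin(LEG_ANGLE), leg_r * cos(LEG_ANGLE))
  }
  if (!present["head"]) pts$head_top <- pts$head_bottom <- NULL

  ys <- vapply(pts, `[`, 0, 2L)
  top_name <- names(pts)[which.min(ys)]
  bot_name <- names(pts)[which.max(ys)]
  pts$figure_topmost <- pts[[top_name]]
  pts$figure_bottommost <- pts[[bot_name]]

  cm_to_px <- function(v) v / 2.54 * config$dpi
  lm <- tibble(
    name = names(pts),
    x_px = cm_to_px(vapply(pts, `[`, 0, 1L)),
    y_px = cm_to_px(vapply(pts, `[`, 0, 2L))
  )
  ft <- tibble(
    feature = vocab,
    present = unname(present),
    connected = ifelse(vocab %in% limb_features() & present,
                       "connected", "not_applicable")
  )
  session <- annotation_session(
    drawing_id = drawing_id,
    width_px = cm_to_px(config$page_width_cm),
    height_px = cm_to_px(config$page_height_cm),
    dpi = config$dpi, rater_id = "ground_truth",
    landmarks = lm, features = ft
  )

  val_or_na <- function(ok, v) if (ok) v else NA_real_
  t_arm_l <- val_or_na(present["arm_left"], arm_l)
  t_arm_r <- val_or_na(present["arm_right"], arm_r)
  t_leg_l <- val_or_na(present["leg_left"], leg_l)
  t_leg_r <- val_or_na(present["leg_right"], leg_r)
  truth <- tibble(
    drawing_id = drawing_id, group = group,
    total_height_cm = max(ys) - min(ys),
    head_size_cm = val_or_na(present["head"], head_cm),
    shoulders_width_cm = shoulders_cm,
    hips_width_cm = hips_cm,
    torso_length_cm = torso_cm,
    arm_left_cm = t_arm_l, arm_right_cm = t_arm_r,
    leg_left_cm = t_leg_l, leg_right_cm = t_leg_r,
    arm_ioa_pct = index_of_asymmetry(t_arm_l, t_arm_r),
    leg_ioa_pct = index_of_asymmetry(t_leg_l, t_leg_r),
    arm_shortening = delta_arm,
    affected_side = if (affected_left) "left" else "right"
  )
  list(session = session, truth = truth,
       features = tibble(drawing_id = drawing_id, group = group,
                         feature = vocab, present = unname(present)))
}

#' Simulate an annotator re-clicking a skeleton's landmarks
#'
#' Perturbs every landmark coordinate with independent Gaussian noise of SD
#' `noise_sd_px`, clipped to the page; feature records are copied faithfully
#' (detection errors are out of scope). Zero noise returns the landmarks
#' unchanged. Uses the RNG state in effect at the call.
#'
#' @param session A skeleton [annotation_session()].
#' @param rater_id Id recorded in the returned session.
#' @param noise_sd_px Per-coordinate noise SD in pixels, `>= 0`.
#' @return A new [annotation_session()].
#' @export
simulate_rater <- function(session, rater_id, noise_sd_px = 2) {
  stopifnot(inherits(session, "annotation_session"), noise_sd_px >= 0)
  lm <- session$landmarks
  n <- nrow(lm)
  if (noise_sd_px > 0 && n > 0) {
    lm$x_px <- pmin(pmax(lm$x_px + rnorm(n, 0, noise_sd_px), 0), session$width_px)
    lm$y_px <- pmin(pmax(lm$y_px + rnorm(n, 0, noise_sd_px), 0), session$height_px)
  }
  annotation_session(
    drawing_id = session$drawing_id,
    width_px = session$width_px, height_px = session$height_px,
    dpi = session$dpi, rater_id = rater_id,
    landmarks = lm, features = session$features, notes = session$notes
  )
}

#' Generate a whole synthetic cohort
#'
#' Samples `n_patients` patient and `n_controls` control skeletons, stores
#' their ground truth, and has every configured rater annotate each drawing
#' with independent landmark noise. Deterministic given `config$seed`: the
#' population is drawn from one substream and each rater from their own, so
#' the same seed always yields the same cohort and adding raters leaves the
#' skeletons untouched.
#'
#' @param config A [synth_config()].
#' @return A `drawing_cohort` list: `sessions` (tibble `subject_id`, `group`,
#'   `rater_id`, `session` list-column), `skeletons` (named list of
#'   noiseless sessions), `truth`, `features`, `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed %% 2147483647L)
  subseeds <- sample.int(2147483646L, 2L)

  ids <- c(sprintf("P%03d", seq_len(config$n_patients)),
           sprintf("C%03d", seq_len(config$n_controls)))
  groups <- c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  if (length(ids) == 0L) abort("cohort must contain at least one subject")

  set.seed(subseeds[1])
  skel <- purrr::map2(ids, groups, function(id, grp) {
    sample_skeleton(config, group = grp, drawing_id = id)
  })
  truth <- purrr::map_dfr(skel, "truth")
  features <- purrr::map_dfr(skel, "features") |>
    dplyr::rename(subject_id = "drawing_id")
  skeletons <- setNames(purrr::map(skel, "session"), ids)

  sessions <- purrr::imap(config$raters, function(rid, i) {
    set.seed((as.numeric(subseeds[2]) + i * 1000003) %% 2147483646 + 1)
    tibble(
      subject_id = ids, group = groups, rater_id = rid,
      session = purrr::map(skeletons, simulate_rater, rater_id = rid,
                           noise_sd_px = config$rater_noise_sd_px)
    )
  })
  structure(
    list(sessions = dplyr::bind_rows(sessions),
         skeletons = skeletons,
         truth = dplyr::rename(truth, subject_id = "drawing_id"),
         features = features, config = config),
    class = "drawing_cohort"
  )
}

#' @export
print.drawing_cohort <- function(x, ...) {
  cat(sprintf("<drawing_cohort> %d patients + %d controls, raters: %s\n",
              sum(x$truth$group == "patient"), sum(x$truth$group == "control"),
              paste(x$config$raters, collapse = ", ")))
  invisible(x)
}

#' Measure a cohort's sessions for one rater
#'
#' @param cohort A `drawing_cohort` from [generate_cohort()].
#' @param rater Rater id; defaults to the first configured rater.
#' @return A measurement tibble with `subject_id` and `group` attached.
#' @export
cohort_measurements <- function(cohort, rater = NULL) {
  stopifnot(inherits(cohort, "drawing_cohort"))
  rater <- rater %||% cohort$config$raters[[1]]
  rows <- cohort$sessions[cohort$sessions$rater_id == rater, ]
  if (nrow(rows) == 0L) abort(sprintf("no sessions for rater '%s'", rater))
  measure_sessions(rows$session) |>
    dplyr::mutate(subject_id = rows$subject_id, group = rows$group,
                  .before = 1L)
}
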