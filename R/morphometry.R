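# Morphometry: landmark geometry -> the nine metric parameters, in cm.

#' Euclidean distance between two named landmarks, in pixels
#'
#' Returns `NA_real_` when either landmark is absent: a missing landmark is
#' missing data, not an error, and propagates as a missing measurement.
#'
#' @param landmarks Tibble with columns `name`, `x_px`, `y_px`.
#' @param name_a,name_b Landmark names.
#' @return Length in pixels, or `NA_real_`.
#' @export
segment_length_px <- function(landmarks, name_a, name_b) {
  a <- landmarks[landmarks$name == name_a, ]
  b <- landmarks[landmarks$name == name_b, ]
  if (nrow(a) != 1L || nrow(b) != 1L) return(NA_real_)
  sqrt((a$x_px - b$x_px)^2 + (a$y_px - b$y_px)^2)
}

#' Convert a pixel length to centimetres
#'
#' `length_px / dpi * 2.54`: a scan at `dpi` dots per inch maps `dpi` pixels
#' to one inch (2.54 cm). Vectorised over `length_px`.
#'
#' @param length_px Length(s) in pixels (non-negative; `NA` passes through).
#' @param dpi Scan density in dots per inch; must be > 0.
#' @return Length(s) in cm.
#' @export
px_to_cm <- function(length_px, dpi = 150) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0) {
    abort("dpi must be a single positive number")
  }
  if (any(length_px < 0, na.rm = TRUE)) {
    abort("length_px must be non-negative")
  }
  length_px / dpi * 2.54
}

#' Extract the nine metric parameters from a session
#'
#' Measures, in cm:
#' * total height: vertical extent `|y(figure_bottommost) - y(figure_topmost)|`
#'   (what a ruler held against the sheet reads, even for a tilted figure);
#' * head size: crown-to-chin distance `head_top` to `head_bottom`;
#' * shoulders / hips width: distance between the left and right landmarks;
#' * torso length: mid-shoulder to mid-hip;
#' * arm length: shoulder-to-wrist, per side;
#' * leg length: hip-to-ankle, per side.
#'
#' A parameter is `NA` (never zero) whenever a required landmark is absent,
#' or — for head size and limb lengths — when the corresponding feature is
#' recorded absent. Disconnected limbs still contribute lengths when their
#' landmarks exist; connectedness is a recorded characteristic, not an
#' exclusion.
#'
#' @param session An [annotation_session()].
#' @param dpi Scan density for unit conversion; defaults to the session's.
#' @return A one-row tibble: `drawing_id`, `rater_id`, `dpi`, then the nine
#'   `*_cm` columns of [metric_parameters()].
#' @export
extract_measurements <- function(session, dpi = session$dpi) {
  stopifnot(inherits(session, "annotation_session"))
  lm <- session$landmarks
  ft <- session$features
  present <- function(f) {
    row <- ft[ft$feature == f, ]
    nrow(row) == 1L && isTRUE(row$present)
  }
  seg <- function(a, b) px_to_cm(segment_length_px(lm, a, b), dpi)
  gated <- function(f, a, b) if (present(f)) seg(a, b) else NA_real_

  ycoord <- function(name) {
    r <- lm[lm$name == name, ]
    if (nrow(r) != 1L) NA_real_ else r$y_px
  }
  total_height <- px_to_cm(abs(ycoord("figure_bottommost") - ycoord("figure_topmost")), dpi)

  mid <- function(a, b) {
    ra <- lm[lm$name == a, ]; rb <- lm[lm$name == b, ]
    if (nrow(ra) != 1L || nrow(rb) != 1L) return(NULL)
    c((ra$x_px + rb$x_px) / 2, (ra$y_px + rb$y_px) / 2)
  }
  msh <- mid("shoulder_left", "shoulder_right")
  mhp <- mid("hip_left", "hip_right")
  torso <- if (is.null(msh) || is.null(mhp)) NA_real_ else {
    px_to_cm(sqrt(sum((msh - mhp)^2)), dpi)
  }

  tibble(
    drawing_id = session$drawing_id,
    rater_id = session$rater_id,
    dpi = dpi,
    total_height_cm = total_height,
    head_size_cm = gated("head", "head_top", "head_bottom"),
    shoulders_width_cm = seg("shoulder_left", "shoulder_right"),
    hips_width_cm = seg("hip_left", "hip_right"),
    torso_length_cm = torso,
    arm_left_cm = gated("arm_left", "shoulder_left", "wrist_left"),
    arm_right_cm = gated("arm_right", "shoulder_right", "wrist_right"),
    leg_left_cm = gated("leg_left", "hip_left", "ankle_left"),
    leg_right_cm = gated("leg_right", "hip_right", "ankle_right")
  )
}

#' Measure a batch of sessions
#'
#' @param sessions A list of [annotation_session()] objects.
#' @return A tibble with one row per session (see [extract_measurements()]).
#' @export
measure_sessions <- function(sessions) {
  purrr::map_dfr(sessions, extract_measurements)
}
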