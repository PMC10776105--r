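# Deterministic raster rendering of figure skeletons, for visual sanity
# checks and I/O exercises. Strokes are 1-valued pixels on a 0 background.

# stamp points (row, col) into img, clipped to bounds
stamp <- function(img, rows, cols) {
  ok <- rows >= 1 & rows <= nrow(img) & cols >= 1 & cols <= ncol(img)
  img[cbind(rows[ok], cols[ok])] <- 1L
  img
}

# dense-sampled line segment between pixel coords (x = col, y = row)
draw_segment <- function(img, x0, y0, x1, y1) {
  n <- max(2L, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1L)
  t <- seq(0, 1, length.out = n)
  stamp(img, round(y0 + t * (y1 - y0)) + 1L, round(x0 + t * (x1 - x0)) + 1L)
}

draw_ellipse <- function(img, cx, cy, rx, ry) {
  n <- max(16L, ceiling(2 * pi * max(rx, ry)))
  t <- seq(0, 2 * pi, length.out = n)
  stamp(img, round(cy + ry * sin(t)) + 1L, round(cx + rx * cos(t)) + 1L)
}

#' Render a figure skeleton as a raster image
#'
#' Deterministic stick-figure rendering of a session's landmarks and present
#' features: an ellipse for the head, line strokes for torso, shoulder and
#' hip lines, arms and legs, small glyphs for hands, feet, eyes, ears, nose,
#' mouth, hair and clothes. Absent features are not drawn. The output is an
#' integer matrix of `height_px` rows by `width_px` columns with ink = 1.
#'
#' @param session An [annotation_session()] whose landmarks are on-page.
#' @return An integer matrix (`height_px` x `width_px`).
#' @export
render_figure <- function(session) {
  stopifnot(inherits(session, "annotation_session"))
  w <- ceiling(session$width_px)
  h <- ceiling(session$height_px)
  img <- matrix(0L, nrow = h, ncol = w)
  lm <- session$landmarks
  ft <- session$features
  pt <- function(name) {
    r <- lm[lm$name == name, ]
    if (nrow(r) != 1L) NULL else c(r$x_px, r$y_px)
  }
  on <- function(f) {
    r <- ft[ft$feature == f, ]
    nrow(r) == 1L && isTRUE(r$present)
  }
  seg <- function(a, b) {
    if (!is.null(a) && !is.null(b)) img <<- draw_segment(img, a[1], a[2], b[1], b[2])
  }
  dot <- function(p, r = 2) {
    if (!is.null(p)) img <<- draw_ellipse(img, p[1], p[2], r, r)
  }

  ht <- pt("head_top"); hb <- pt("head_bottom")
  sl <- pt("shoulder_left"); sr <- pt("shoulder_right")
  hl <- pt("hip_left"); hr <- pt("hip_right")
  head_c <- NULL; head_ry <- NULL
  if (on("head") && !is.null(ht) && !is.null(hb)) {
    head_c <- (ht + hb) / 2
    head_ry <- sqrt(sum((hb - ht)^2)) / 2
    img <- draw_ellipse(img, head_c[1], head_c[2], 0.7 * head_ry, head_ry)
  }
  seg(sl, sr)                                   # shoulder line
  seg(hl, hr)                                   # hip line
  if (!is.null(sl) && !is.null(sr) && !is.null(hl) && !is.null(hr)) {
    seg((sl + sr) / 2, (hl + hr) / 2)           # torso
  }
  if (on("arm_left")) seg(sl, pt("wrist_left"))
  if (on("arm_right")) seg(sr, pt("wrist_right"))
  if (on("leg_left")) seg(hl, pt("ankle_left"))
  if (on("leg_right")) seg(hr, pt("ankle_right"))
  if (on("hand_left")) dot(pt("wrist_left"), 4)
  if (on("hand_right")) dot(pt("wrist_right"), 4)
  foot <- function(p, dir) {
    if (!is.null(p)) img <<- draw_segment(img, p[1], p[2], p[1] + dir * 10, p[2])
  }
  if (on("foot_left")) foot(pt("ankle_left"), -1)
  if (on("foot_right")) foot(pt("ankle_right"), 1)

  if (!is.null(head_c)) {
    r_eye <- max(1, 0.12 * head_ry)
    if (on("eye_left")) dot(head_c + c(-0.3, -0.3) * head_ry, r_eye)
    if (on("eye_right")) dot(head_c + c(0.3, -0.3) * head_ry, r_eye)
    if (on("nose")) dot(head_c, max(1, 0.08 * head_ry))
    if (on("mouth")) {
      img <- draw_segment(img, head_c[1] - 0.3 * head_ry, head_c[2] + 0.4 * head_ry,
                          head_c[1] + 0.3 * head_ry, head_c[2] + 0.4 * head_ry)
    }
    if (on("ear_left")) dot(head_c + c(-0.75, 0) * head_ry, max(1, 0.15 * head_ry))
    if (on("ear_right")) dot(head_c + c(0.75, 0) * head_ry, max(1, 0.15 * head_ry))
    if (on("hair") && !is.null(ht)) {
      for (dx in seq(-0.5, 0.5, by = 0.25)) {
        x <- ht[1] + dx * head_ry
        img <- draw_segment(img, x, ht[2], x, max(0, ht[2] - 0.4 * head_ry))
      }
    }
  }
  if (on("clothes") && !is.null(sl) && !is.null(sr) && !is.null(hl) && !is.null(hr)) {
    mid_y <- (sl[2] + hl[2]) / 2
    img <- draw_segment(img, (sl[1] + hl[1]) / 2, mid_y, (sr[1] + hr[1]) / 2, mid_y)
  }
  img
}

#' Write a rendered figure to a PNG file
#'
#' @param img Matrix from [render_figure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_figure_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG files")
  }
  png::writePNG(1 - img, path)  # ink black on white
  invisible(path)
}
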