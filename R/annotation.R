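# Annotation model: landmark/feature vocabularies, session objects,
# validation and (de)serialization.

SESSION_FORMAT <- "drawmetry-annotation"
SESSION_VERSION <- 1L

#' Landmark and feature vocabularies
#'
#' The landmark vocabulary is the closed set of reference points placed on a
#' drawing from which the nine metric parameters are measured. The feature
#' vocabulary is the closed set of body features whose presence or absence is
#' recorded per drawing; limb features additionally record whether the limb
#' is drawn connected to the body.
#'
#' Coordinates follow the raster convention: origin at the top-left corner of
#' the scanned page, x growing rightward, y growing downward, units pixels.
#' `left`/`right` denote the viewer's side of the image, not the anatomical
#' side of the drawn figure.
#'
#' @return A character vector of vocabulary entries.
#' @export
landmark_vocabulary <- function() {
  c("head_top", "head_bottom",
    "shoulder_left", "shoulder_right",
    "hip_left", "hip_right",
    "wrist_left", "wrist_right",
    "ankle_left", "ankle_right",
    "figure_topmost", "figure_bottommost")
}

#' @rdname landmark_vocabulary
#' @export
feature_vocabulary <- function() {
  c("head", "hair", "clothes", "nose", "mouth",
    "eye_left", "eye_right", "ear_left", "ear_right",
    "arm_left", "arm_right", "hand_left", "hand_right",
    "leg_left", "leg_right", "foot_left", "foot_right")
}

#' @rdname landmark_vocabulary
#' @export
limb_features <- function() {
  c("arm_left", "arm_right", "hand_left", "hand_right",
    "leg_left", "leg_right", "foot_left", "foot_right")
}

#' @rdname landmark_vocabulary
#' @export
metric_parameters <- function() {
  c("total_height_cm", "head_size_cm", "shoulders_width_cm",
    "hips_width_cm", "torso_length_cm",
    "arm_left_cm", "arm_right_cm", "leg_left_cm", "leg_right_cm")
}

# landmarks a present feature must carry for its measurement to exist
measurement_landmarks <- function() {
  list(
    head      = c("head_top", "head_bottom"),
    arm_left  = c("shoulder_left", "wrist_left"),
    arm_right = c("shoulder_right", "wrist_right"),
    leg_left  = c("hip_left", "ankle_left"),
    leg_right = c("hip_right", "ankle_right")
  )
}

#' Construct an annotation session
#'
#' One rater's annotation of one drawing: page metadata, a set of landmark
#' coordinates in pixels, and one presence record per body feature.
#'
#' @param drawing_id Identifier of the drawing (string).
#' @param width_px,height_px Page dimensions of the scanned image in pixels.
#' @param dpi Scan density in dots per inch (default 150).
#' @param rater_id Identifier of the annotator.
#' @param landmarks Tibble with columns `name`, `x_px`, `y_px`, or `NULL` for
#'   no landmarks. Names must come from [landmark_vocabulary()].
#' @param features Either a tibble with columns `feature`, `present`,
#'   `connected`, or a character vector naming the present features (all
#'   others are recorded absent; present limbs default to `"connected"`).
#' @param notes Free-text notes (e.g. figure orientation).
#'
#' @return An object of class `annotation_session`.
#' @export
annotation_session <- function(drawing_id, width_px, height_px, dpi = 150,
                               rater_id = "unknown", landmarks = NULL,
                               features = character(), notes = "") {
  stopifnot(is.character(drawing_id), length(drawing_id) == 1L,
            is.character(rater_id), length(rater_id) == 1L,
            is.numeric(width_px), is.numeric(height_px), is.numeric(dpi),
            is.character(notes), length(notes) == 1L)
  if (is.null(landmarks)) {
    landmarks <- tibble(name = character(), x_px = numeric(), y_px = numeric())
  }
  landmarks <- as_tibble(landmarks)
  stopifnot(all(c("name", "x_px", "y_px") %in% names(landmarks)))
  landmarks <- tibble(name = as.character(landmarks$name),
                      x_px = as.numeric(landmarks$x_px),
                      y_px = as.numeric(landmarks$y_px))
  if (is.character(features)) {
    features <- default_features(present = features)
  }
  features <- as_tibble(features)
  stopifnot(all(c("feature", "present", "connected") %in% names(features)))
  features <- tibble(feature = as.character(features$feature),
                     present = as.logical(features$present),
                     connected = as.character(features$connected))
  structure(
    list(drawing_id = drawing_id,
         width_px = as.numeric(width_px), height_px = as.numeric(height_px),
         dpi = as.numeric(dpi), rater_id = rater_id,
         landmarks = landmarks, features = features, notes = notes),
    class = "annotation_session"
  )
}

#' @rdname annotation_session
#' @param present Character vector of features marked present.
#' @export
default_features <- function(present = character()) {
  vocab <- feature_vocabulary()
  unknown <- setdiff(present, vocab)
  if (length(unknown) > 0L) {
    abort(paste0("unknown feature name(s): ", paste(unknown, collapse = ", ")))
  }
  is_present <- vocab %in% present
  tibble(
    feature = vocab,
    present = is_present,
    connected = ifelse(vocab %in% limb_features() & is_present,
                       "connected", "not_applicable")
  )
}

#' @export
print.annotation_session <- function(x, ...) {
  cat(sprintf("<annotation_session> drawing %s, rater %s\n",
              x$drawing_id, x$rater_id))
  cat(sprintf("  page %g x %g px at %g dpi\n", x$width_px, x$height_px, x$dpi))
  cat(sprintf("  %d landmarks, %d/%d features present\n",
              nrow(x$landmarks), sum(x$features$present), nrow(x$features)))
  invisible(x)
}

#' Validate an annotation session
#'
#' Checks every structural invariant of a session and returns a character
#' vector of human-readable issues, one per violation; a valid session yields
#' an empty vector. Validation never raises: it is meant for batch QC where a
#' bad file must not stop the run.
#'
#' Checks: positive page dimensions and dpi; landmark names drawn from the
#' vocabulary, at most one per name; coordinates within the page; exactly one
#' feature record per vocabulary entry; `connected` set to `not_applicable`
#' exactly for non-limb features or absent limbs; every present measurable
#' part (head, arms, legs) carries the landmarks its measurement needs.
#'
#' @param session An [annotation_session()].
#' @return Character vector of issues (empty when the session is valid).
#' @export
validate_session <- function(session) {
  issues <- character()
  say <- function(...) issues <<- c(issues, sprintf(...))

  if (!inherits(session, "annotation_session")) {
    return("not an annotation_session object")
  }
  if (!is.finite(session$dpi) || session$dpi <= 0) {
    say("dpi must be > 0 (got %s)", format(session$dpi))
  }
  if (!is.finite(session$width_px) || session$width_px <= 0) {
    say("width_px must be > 0 (got %s)", format(session$width_px))
  }
  if (!is.finite(session$height_px) || session$height_px <= 0) {
    say("height_px must be > 0 (got %s)", format(session$height_px))
  }

  lm <- session$landmarks
  bad <- setdiff(lm$name, landmark_vocabulary())
  for (b in bad) say("unknown landmark name: %s", b)
  dup <- unique(lm$name[duplicated(lm$name)])
  for (d in dup) say("duplicated landmark: %s", d)
  oob <- lm$x_px < 0 | lm$x_px > session$width_px |
    lm$y_px < 0 | lm$y_px > session$height_px
  oob[is.na(oob)] <- TRUE
  for (i in which(oob)) {
    say("landmark %s at (%g, %g) is outside the page [0, %g] x [0, %g]",
        lm$name[i], lm$x_px[i], lm$y_px[i],
        session$width_px, session$height_px)
  }

  ft <- session$features
  vocab <- feature_vocabulary()
  bad <- setdiff(ft$feature, vocab)
  for (b in bad) say("unknown feature name: %s", b)
  missing <- setdiff(vocab, ft$feature)
  for (m in missing) say("missing feature record: %s", m)
  dup <- unique(ft$feature[duplicated(ft$feature)])
  for (d in dup) say("duplicated feature record: %s", d)
  bad_conn <- !ft$connected %in% c("connected", "disconnected", "not_applicable")
  for (i in which(bad_conn)) {
    say("feature %s has invalid connected value: %s", ft$feature[i], ft$connected[i])
  }
  limb <- ft$feature %in% limb_features()
  for (i in which(!limb & ft$connected != "not_applicable")) {
    say("non-limb feature %s must have connected = not_applicable", ft$feature[i])
  }
  for (i in which(limb & ft$present & ft$connected == "not_applicable")) {
    say("present limb %s must be connected or disconnected", ft$feature[i])
  }

  need <- measurement_landmarks()
  for (part in names(need)) {
    row <- ft[ft$feature == part, ]
    if (nrow(row) == 1L && isTRUE(row$present)) {
      for (lname in setdiff(need[[part]], lm$name)) {
        say("feature %s is present but landmark %s is missing", part, lname)
      }
    }
  }
  issues
}

#' Read and write annotation sessions
#'
#' The canonical on-disk format is a structured, human-diffable YAML document
#' (one session per file) with a required `format`/`version` header.
#' `write_session()` stores coordinates with 17 significant digits so that
#' `read_session(write_session(s))` reproduces `s` exactly.
#'
#' @param session An [annotation_session()].
#' @param path File path.
#' @return `read_session()` returns an [annotation_session()];
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "annotation_session"))
  doc <- list(
    format = SESSION_FORMAT,
    version = SESSION_VERSION,
    drawing_id = session$drawing_id,
    rater_id = session$rater_id,
    image = list(width_px = session$width_px,
                 height_px = session$height_px,
                 dpi = session$dpi),
    notes = session$notes,
    landmarks = purrr::pmap(session$landmarks, function(name, x_px, y_px) {
      list(name = name, x_px = x_px, y_px = y_px)
    }),
    features = purrr::pmap(session$features, function(feature, present, connected) {
      list(feature = feature, present = present, connected = connected)
    })
  )
  txt <- yaml::as.yaml(doc, precision = 17L)
  writeLines(txt, path, sep = "")
  invisible(path)
}

parse_abort <- function(...) {
  abort(sprintf(...), class = "drawmetry_parse_error")
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  doc <- tryCatch(yaml::yaml.load_file(path),
                  error = function(e) {
                    parse_abort("cannot parse %s: %s", path, conditionMessage(e))
                  })
  if (is.null(doc) || length(doc) == 0L) {
    parse_abort("no session found in %s", path)
  }
  if (!identical(doc$format, SESSION_FORMAT)) {
    parse_abort("%s: not a %s file (format field: %s)",
                path, SESSION_FORMAT, doc$format %||% "<missing>")
  }
  if (!identical(as.integer(doc$version), SESSION_VERSION)) {
    parse_abort("%s: unsupported version %s (expected %d)",
                path, doc$version %||% "<missing>", SESSION_VERSION)
  }
  for (f in c("drawing_id", "rater_id", "image")) {
    if (is.null(doc[[f]])) parse_abort("%s: missing field '%s'", path, f)
  }
  lms <- doc$landmarks %||% list()
  lm_tbl <- purrr::map_dfr(lms, function(l) {
    if (is.null(l$name) || is.null(l$x_px) || is.null(l$y_px)) {
      parse_abort("%s: landmark entry missing name/x_px/y_px", path)
    }
    if (!l$name %in% landmark_vocabulary()) {
      parse_abort("%s: unknown landmark name '%s'", path, l$name)
    }
    tibble(name = l$name, x_px = as.numeric(l$x_px), y_px = as.numeric(l$y_px))
  })
  if (nrow(lm_tbl) == 0L) {
    lm_tbl <- tibble(name = character(), x_px = numeric(), y_px = numeric())
  }
  fts <- doc$features %||% list()
  ft_tbl <- purrr::map_dfr(fts, function(f) {
    if (is.null(f$feature) || is.null(f$present) || is.null(f$connected)) {
      parse_abort("%s: feature entry missing feature/present/connected", path)
    }
    if (!f$feature %in% feature_vocabulary()) {
      parse_abort("%s: unknown feature name '%s'", path, f$feature)
    }
    tibble(feature = f$feature, present = as.logical(f$present),
           connected = as.character(f$connected))
  })
  if (nrow(ft_tbl) == 0L) {
    ft_tbl <- default_features()
  }
  annotation_session(
    drawing_id = as.character(doc$drawing_id),
    width_px = as.numeric(doc$image$width_px),
    height_px = as.numeric(doc$image$height_px),
    dpi = as.numeric(doc$image$dpi %||% 150),
    rater_id = as.character(doc$rater_id),
    landmarks = lm_tbl, features = ft_tbl,
    notes = as.character(doc$notes %||% "")
  )
}

#' Export a session as flat key-value text
#'
#' Mirrors the flat `.txt` report style of legacy drawing-analysis tools:
#' one `key = value` line per feature (presence, connectedness) and per
#' metric parameter (value in cm, or `MISSING` when the parameter cannot be
#' measured). Output is UTF-8 with LF line endings, deterministically
#' ordered, and byte-identical across repeated calls on the same session.
#'
#' @param session A valid [annotation_session()].
#' @param dpi Scan density used for the pixel-to-cm conversion; defaults to
#'   the session's own dpi.
#' @return A single string (the text block).
#' @export
export_legacy_txt <- function(session, dpi = session$dpi) {
  stopifnot(inherits(session, "annotation_session"))
  ms <- extract_measurements(session, dpi = dpi)
  fmt_num <- function(x) {
    if (is.na(x)) "MISSING" else format(x, digits = 15, trim = TRUE, scientific = FALSE)
  }
  lines <- c(
    sprintf("format = drawmetry-legacy-v1"),
    sprintf("drawing_id = %s", session$drawing_id),
    sprintf("rater_id = %s", session$rater_id),
    sprintf("dpi = %s", fmt_num(dpi))
  )
  ft <- session$features
  for (f in feature_vocabulary()) {
    row <- ft[ft$feature == f, ]
    present <- nrow(row) == 1L && isTRUE(row$present)
    lines <- c(lines, sprintf("feature.%s.present = %s", f,
                              if (present) "present" else "absent"))
    if (f %in% limb_features()) {
      conn <- if (nrow(row) == 1L) row$connected else "not_applicable"
      lines <- c(lines, sprintf("feature.%s.connected = %s", f, conn))
    }
  }
  for (m in metric_parameters()) {
    lines <- c(lines, sprintf("metric.%s = %s", m, fmt_num(ms[[m]])))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname export_legacy_txt
#' @param text A string produced by `export_legacy_txt()`.
#' @return `parse_legacy_txt()` returns a tibble with columns `key`, `value`.
#' @export
parse_legacy_txt <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  m <- regexec("^([^=]+?)\\s*=\\s*(.*)$", lines)
  parts <- regmatches(lines, m)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    parse_abort("malformed key-value line: '%s'", lines[which(bad)[1]])
  }
  tibble(key = vapply(parts, `[[`, "", 2L),
         value = vapply(parts, `[[`, "", 3L))
}
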