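# Session fixtures built in code.

# full-figure session on a 1240 x 1754 page (A4 at 150 dpi) with simple
# hand-checkable geometry
make_full_session <- function(dpi = 150, rater_id = "r1") {
  lm <- tibble::tribble(
    ~name,               ~x_px, ~y_px,
    "head_top",            620,   200,
    "head_bottom",         620,   380,
    "shoulder_left",       440,   420,
    "shoulder_right",      800,   420,
    "hip_left",            490,   800,
    "hip_right",           750,   800,
    "wrist_left",          240,   740,
    "wrist_right",        1000,   740,
    "ankle_left",          420,  1300,
    "ankle_right",         820,  1300,
    "figure_topmost",      620,   200,
    "figure_bottommost",   820,  1300
  )
  annotation_session(
    "full_fig", 1240, 1754, dpi = dpi, rater_id = rater_id,
    landmarks = lm,
    features = c("head", "hair", "nose", "mouth", "eye_left", "eye_right",
                 "arm_left", "arm_right", "leg_left", "leg_right")
  )
}

# the worked skeleton used in the morphometry examples
make_worked_session <- function(wrist_y = 210) {
  lm <- tibble::tribble(
    ~name,               ~x_px, ~y_px,
    "shoulder_left",        30,    60,
    "wrist_left",           30, wrist_y,
    "figure_topmost",       50,    10,
    "figure_bottommost",    55,   310
  )
  annotation_session("worked", 1240, 1754, dpi = 150, rater_id = "r1",
                     landmarks = lm, features = c("arm_left"))
}

# randomized valid session (all invariants hold), full-precision coordinates
random_valid_session <- function(id = "rand") {
  vocab <- drawmetry::feature_vocabulary()
  present <- runif(length(vocab)) < 0.8
  names(present) <- vocab
  present["hand_left"] <- present["hand_left"] && present["arm_left"]
  present["hand_right"] <- present["hand_right"] && present["arm_right"]
  present["foot_left"] <- present["foot_left"] && present["leg_left"]
  present["foot_right"] <- present["foot_right"] && present["leg_right"]
  need <- list(head = c("head_top", "head_bottom"),
               arm_left = c("shoulder_left", "wrist_left"),
               arm_right = c("shoulder_right", "wrist_right"),
               leg_left = c("hip_left", "ankle_left"),
               leg_right = c("hip_right", "ankle_right"))
  names_needed <- unique(c(unlist(need[names(need)[present[names(need)]]]),
                           "figure_topmost", "figure_bottommost"))
  lm <- tibble::tibble(
    name = names_needed,
    x_px = runif(length(names_needed), 0, 1240),
    y_px = runif(length(names_needed), 0, 1754)
  )
  ft <- tibble::tibble(
    feature = vocab,
    present = unname(present),
    connected = ifelse(vocab %in% drawmetry::limb_features() & present,
                       sample(c("connected", "disconnected"), length(vocab), TRUE),
                       "not_applicable")
  )
  annotation_session(id, 1240, 1754, dpi = 150,
                     rater_id = sample(c("a", "b"), 1),
                     landmarks = lm, features = ft,
                     notes = "synthetic random session")
}
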