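#' Exercise specification
#'
#' A parameterized eccentric-viewing task. `skills` is a named numeric vector
#' mapping the skills the task exercises to the proficiency level (in
#' \[0, 1\]) required to complete it comfortably; the recommender matches these
#' requirements against the patient's ability model. `complexity_rank` encodes
#' the designed ordering of recognition difficulty (solid figures < hollow
#' figures < bold letters < non-bold letters, and onward through objects,
#' faces, scenes and letter lines).
#'
#' @param id exercise number (the demonstration keeps id 1)
#' @param version `"initial"` or `"revised"`
#' @param task_kind one of `demo`, `figure_single_fixation`,
#'   `figure_alternating_fixation`, `real_objects`, `faces`, `scene_search`,
#'   `letter_lines`
#' @param target list with `image` (designated target) and `pool`
#'   (image family identifiers; rendering is out of scope)
#' @param label human-readable description
#' @param skills named numeric vector of required skill levels
#' @param complexity_rank integer recognition-difficulty rank (0 = demo)
#' @param is_exercise `FALSE` for the demonstration entry, which is shown to
#'   the patient but not counted or recommended as an exercise
#' @param params list overriding the defaults: `inter_stimulus_s`,
#'   `n_stimuli`, `stimulus_size_cm`, `duration_s`, `fixation_mode`
#'   (`single`/`alternating`/`none`), `response_mode`
#'   (`touch_target`/`touch_anywhere`), `voice_guided`, `forced_voice`,
#'   `min_target_repeats`, `sequential_fixation`
#' @return an object of class `exercise_spec`
#' @export
exercise_spec <- function(id, version, task_kind, target, label, skills,
                          complexity_rank, is_exercise = TRUE, params = list()) {
  defaults <- list(
    inter_stimulus_s = 10, n_stimuli = 10L, stimulus_size_cm = 2,
    duration_s = NULL, fixation_mode = "single", response_mode = "touch_target",
    voice_guided = FALSE, forced_voice = FALSE, min_target_repeats = 1L,
    sequential_fixation = FALSE
  )
  p <- utils::modifyList(defaults, params)
  if (isTRUE(p$forced_voice)) p$voice_guided <- TRUE
  if (is.null(p$duration_s)) p$duration_s <- p$n_stimuli * p$inter_stimulus_s
  if (p$inter_stimulus_s <= 0 || p$n_stimuli < 1 || p$stimulus_size_cm <= 0) {
    stop_rehab("exercise timing, count and size parameters must be positive",
               "eyerehab_domain_error")
  }
  structure(
    list(id = id, version = version, task_kind = task_kind, target = target,
         label = label, skills = skills, complexity_rank = as.integer(complexity_rank),
         is_exercise = isTRUE(is_exercise), params = p),
    class = "exercise_spec"
  )
}

figure_pools <- list(
  solid = c("circle_solid", "square_solid", "triangle_solid", "star_solid"),
  hollow = c("circle_hollow", "square_hollow", "triangle_hollow", "star_hollow"),
  bold_letters = c("A_bold", "E_bold", "H_bold", "N_bold", "R_bold"),
  plain_letters = c("A_plain", "E_plain", "H_plain", "N_plain", "R_plain"),
  drinks = c("water", "juice", "soda", "coffee", "milk", "wine"),
  faces = c("face_woman_1", "face_man_1", "face_woman_2", "face_man_2"),
  room_objects = c("lamp", "chair", "table", "sofa", "clock", "vase"),
  letters = c("A", "B", "C", "D", "E", "F", "G", "H")
)

#' Exercise catalogue
#'
#' Returns the initial catalogue of 15 exercises or the revised catalogue
#' produced by user testing: exercise 1 recast as a demonstration (not counted
#' as an exercise), exercises 2-5 and 10 switched to touch-anywhere responses
#' with the inter-stimulus interval reduced from 10 s to 5 s, exercises 6-9
#' converted to sequential alternating fixation with voice guidance (a switch
#' of fixation point is prompted after a missed target), exercise 10 requiring
#' the target at least twice with a reduced default size, exercises 11 and 12
#' merged into a single faces exercise with touch-anywhere dynamics, exercise
#' 13 with a fixed fixation dot and compulsory voice guidance, and exercises
#' 14-15 removed as too difficult. The revised catalogue therefore holds 11
#' exercises plus one demonstration entry.
#'
#' @param version `"initial"` or `"revised"`
#' @return list of [exercise_spec()] objects
#' @examples
#' length(catalogue("initial")) # 15
#' sum(vapply(catalogue("revised"), function(s) s$is_exercise, logical(1))) # 11
#' @export
catalogue <- function(version = c("revised", "initial")) {
  version <- match.arg(version)
  fam <- list(
    list(pool = "solid", skill = "shape_recognition", level = 0.30, rank = 1L, size = 2.0),
    list(pool = "hollow", skill = "shape_recognition", level = 0.45, rank = 2L, size = 2.0),
    list(pool = "bold_letters", skill = "letter_recognition", level = 0.50, rank = 3L, size = 1.5),
    list(pool = "plain_letters", skill = "letter_recognition", level = 0.65, rank = 4L, size = 1.5)
  )
  tgt <- function(pool) list(image = figure_pools[[pool]][1], pool = figure_pools[[pool]])

  if (version == "initial") {
    specs <- list(
      exercise_spec(1L, version, "demo", tgt("solid"),
                    "Demonstration of the interaction",
                    c(fixation_stability = 0.10), 0L,
                    params = list(response_mode = "touch_anywhere", n_stimuli = 5L,
                                  stimulus_size_cm = 3))
    )
    for (i in seq_along(fam)) {
      f <- fam[[i]]
      specs[[length(specs) + 1L]] <- exercise_spec(
        i + 1L, version, "figure_single_fixation", tgt(f$pool),
        sprintf("Identify the requested %s (single fixation)", f$pool),
        stats::setNames(c(0.3 + 0.05 * i, f$level), c("fixation_stability", f$skill)),
        f$rank, params = list(stimulus_size_cm = f$size)
      )
    }
    for (i in seq_along(fam)) {
      f <- fam[[i]]
      specs[[length(specs) + 1L]] <- exercise_spec(
        i + 5L, version, "figure_alternating_fixation", tgt(f$pool),
        sprintf("Identify the requested %s, alternating fixation", f$pool),
        stats::setNames(c(0.4 + 0.05 * i, f$level, 0.45 + 0.05 * i),
                        c("fixation_stability", f$skill, "fixation_alternation")),
        f$rank + 2L,
        params = list(stimulus_size_cm = f$size, fixation_mode = "alternating")
      )
    }
    specs[[length(specs) + 1L]] <- exercise_spec(
      10L, version, "real_objects", tgt("drinks"),
      "Identify the requested drink among real objects",
      c(fixation_stability = 0.40, object_recognition = 0.50), 3L,
      params = list(stimulus_size_cm = 2.0)
    )
    specs[[length(specs) + 1L]] <- exercise_spec(
      11L, version, "faces", list(image = "face_woman_1", pool = figure_pools$faces),
      "Touch the indicated part of a woman's face",
      c(face_recognition = 0.60, eccentric_localization = 0.50), 4L,
      params = list(stimulus_size_cm = 2.5)
    )
    specs[[length(specs) + 1L]] <- exercise_spec(
      12L, version, "faces", list(image = "face_man_1", pool = figure_pools$faces),
      "Touch the indicated part of a man's face",
      c(face_recognition = 0.60, eccentric_localization = 0.50), 4L,
      params = list(stimulus_size_cm = 2.5)
    )
    specs[[length(specs) + 1L]] <- exercise_spec(
      13L, version, "scene_search", list(image = "lamp", pool = figure_pools$room_objects),
      "Find the requested object in a furnished room (moving fixation dot)",
      c(scene_search = 0.65, eccentric_localization = 0.55), 5L,
      params = list(stimulus_size_cm = 2.0)
    )
    specs[[length(specs) + 1L]] <- exercise_spec(
      14L, version, "letter_lines", list(image = "A", pool = figure_pools$letters),
      "Tap the requested letters across three lines (no fixation point)",
      c(letter_recognition = 0.75, scene_search = 0.60), 6L,
      params = list(fixation_mode = "none", stimulus_size_cm = 1.2)
    )
    specs[[length(specs) + 1L]] <- exercise_spec(
      15L, version, "letter_lines", list(image = "E", pool = figure_pools$letters),
      "Tap the requested letters across three lines, smaller print",
      c(letter_recognition = 0.85, scene_search = 0.65), 6L,
      params = list(fixation_mode = "none", stimulus_size_cm = 0.9)
    )
    return(specs)
  }

  # revised catalogue
  specs <- list(
    exercise_spec(1L, version, "demo", tgt("solid"),
                  "Demonstration (not counted as an exercise)",
                  c(fixation_stability = 0.10), 0L, is_exercise = FALSE,
                  params = list(response_mode = "touch_anywhere", n_stimuli = 5L,
                                stimulus_size_cm = 3, inter_stimulus_s = 5))
  )
  for (i in seq_along(fam)) {
    f <- fam[[i]]
    specs[[length(specs) + 1L]] <- exercise_spec(
      i + 1L, version, "figure_single_fixation", tgt(f$pool),
      sprintf("Identify the requested %s (touch anywhere)", f$pool),
      stats::setNames(c(0.3 + 0.05 * i, f$level), c("fixation_stability", f$skill)),
      f$rank,
      params = list(stimulus_size_cm = f$size, inter_stimulus_s = 5,
                    response_mode = "touch_anywhere")
    )
  }
  for (i in seq_along(fam)) {
    f <- fam[[i]]
    specs[[length(specs) + 1L]] <- exercise_spec(
      i + 5L, version, "figure_alternating_fixation", tgt(f$pool),
      sprintf("Identify the requested %s, sequential alternating fixation", f$pool),
      stats::setNames(c(0.4 + 0.05 * i, f$level, 0.45 + 0.05 * i),
                      c("fixation_stability", f$skill, "fixation_alternation")),
      f$rank + 2L,
      params = list(stimulus_size_cm = f$size, fixation_mode = "alternating",
                    sequential_fixation = TRUE, voice_guided = TRUE)
    )
  }
  specs[[length(specs) + 1L]] <- exercise_spec(
    10L, version, "real_objects", tgt("drinks"),
    "Identify the requested drink (target shown at least twice, smaller)",
    c(fixation_stability = 0.40, object_recognition = 0.50), 3L,
    params = list(stimulus_size_cm = 1.5, inter_stimulus_s = 5,
                  response_mode = "touch_anywhere", min_target_repeats = 2L)
  )
  specs[[length(specs) + 1L]] <- exercise_spec(
    11L, version, "faces", list(image = "face_woman_1", pool = figure_pools$faces),
    "Touch the screen when the requested face appears",
    c(face_recognition = 0.60, eccentric_localization = 0.50), 4L,
    params = list(stimulus_size_cm = 2.5, inter_stimulus_s = 5,
                  response_mode = "touch_anywhere")
  )
  specs[[length(specs) + 1L]] <- exercise_spec(
    13L, version, "scene_search", list(image = "lamp", pool = figure_pools$room_objects),
    "Find the requested object in the room (fixed dot, voice guided)",
    c(scene_search = 0.65, eccentric_localization = 0.55), 5L,
    params = list(stimulus_size_cm = 2.0, inter_stimulus_s = 8, forced_voice = TRUE)
  )
  specs
}

#' Look up a catalogue spec by id
#'
#' @param id exercise id
#' @param version catalogue version
#' @return an `exercise_spec`
#' @export
catalogue_spec <- function(id, version = "revised") {
  specs <- catalogue(version)
  ids <- vapply(specs, function(s) s$id, integer(1))
  hit <- which(ids == id)
  if (length(hit) == 0) stop_rehab(sprintf("no exercise with id %s", id),
                                   "eyerehab_not_found")
  specs[[hit[1]]]
}

#' The practitioner-adjustable exercise parameters
#'
#' @return character vector of parameter names a practitioner may edit
#' @export
adjustable_params <- function() {
  c("inter_stimulus_s", "n_stimuli", "stimulus_size_cm", "duration_s")
}

#' Edit exercise parameters (practitioner only)
#'
#' Only the practitioner role may change exercise parameters, and only the
#' timing/count/size/duration set; voice guidance on a forced-voice exercise
#' cannot be disabled.
#'
#' @param spec an `exercise_spec`
#' @param params named list of new parameter values
#' @param actor_role role attempting the change
#' @return the updated spec
#' @export
set_exercise_params <- function(spec, params, actor_role) {
  if (!identical(actor_role, "practitioner")) {
    stop_rehab("only the practitioner can modify exercise parameters",
               "eyerehab_permission_error")
  }
  bad <- setdiff(names(params), adjustable_params())
  if (length(bad)) {
    stop_rehab(paste("parameters not adjustable:", paste(bad, collapse = ", ")),
               "eyerehab_permission_error")
  }
  spec$params <- utils::modifyList(spec$params, params)
  if (isTRUE(spec$params$forced_voice)) spec$params$voice_guided <- TRUE
  spec
}

#' Sanitize a user-entered timing value
#'
#' Each exercise shows its recommended time pre-filled; if the user clears it
#' and starts without entering a new one, the default is restored
#' automatically. Non-numeric or non-positive entries are also replaced by the
#' default, with a warning of class `eyerehab_timing_corrected`.
#'
#' @param raw_input user-entered value (may be `NULL`, `NA`, `""`)
#' @param default the exercise's default duration in seconds
#' @return a positive duration in seconds
#' @export
sanitize_timing <- function(raw_input, default) {
  if (is.null(raw_input) || length(raw_input) == 0) return(default)
  val <- suppressWarnings(as.numeric(raw_input))
  if (is.na(val)) {
    if (is.character(raw_input) && !nzchar(trimws(raw_input))) return(default)
    warning(warningCondition(
      sprintf("invalid timing %s replaced by default %g s", deparse(raw_input), default),
      class = "eyerehab_timing_corrected"))
    return(default)
  }
  if (val <= 0) {
    warning(warningCondition(
      sprintf("non-positive timing %g replaced by default %g s", val, default),
      class = "eyerehab_timing_corrected"))
    return(default)
  }
  val
}

fixation_points <- function(spec, grid = grid_spec()) {
  if (identical(spec$params$fixation_mode, "alternating")) {
    # first fixation on the right, second on the left
    rbind(c(grid$width_cm / 4, 0), c(-grid$width_cm / 4, 0))
  } else {
    rbind(c(0, 0))
  }
}

#' Build a seeded stimulus stream for an exercise
#'
#' Draws the presentation schedule: the designated target interleaved with
#' filler images from the same family (no immediate filler repetition), every
#' stimulus positioned at the treatment-area offset from the active fixation
#' point. The target occurs at least `min_target_repeats` times (two for the
#' revised real-objects exercise). Alternating-fixation exercises start at the
#' first (right-hand) fixation point; realized switches are produced by
#' [run_exercise()]. Identical `(spec, area, seed)` yield identical streams.
#'
#' @param spec an [exercise_spec()]
#' @param area a [treatment_area()]
#' @param seed integer seed
#' @param grid reference [grid_spec()] used for placement checks
#' @return an object of class `stimulus_stream`
#' @export
build_stimulus_stream <- function(spec, area, seed = 1L, grid = grid_spec()) {
  stopifnot(inherits(spec, "exercise_spec"), inherits(area, "treatment_area"))
  p <- spec$params
  n <- p$n_stimuli
  fix <- fixation_points(spec, grid)
  # placement check: the projected stimulus must stay on the conceptual grid
  for (k in seq_len(nrow(fix))) {
    if (!in_grid(grid, fix[k, 1] + area$x_cm, fix[k, 2] + area$y_cm)) {
      stop_rehab("treatment-area offset places stimuli outside the grid",
                 "eyerehab_placement_error")
    }
  }
  events <- withr::with_seed(seed, {
    n_target <- min(n, max(p$min_target_repeats, stats::rbinom(1L, n, 0.3)))
    tpos <- sort(sample.int(n, n_target))
    fillers <- setdiff(spec$target$pool, spec$target$image)
    imgs <- character(n)
    last <- ""
    for (i in seq_len(n)) {
      if (i %in% tpos) {
        imgs[i] <- spec$target$image
      } else {
        choices <- setdiff(fillers, last)
        imgs[i] <- choices[sample.int(length(choices), 1L)]
      }
      last <- imgs[i]
    }
    data.frame(
      index = seq_len(n),
      onset_s = (seq_len(n) - 1) * p$inter_stimulus_s,
      duration_s = p$inter_stimulus_s,
      image = imgs,
      is_target = seq_len(n) %in% tpos,
      fixation_id = 1L,
      fixation_x = fix[1, 1], fixation_y = fix[1, 2],
      x_cm = fix[1, 1] + area$x_cm, y_cm = fix[1, 2] + area$y_cm
    )
  })
  structure(
    list(spec_id = spec$id, version = spec$version, seed = as.integer(seed),
         area = area, response_mode = p$response_mode,
         fixation = fix, events = events),
    class = "stimulus_stream"
  )
}

#' Exercise result
#'
#' Stored outcome of a session: the number of correct answers (hits),
#' incorrect answers (unanswered targets plus false-alarm taps) and attempts
#' (taps plus target presentations), with per-hit reaction times.
#'
#' @param spec_id exercise id
#' @param hits,misses,attempts non-negative counts; `hits` can never exceed
#'   `attempts`
#' @param reaction_times numeric vector of per-hit reaction times (s)
#' @param eye_mode `"monocular"` or `"binocular"` as instructed (recorded only)
#' @param timestamp orderable scalar
#' @return an object of class `exercise_result`
#' @export
exercise_result <- function(spec_id, hits, misses, attempts,
                            reaction_times = numeric(), eye_mode = "binocular",
                            timestamp = 0) {
  if (hits < 0 || misses < 0 || attempts < 0 || hits > attempts) {
    stop_rehab("inconsistent hit/miss/attempt counts", "eyerehab_domain_error")
  }
  structure(
    list(spec_id = spec_id, hits = as.integer(hits), misses = as.integer(misses),
         attempts = as.integer(attempts), reaction_times = reaction_times,
         eye_mode = eye_mode, timestamp = timestamp),
    class = "exercise_result"
  )
}

#' Score a session from a stream and a list of responses
#'
#' In touch-anywhere mode a tap falling inside a target event's window is a
#' hit for that event (one hit per event; surplus taps count as attempts); a
#' tap during a non-target window or between windows is a false alarm; an
#' unanswered target is a miss. Misses are unanswered targets plus false
#' alarms; attempts are taps plus target presentations. In touch-target mode
#' the response must additionally carry `on_target = TRUE` (a boolean oracle
#' for the hit test) to count as a hit.
#'
#' @param stream a [build_stimulus_stream()] stream
#' @param responses data.frame with `time_s` (tap times in session seconds)
#'   and, for touch-target exercises, logical `on_target`
#' @param eye_mode,timestamp stored on the result
#' @return an [exercise_result()]
#' @export
score_session <- function(stream, responses, eye_mode = "binocular", timestamp = 0) {
  stopifnot(inherits(stream, "stimulus_stream"))
  ev <- stream$events
  if (is.null(responses) || nrow(responses) == 0) {
    responses <- data.frame(time_s = numeric(), on_target = logical())
  }
  if (any(responses$time_s < 0 | responses$time_s > max(ev$onset_s + ev$duration_s))) {
    stop_rehab("responses fall outside the session window", "eyerehab_domain_error")
  }
  need_target <- identical(stream$response_mode, "touch_target")
  on_target <- if ("on_target" %in% names(responses)) responses$on_target else
    rep(TRUE, nrow(responses))

  hit_event <- logical(nrow(ev))
  rts <- numeric(0)
  false_alarms <- 0L
  for (j in seq_len(nrow(responses))) {
    t <- responses$time_s[j]
    i <- which(t >= ev$onset_s & t < ev$onset_s + ev$duration_s)
    valid <- length(i) == 1 && ev$is_target[i[1]] && (!need_target || isTRUE(on_target[j]))
    if (valid && !hit_event[i[1]]) {
      hit_event[i[1]] <- TRUE
      rts <- c(rts, t - ev$onset_s[i[1]])
    } else if (!valid) {
      false_alarms <- false_alarms + 1L
    }
    # surplus taps on an already-hit target count only toward attempts
  }
  n_targets <- sum(ev$is_target)
  hits <- sum(hit_event)
  misses <- (n_targets - hits) + false_alarms
  attempts <- nrow(responses) + n_targets
  exercise_result(stream$spec_id, hits, misses, attempts, rts, eye_mode, timestamp)
}

#' Run an exercise against a responder, realizing fixation switches
#'
#' Walks the stimulus stream event by event. For sequential
#' alternating-fixation exercises (revised 6-9) the active fixation point
#' switches after a missed target, prompting the patient to try the other
#' point; in the initial simultaneous variant the patient switches after each
#' successful identification. Every event's position is the treatment-area
#' offset from the fixation point active at that moment.
#'
#' `responder` is a function `(event, difficulty, skills)` returning
#' `list(tap =, rt_s =)`; a [make_patient()] object is also accepted.
#'
#' @param spec an [exercise_spec()]
#' @param area a [treatment_area()]
#' @param responder response callback or `simulated_patient`
#' @param seed integer seed (stream and, for a simulated patient, responses)
#' @param grid reference [grid_spec()]
#' @param eye_mode,timestamp stored on the result
#' @return list with the realized `stream`, the `responses` data.frame and the
#'   scored `result`
#' @export
run_exercise <- function(spec, area, responder, seed = 1L, grid = grid_spec(),
                         eye_mode = "binocular", timestamp = 0) {
  stream <- build_stimulus_stream(spec, area, seed, grid)
  d <- difficulty_index(spec)
  if (inherits(responder, "simulated_patient")) {
    patient <- responder
    # the simulated patient only ever taps on (detected) targets
    responder <- function(event, difficulty, skills) {
      if (!isTRUE(event$is_target)) return(list(tap = FALSE, rt_s = NA_real_))
      respond_exercise(patient, difficulty, skills)
    }
    run_seed <- combine_seeds(patient$seed, seed)
  } else {
    run_seed <- combine_seeds(seed, 7L)
  }
  fix <- stream$fixation
  sequential <- isTRUE(spec$params$sequential_fixation)
  alternating <- identical(spec$params$fixation_mode, "alternating")

  withr::with_seed(run_seed, {
    ev <- stream$events
    active <- 1L
    taps <- data.frame(time_s = numeric(), on_target = logical())
    for (i in seq_len(nrow(ev))) {
      ev$fixation_id[i] <- active
      ev$fixation_x[i] <- fix[active, 1]
      ev$fixation_y[i] <- fix[active, 2]
      ev$x_cm[i] <- fix[active, 1] + stream$area$x_cm
      ev$y_cm[i] <- fix[active, 2] + stream$area$y_cm
      resp <- responder(as.list(ev[i, ]), d, spec$skills)
      tapped <- isTRUE(resp$tap)
      if (tapped) {
        rt <- min(resp$rt_s %||% (ev$duration_s[i] / 2), ev$duration_s[i] * 0.999)
        taps <- rbind(taps, data.frame(time_s = ev$onset_s[i] + rt, on_target = TRUE))
      }
      if (alternating && ev$is_target[i]) {
        switch_now <- if (sequential) !tapped else tapped
        if (switch_now) active <- 3L - active
      }
    }
    stream$events <- ev
    result <- score_session(stream, taps, eye_mode, timestamp)
    list(stream = stream, responses = taps, result = result)
  })
}
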