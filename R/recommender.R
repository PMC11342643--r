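#' Default skill taxonomy
#'
#' Skills exercised by the catalogue and tracked by the ability model.
#'
#' @return character vector of skill names
#' @export
default_skills <- function() {
  c("fixation_stability", "fixation_alternation", "shape_recognition",
    "letter_recognition", "object_recognition", "face_recognition",
    "scene_search", "eccentric_localization")
}

#' Patient ability model
#'
#' Per-skill ability scores in \[0, 1\] updated as an exponentially weighted
#' moving average of session success rates (learning rate `alpha`), plus a
#' running-mean reaction-time tendency per skill. Age and recorded visual
#' difficulties shift the initial prior only (older patients and more
#' difficulties start slightly lower); they have no per-session effect.
#'
#' @param skills skill names to track
#' @param prior initial ability score applied to every skill
#' @param alpha learning rate of the ability update in (0, 1\]
#' @param age optional patient age in years
#' @param impairments optional character vector of recorded visual difficulties
#' @return an object of class `ability_model`
#' @export
ability_model <- function(skills = default_skills(), prior = 0.5, alpha = 0.3,
                          age = NULL, impairments = NULL) {
  if (alpha <= 0 || alpha > 1) stop_rehab("alpha must lie in (0, 1]",
                                          "eyerehab_domain_error")
  if (!is.null(age)) prior <- prior - 0.005 * max(0, age - 60)
  if (!is.null(impairments)) prior <- prior - 0.02 * length(impairments)
  prior <- clamp01(prior)
  structure(
    list(
      ability = stats::setNames(rep(prior, length(skills)), skills),
      rt_mean = stats::setNames(rep(NA_real_, length(skills)), skills),
      rt_n = stats::setNames(rep(0L, length(skills)), skills),
      alpha = alpha, sessions = 0L
    ),
    class = "ability_model"
  )
}

#' Update the ability model from a session result
#'
#' Each skill required by the exercise moves toward the session success rate
#' `hits / (hits + misses)` with learning rate `alpha`; the per-skill reaction
#' time tendency is updated as a running mean of the session's hit reaction
#' times. A session with no scoreable outcomes leaves the model unchanged.
#'
#' @param model an [ability_model()]
#' @param result an [exercise_result()] for `spec`
#' @param spec the [exercise_spec()] that produced `result`
#' @param alpha learning-rate override (defaults to the model's)
#' @return the updated model
#' @export
update_ability <- function(model, result, spec, alpha = model$alpha) {
  stopifnot(inherits(model, "ability_model"), inherits(result, "exercise_result"),
            inherits(spec, "exercise_spec"))
  if (!identical(result$spec_id, spec$id)) {
    stop_rehab("result does not belong to this exercise spec",
               "eyerehab_domain_error")
  }
  total <- result$hits + result$misses
  if (total == 0) return(model)
  s <- result$hits / total
  for (sk in names(spec$skills)) {
    old <- model$ability[sk]
    if (is.na(old)) old <- 0.5
    model$ability[sk] <- clamp01((1 - alpha) * old + alpha * s)
  }
  if (length(result$reaction_times)) {
    m <- mean(result$reaction_times)
    k <- length(result$reaction_times)
    for (sk in names(spec$skills)) {
      n0 <- model$rt_n[sk]
      old <- if (n0 > 0) model$rt_mean[sk] else 0
      model$rt_mean[sk] <- (old * n0 + m * k) / (n0 + k)
      model$rt_n[sk] <- n0 + k
    }
  }
  model$sessions <- model$sessions + 1L
  model
}

#' Requirement-weighted aggregate ability for an exercise
#'
#' Mean of the per-skill abilities touched by the exercise, weighted by the
#' required level of each skill.
#'
#' @param model an [ability_model()]
#' @param spec an [exercise_spec()]
#' @return scalar ability in \[0, 1\]
#' @export
aggregate_ability <- function(model, spec) {
  w <- spec$skills
  a <- model$ability[names(w)]
  a[is.na(a)] <- 0.5
  sum(w * a) / sum(w)
}

#' Per-skill reaction-time tendency flags
#'
#' @param model an [ability_model()]
#' @param slow_threshold_s reaction-time mean above which a skill is flagged slow
#' @return named character vector: `"slow"`, `"fast"` or `"unknown"` per skill
#' @export
rt_tendency <- function(model, slow_threshold_s = 1.5) {
  ifelse(model$rt_n == 0, "unknown",
         ifelse(model$rt_mean > slow_threshold_s, "slow", "fast"))
}

#' Scalar difficulty index of an exercise
#'
#' Combines the recognition-complexity rank with the stimulus size and the
#' inter-stimulus interval into a single index in \[0, 1\]: strictly
#' increasing in rank, strictly decreasing in size and interval (smaller,
#' faster stimuli of harder image families are harder to detect
#' eccentrically).
#'
#' @param spec an [exercise_spec()]
#' @return numeric difficulty in \[0, 1\]
#' @export
difficulty_index <- function(spec) {
  p <- spec$params
  d <- 0.5 * (spec$complexity_rank / 6) +
    0.3 / (1 + p$stimulus_size_cm / 2) +
    0.2 / (1 + p$inter_stimulus_s / 5)
  clamp01(d)
}

#' Self-adjust exercise difficulty from a session result
#'
#' When negative results exceed positive ones (misses > hits) the exercise is
#' made one step easier (larger stimulus, longer interval) so as not to
#' frustrate the patient; when the success rate exceeds the upper edge of the
#' target band the exercise is made one step harder (smaller stimulus,
#' slightly shorter interval) to keep the patient challenged; otherwise it is
#' returned unchanged (ties hold). Step sizes are multiplicative with caps
#' (size in \[0.2, 5\] cm, interval in \[1, 15\] s); at a cap the spec may be
#' returned unchanged.
#'
#' @param spec an [exercise_spec()]
#' @param result an [exercise_result()] for this spec
#' @param band numeric length-2 target success band
#' @return the adjusted spec, with an `"adjustment"` attribute
#'   (`"easier"`, `"harder"` or `"hold"`)
#' @export
adjust_difficulty <- function(spec, result, band = c(0.6, 0.8)) {
  stopifnot(inherits(spec, "exercise_spec"), inherits(result, "exercise_result"))
  total <- result$hits + result$misses
  tag <- "hold"
  p <- spec$params
  if (total > 0) {
    s <- result$hits / total
    if (result$misses > result$hits) {
      p$stimulus_size_cm <- min(5, p$stimulus_size_cm * 1.25)
      p$inter_stimulus_s <- min(15, p$inter_stimulus_s + 1)
      tag <- "easier"
    } else if (s > band[2] && result$hits > result$misses) {
      p$stimulus_size_cm <- max(0.2, p$stimulus_size_cm * 0.8)
      p$inter_stimulus_s <- max(1, p$inter_stimulus_s * 0.9)
      tag <- "harder"
    }
  }
  p$duration_s <- p$n_stimuli * p$inter_stimulus_s
  spec$params <- p
  attr(spec, "adjustment") <- tag
  spec
}

#' Recommend the next exercise
#'
#' Content-based selection: among the practitioner-enabled exercises, picks
#' the one whose difficulty index is closest from above to the patient's
#' requirement-weighted aggregate ability plus a margin `delta`, keeping the
#' prescribed challenge slightly above the current ability level. If no
#' enabled exercise lies above the target, the closest one below (the hardest
#' reachable) is chosen. Ties break deterministically toward the lower
#' exercise id. As a safety rule, after a session in which misses exceeded
#' hits the next recommendation never escalates above that session's
#' difficulty.
#'
#' @param model an [ability_model()]
#' @param enabled_specs non-empty list of enabled [exercise_spec()]s
#'   (demonstration entries are ignored)
#' @param history optional session history data.frame from
#'   [run_selection_loop()] (columns `completed`, `hits`, `misses`,
#'   `difficulty`) used for the rationale tag and the no-escalation rule
#' @param delta challenge margin above ability
#' @return object of class `recommendation`: list with `spec`, `difficulty`,
#'   `target` and `rationale` (`"easier"`, `"harder"` or `"hold"` relative to
#'   the previous session)
#' @export
recommend_next <- function(model, enabled_specs, history = NULL, delta = 0.1) {
  specs <- Filter(function(s) isTRUE(s$is_exercise), enabled_specs)
  if (length(specs) == 0) {
    stop_rehab("the practitioner has not enabled any exercise",
               "eyerehab_precondition_error")
  }
  ids <- vapply(specs, function(s) as.numeric(s$id), numeric(1))
  specs <- specs[order(ids)]
  ids <- sort(ids)
  d <- vapply(specs, difficulty_index, numeric(1))
  agg <- vapply(specs, function(s) aggregate_ability(model, s), numeric(1))
  target <- pmin(1, agg + delta)
  score <- d - target

  last <- NULL
  if (!is.null(history) && nrow(history) > 0) {
    done <- history[history$completed, , drop = FALSE]
    if (nrow(done) > 0) last <- done[nrow(done), ]
  }
  allowed <- rep(TRUE, length(specs))
  if (!is.null(last) && last$misses > last$hits) {
    allowed <- d <= last$difficulty + 1e-9
    if (!any(allowed)) allowed <- d == min(d)
  }
  cand <- which(allowed)
  above <- cand[score[cand] >= 0]
  pick <- if (length(above)) {
    above[order(score[above], ids[above])][1]
  } else {
    cand[order(-score[cand], ids[cand])][1]
  }
  rationale <- "hold"
  if (!is.null(last)) {
    if (d[pick] < last$difficulty - 1e-9) rationale <- "easier"
    else if (d[pick] > last$difficulty + 1e-9) rationale <- "harder"
  }
  structure(
    list(spec = specs[[pick]], difficulty = d[pick], target = target[pick],
         rationale = rationale),
    class = "recommendation"
  )
}

#' Run the automatic exercise selection loop
#'
#' Iterates recommend -> execute -> store -> update: the next exercise is
#' recommended, executed by the responder (a [make_patient()] simulated
#' patient or a function `(spec, difficulty)` returning an
#' [exercise_result()]), its result appended to the history, the ability
#' model updated, and the executed exercise's parameters self-adjusted for
#' the next time it is chosen. A simulated patient may skip whole sessions
#' with probability `1 - compliance_prob`; skipped sessions are recorded but
#' neither scored nor used for updates. The entire trajectory is a pure
#' function of `(model, specs, responder, seed)`.
#'
#' @param model starting [ability_model()]
#' @param enabled_specs practitioner-enabled exercise list
#' @param responder `simulated_patient` or result-producing function
#' @param n_sessions number of sessions to run (>= 1)
#' @param seed integer seed for all randomness in the loop
#' @param delta,band recommender margin and target success band
#' @return list with `history` (one row per session), the final `model` and
#'   the parameter-adjusted `specs`
#' @export
run_selection_loop <- function(model, enabled_specs, responder, n_sessions,
                               seed = 1L, delta = 0.1, band = c(0.6, 0.8)) {
  if (n_sessions < 1) stop_rehab("n_sessions must be at least 1",
                                 "eyerehab_precondition_error")
  specs <- enabled_specs
  ids <- vapply(specs, function(s) as.numeric(s$id), numeric(1))
  patient <- if (inherits(responder, "simulated_patient")) responder else NULL

  withr::with_seed(seed, {
    rows <- vector("list", n_sessions)
    for (session in seq_len(n_sessions)) {
      history <- if (session > 1) do.call(rbind, rows[seq_len(session - 1)]) else NULL
      rec <- tryCatch(
        recommend_next(model, specs, history, delta),
        error = function(e) e
      )
      if (inherits(rec, "error")) {
        rows[[session]] <- data.frame(
          session = session, spec_id = NA_integer_, difficulty = NA_real_,
          rationale = "error", completed = FALSE, hits = NA_integer_,
          misses = NA_integer_, attempts = NA_integer_, success = NA_real_,
          ability = NA_real_, error = conditionMessage(rec)
        )
        break
      }
      spec <- rec$spec

      skipped <- !is.null(patient) &&
        stats::runif(1) > patient$compliance_prob
      if (skipped) {
        rows[[session]] <- data.frame(
          session = session, spec_id = spec$id, difficulty = rec$difficulty,
          rationale = rec$rationale, completed = FALSE, hits = NA_integer_,
          misses = NA_integer_, attempts = NA_integer_, success = NA_real_,
          ability = aggregate_ability(model, spec), error = NA_character_
        )
        next
      }

      result <- if (!is.null(patient)) {
        simulate_exercise_session(patient, spec, rec$difficulty)
      } else {
        tryCatch(responder(spec, rec$difficulty), error = identity)
      }
      if (inherits(result, "error")) {
        rows[[session]] <- data.frame(
          session = session, spec_id = spec$id, difficulty = rec$difficulty,
          rationale = rec$rationale, completed = FALSE, hits = NA_integer_,
          misses = NA_integer_, attempts = NA_integer_, success = NA_real_,
          ability = aggregate_ability(model, spec),
          error = conditionMessage(result)
        )
        break
      }

      model <- update_ability(model, result, spec)
      i <- which(ids == as.numeric(spec$id))[1]
      specs[[i]] <- adjust_difficulty(spec, result, band)
      total <- result$hits + result$misses
      rows[[session]] <- data.frame(
        session = session, spec_id = spec$id, difficulty = rec$difficulty,
        rationale = rec$rationale, completed = TRUE, hits = result$hits,
        misses = result$misses, attempts = result$attempts,
        success = if (total > 0) result$hits / total else NA_real_,
        ability = aggregate_ability(model, spec), error = NA_character_
      )
    }
    history <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(history) <- NULL
    list(history = history, model = model, specs = specs)
  })
}

#' Rolling session success rate
#'
#' Mean success rate over the most recent `window` completed sessions at each
#' completed session (skipped sessions yield `NA` and are excluded from the
#' window).
#'
#' @param history a [run_selection_loop()] history
#' @param window number of completed sessions averaged
#' @return numeric vector aligned with `history` rows
#' @export
rolling_success <- function(history, window = 10L) {
  out <- rep(NA_real_, nrow(history))
  done <- which(history$completed)
  for (k in seq_along(done)) {
    i <- done[max(1, k - window + 1):k]
    out[done[k]] <- mean(history$success[i])
  }
  out
}

#' Check compliance with the prescribed exercise program
#'
#' Raises the practitioner alert flag when the patient completed fewer
#' sessions than prescribed over the evaluation window (a prescription of
#' zero never alerts).
#'
#' @param completed completed-session count, or a [run_selection_loop()]
#'   history whose `completed` column is summed
#' @param prescribed sessions prescribed for the window
#' @return object of class `compliance_record`: list with `prescribed`,
#'   `completed`, `alert`
#' @export
check_compliance <- function(completed, prescribed) {
  if (is.data.frame(completed)) completed <- sum(completed$completed)
  if (prescribed < 0 || completed < 0) {
    stop_rehab("session counts must be non-negative", "eyerehab_domain_error")
  }
  structure(
    list(prescribed = as.integer(prescribed), completed = as.integer(completed),
         alert = prescribed > 0 && completed < prescribed),
    class = "compliance_record"
  )
}
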