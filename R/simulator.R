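#' Create a synthetic AMD patient
#'
#' A deterministic responder factory emulating a patient with a localized
#' central scotoma: detection probability is low inside the scotoma and high
#' outside, with an optional linear probability ramp of width
#' `edge_softness_cm` across the border. Exercise responses follow a logistic
#' psychometric function of (ability - difficulty); reaction times are drawn
#' from a truncated normal; whole sessions may be skipped with probability
#' `1 - compliance_prob`. All responses are reproducible from the seeds.
#'
#' Config entries (all optional, defaults shown):
#' \describe{
#'   \item{scotoma}{`list(shape = "block", center_row = 10, center_col = 10,
#'     half_cells = 1)` - an axis-aligned cell block (default: 3 x 3 cells at
#'     the grid center, the typical central AMD lesion) - or
#'     `list(shape = "disk", x_cm =, y_cm =, radius_cm =)`.}
#'   \item{p_detect_inside / p_detect_outside}{0.05 / 0.98}
#'   \item{edge_softness_cm}{0 (hard edge)}
#'   \item{true_ability}{0.9, scalar or named per-skill vector in \[0, 1\]}
#'   \item{logistic_slope}{8 (steepness of the psychometric function on the
#'     unit difficulty scale)}
#'   \item{rt_mean_s / rt_sd_s / rt_floor_s}{0.9 / 0.3 / 0.2 seconds}
#'   \item{compliance_prob}{1 (per-session attendance probability)}
#' }
#'
#' @param config list of overrides, see Details
#' @param seed integer seed owned by the patient
#' @param grid [grid_spec()] used to resolve cell-based scotoma definitions
#' @return an object of class `simulated_patient`
#' @export
make_patient <- function(config = list(), seed = 1L, grid = grid_spec()) {
  defaults <- list(
    scotoma = list(shape = "block", center_row = 10L, center_col = 10L,
                   half_cells = 1L),
    p_detect_inside = 0.05, p_detect_outside = 0.98, edge_softness_cm = 0,
    true_ability = 0.9, logistic_slope = 8,
    rt_mean_s = 0.9, rt_sd_s = 0.3, rt_floor_s = 0.2,
    compliance_prob = 1
  )
  cfg <- utils::modifyList(defaults, config)
  if (cfg$p_detect_inside < 0 || cfg$p_detect_outside > 1 ||
      cfg$p_detect_inside >= cfg$p_detect_outside) {
    stop_rehab("need 0 <= p_detect_inside < p_detect_outside <= 1",
               "eyerehab_config_error")
  }
  if (cfg$compliance_prob < 0 || cfg$compliance_prob > 1) {
    stop_rehab("compliance_prob must lie in [0, 1]", "eyerehab_config_error")
  }
  sc <- cfg$scotoma
  if (identical(sc$shape, "block")) {
    rows <- (sc$center_row - sc$half_cells):(sc$center_row + sc$half_cells)
    cols <- (sc$center_col - sc$half_cells):(sc$center_col + sc$half_cells)
    rows <- rows[rows >= 0 & rows < grid$n_rows]
    cols <- cols[cols >= 0 & cols < grid$n_cols]
    # cell-block bounding rectangle in centred cm coordinates
    sc$rect <- c(
      x0 = -grid$width_cm / 2 + min(cols) * grid$spacing_cm,
      x1 = -grid$width_cm / 2 + (max(cols) + 1) * grid$spacing_cm,
      y0 = grid$height_cm / 2 - (max(rows) + 1) * grid$spacing_cm,
      y1 = grid$height_cm / 2 - min(rows) * grid$spacing_cm
    )
    sc$cells <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  } else if (!identical(sc$shape, "disk")) {
    stop_rehab("scotoma shape must be 'block' or 'disk'", "eyerehab_config_error")
  }
  cfg$scotoma <- sc
  cfg$seed <- as.integer(seed)
  cfg$grid <- grid
  structure(cfg, class = "simulated_patient")
}

#' Ground-truth scotoma cells of a simulated patient
#'
#' @param patient a [make_patient()] patient
#' @return data.frame of 0-based `row`, `col` cells inside the scotoma
#' @export
true_scotoma_cells <- function(patient) {
  sc <- patient$scotoma
  if (identical(sc$shape, "block")) {
    d <- sc$cells
    rownames(d) <- NULL
    return(d)
  }
  cells <- cell_centers(patient$grid)
  r <- sqrt((cells$x_cm - sc$x_cm)^2 + (cells$y_cm - sc$y_cm)^2)
  cells[r <= sc$radius_cm, c("row", "col")]
}

# Signed distance (cm) from a point to the scotoma border: negative inside.
scotoma_signed_distance <- function(patient, x_cm, y_cm) {
  sc <- patient$scotoma
  if (identical(sc$shape, "disk")) {
    return(sqrt((x_cm - sc$x_cm)^2 + (y_cm - sc$y_cm)^2) - sc$radius_cm)
  }
  r <- sc$rect
  dx <- pmax(r["x0"] - x_cm, x_cm - r["x1"])
  dy <- pmax(r["y0"] - y_cm, y_cm - r["y1"])
  outside <- sqrt(pmax(dx, 0)^2 + pmax(dy, 0)^2)
  inside <- pmin(pmax(dx, dy), 0)
  unname(outside + inside)
}

#' Detection probability at a grid position
#'
#' `p_detect_inside` inside the scotoma, `p_detect_outside` outside, linearly
#' interpolated over the `edge_softness_cm` window straddling the border (a
#' point exactly on the border sits at the midpoint).
#'
#' @param patient a [make_patient()] patient
#' @param x_cm,y_cm position in centred cm coordinates
#' @return detection probability
#' @export
detection_probability <- function(patient, x_cm, y_cm) {
  d <- scotoma_signed_distance(patient, x_cm, y_cm)
  s <- patient$edge_softness_cm
  if (s <= 0) {
    frac <- as.numeric(d > 0)
  } else {
    frac <- clamp01(d / s + 0.5)
  }
  patient$p_detect_inside + (patient$p_detect_outside - patient$p_detect_inside) * frac
}

# Truncated-normal reaction time on [floor, upper].
draw_rt <- function(patient, upper = Inf) {
  for (i in 1:1000) {
    r <- stats::rnorm(1, patient$rt_mean_s, patient$rt_sd_s)
    if (r >= patient$rt_floor_s && r <= upper) return(r)
  }
  min(max(patient$rt_floor_s, patient$rt_mean_s), upper)
}

#' Respond to a single Amsler-grid stimulus
#'
#' Bernoulli detection at the stimulus position (see
#' [detection_probability()]); when seen, the reaction time is drawn truncated
#' to the display-plus-response window. Draws from the current RNG stream -
#' wrap in a seed context (as [simulate_test()] does) for reproducibility.
#'
#' @param patient a [make_patient()] patient
#' @param stimulus list with `x_cm`, `y_cm`, `display_s`, `response_window_s`
#' @return list with `seen` and `rt_s`
#' @export
respond_amsler <- function(patient, stimulus) {
  p <- detection_probability(patient, stimulus$x_cm, stimulus$y_cm)
  seen <- stats::runif(1) < p
  rt <- if (seen) {
    draw_rt(patient, upper = stimulus$display_s + stimulus$response_window_s)
  } else {
    NA_real_
  }
  list(seen = seen, rt_s = rt)
}

#' Responder closure for [run_test()]
#'
#' @param patient a [make_patient()] patient
#' @return function mapping a stimulus event to `list(seen =, rt_s =)`
#' @export
amsler_responder <- function(patient) {
  force(patient)
  function(stimulus) respond_amsler(patient, stimulus)
}

#' Simulate a complete Amsler test
#'
#' Runs the plan against the patient's detection field inside a seed context
#' derived from the patient and plan seeds, so `(patient seed, plan seed)`
#' fully determine the result.
#'
#' @param plan a [build_test_plan()] plan
#' @param patient a [make_patient()] patient
#' @param patient_id,eye,timestamp metadata stored on the result
#' @return a `test_result`
#' @export
simulate_test <- function(plan, patient, patient_id = "sim", eye = "OU",
                          timestamp = 0) {
  withr::with_seed(
    combine_seeds(patient$seed, plan$seed),
    run_test(plan, amsler_responder(patient), patient_id, eye, timestamp)
  )
}

# Ability relevant to a skill set: requirement-weighted mean of the patient's
# true per-skill abilities (a scalar ability applies to every skill).
patient_ability <- function(patient, skills = NULL) {
  a <- patient$true_ability
  if (is.null(names(a)) || is.null(skills) || length(skills) == 0) {
    return(mean(a))
  }
  lv <- skills[names(skills) %in% names(a)]
  if (length(lv) == 0) return(mean(a))
  sum(lv * a[names(lv)]) / sum(lv)
}

#' Respond to a single exercise target
#'
#' Hit probability is `plogis(slope * (ability - difficulty))` where ability
#' is the patient's (requirement-weighted) true ability, so a patient whose
#' ability equals the exercise difficulty hits half the time. Draws from the
#' current RNG stream.
#'
#' @param patient a [make_patient()] patient
#' @param difficulty scalar exercise difficulty in \[0, 1\]
#' @param skills optional named skill requirements used to weight ability
#' @return list with `tap` (logical), `rt_s` and the hit probability `p`
#' @export
respond_exercise <- function(patient, difficulty, skills = NULL) {
  a <- patient_ability(patient, skills)
  p <- stats::plogis(patient$logistic_slope * (a - difficulty))
  tap <- stats::runif(1) < p
  list(tap = tap, rt_s = if (tap) draw_rt(patient) else NA_real_, p = p)
}

# One recommender-loop session: every presented stimulus is a detection
# opportunity drawn from the patient's psychometric function.
simulate_exercise_session <- function(patient, spec, difficulty,
                                      timestamp = 0) {
  n <- spec$params$n_stimuli
  hits <- 0L
  rts <- numeric(0)
  for (i in seq_len(n)) {
    r <- respond_exercise(patient, difficulty, spec$skills)
    if (isTRUE(r$tap)) {
      hits <- hits + 1L
      rts <- c(rts, r$rt_s)
    }
  }
  exercise_result(spec$id, hits, n - hits, n + hits, rts,
                  timestamp = timestamp)
}
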