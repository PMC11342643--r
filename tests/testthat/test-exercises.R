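test_that("catalogue sizes and revision changes match the final design", {
  ini <- catalogue("initial")
  expect_length(ini, 15)
  expect_identical(vapply(ini, function(s) s$id, integer(1)), 1:15)
  expect_true(all(vapply(ini, function(s) s$params$inter_stimulus_s, numeric(1))[2:5] == 10))

  rev <- catalogue("revised")
  ids <- vapply(rev, function(s) s$id, integer(1))
  is_ex <- vapply(rev, function(s) s$is_exercise, logical(1))
  expect_length(rev, 12)
  expect_equal(sum(is_ex), 11)         # 11 exercises + 1 demonstration
  expect_false(rev[[which(ids == 1)]]$is_exercise)
  expect_false(any(c(12, 14, 15) %in% ids)) # 11+12 merged, 14-15 dropped

  # 2-5 and 10: touch anywhere, interval reduced from 10 s to 5 s
  for (i in c(2:5, 10)) {
    s <- rev[[which(ids == i)]]
    expect_identical(s$params$response_mode, "touch_anywhere")
    expect_equal(s$params$inter_stimulus_s, 5)
  }
  # 6-9: sequential alternating fixation, voice guided
  for (i in 6:9) {
    s <- rev[[which(ids == i)]]
    expect_identical(s$params$fixation_mode, "alternating")
    expect_true(s$params$sequential_fixation)
    expect_true(s$params$voice_guided)
  }
  # 10: target at least twice, size reduced below the initial 2 cm
  s10 <- rev[[which(ids == 10)]]
  expect_gte(s10$params$min_target_repeats, 2)
  expect_lt(s10$params$stimulus_size_cm, 2)
  # 13: compulsory voice guidance that cannot be disabled
  s13 <- rev[[which(ids == 13)]]
  expect_true(s13$params$forced_voice)
  expect_true(s13$params$voice_guided)
  expect_error(catalogue("v3"))
})

test_that("difficulty index orders figure families and tracks parameters", {
  rev <- catalogue("revised")
  ids <- vapply(rev, function(s) s$id, integer(1))
  d <- vapply(rev, difficulty_index, numeric(1))
  # solid < hollow < bold letters < plain letters, single then alternating
  expect_true(all(diff(d[match(2:5, ids)]) > 0))
  expect_true(all(diff(d[match(6:9, ids)]) > 0))
  expect_true(all(d[match(6:9, ids)] > d[match(2:5, ids)]))
  expect_true(all(d >= 0 & d <= 1))
  # strictly decreasing in stimulus size and in inter-stimulus interval
  s <- rev[[which(ids == 3)]]
  bigger <- s; bigger$params$stimulus_size_cm <- s$params$stimulus_size_cm * 2
  slower <- s; slower$params$inter_stimulus_s <- s$params$inter_stimulus_s + 3
  expect_lt(difficulty_index(bigger), difficulty_index(s))
  expect_lt(difficulty_index(slower), difficulty_index(s))
})

test_that("streams are seeded, target-bearing and projected on the treatment area", {
  area <- treatment_area(2, 1)
  s10 <- catalogue_spec(10)
  for (seed in 1:10) {
    st <- build_stimulus_stream(s10, area, seed)
    expect_gte(sum(st$events$image == s10$target$image), 2)
  }
  a <- build_stimulus_stream(s10, area, seed = 6)
  b <- build_stimulus_stream(s10, area, seed = 6)
  expect_identical(jsonlite::toJSON(a$events, digits = NA),
                   jsonlite::toJSON(b$events, digits = NA))
  # no immediate filler repetition
  ev <- a$events
  rep_pos <- which(ev$image[-1] == ev$image[-nrow(ev)]) + 1
  expect_true(all(ev$is_target[rep_pos]))
  # every event offset from its fixation point by exactly the treatment area
  expect_equal(ev$x_cm - ev$fixation_x, rep(2, nrow(ev)))
  expect_equal(ev$y_cm - ev$fixation_y, rep(1, nrow(ev)))
  # an area that projects off-grid is refused
  expect_error(build_stimulus_stream(s10, treatment_area(6, 0), 1),
               class = "eyerehab_placement_error")
})

test_that("sequential alternating fixation switches only after a missed target", {
  area <- treatment_area(2, 1)
  spec <- catalogue_spec(6)
  # deterministic responder: miss target events 1 and 3, hit the rest
  seen <- 0
  responder <- function(event, difficulty, skills) {
    if (!isTRUE(event$is_target)) return(list(tap = FALSE))
    seen <<- seen + 1
    list(tap = !(seen %in% c(1, 3)), rt_s = 1)
  }
  run <- run_exercise(spec, area, responder, seed = 7) # stream with >= 3 targets
  ev <- run$stream$events
  tpos <- which(ev$is_target)
  expect_gte(length(tpos), 3)
  # reconstruct expected fixation sequence: switch after each missed target
  active <- 1L; misses <- 0; expected <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    expected[i] <- active
    if (ev$is_target[i]) {
      misses <- misses + 1
      if (misses %in% c(1, 3)) active <- 3L - active
    }
  }
  expect_identical(ev$fixation_id, expected)
  # fixation never changes off a target event
  ch <- which(diff(ev$fixation_id) != 0)
  expect_true(all(ev$is_target[ch]))
})

test_that("session scoring matches a brute-force interval enumeration", {
  area <- treatment_area(2, 1)
  spec <- catalogue_spec(2) # touch-anywhere, 5 s windows
  st <- build_stimulus_stream(spec, area, seed = 3)
  ev <- st$events
  taps <- data.frame(time_s = c(1.0, 7.2, 12.5, 21.0, 33.3, 48.0))
  res <- score_session(st, taps)

  # independent oracle: enumerate tap/window overlaps
  hit_ev <- rep(FALSE, nrow(ev)); fa <- 0
  for (t in taps$time_s) {
    i <- which(t >= ev$onset_s & t < ev$onset_s + ev$duration_s)
    if (length(i) == 1 && ev$is_target[i] && !hit_ev[i]) hit_ev[i] <- TRUE
    else if (!(length(i) == 1 && ev$is_target[i])) fa <- fa + 1
  }
  expect_equal(res$hits, sum(hit_ev))
  expect_equal(res$misses, sum(ev$is_target) - sum(hit_ev) + fa)
  expect_equal(res$attempts, nrow(taps) + sum(ev$is_target))
})

test_that("perfect and absent responders score at the boundaries", {
  area <- treatment_area(2, 1)
  st <- build_stimulus_stream(catalogue_spec(2), area, seed = 4)
  n_t <- sum(st$events$is_target)
  perfect <- data.frame(time_s = st$events$onset_s[st$events$is_target] + 1)
  res <- score_session(st, perfect)
  expect_equal(res$hits, n_t)
  expect_equal(res$misses, 0)
  res0 <- score_session(st, NULL)
  expect_equal(res0$hits, 0)
  expect_equal(res0$misses, n_t)
  expect_equal(res0$attempts, n_t)
  expect_error(score_session(st, data.frame(time_s = 1e6)),
               class = "eyerehab_domain_error")
})

test_that("timing entries are sanitized with default fallback", {
  expect_equal(sanitize_timing(NULL, 5), 5)
  expect_equal(sanitize_timing("", 5), 5)
  expect_equal(sanitize_timing(7, 5), 7)
  expect_equal(sanitize_timing("7.5", 5), 7.5)
  expect_warning(v <- sanitize_timing(-2, 5), class = "eyerehab_timing_corrected")
  expect_equal(v, 5)
  expect_warning(v2 <- sanitize_timing("fast", 5), class = "eyerehab_timing_corrected")
  expect_equal(v2, 5)
})

test_that("only practitioners may edit the four adjustable parameters", {
  spec <- catalogue_spec(2)
  expect_setequal(adjustable_params(),
                  c("inter_stimulus_s", "n_stimuli", "stimulus_size_cm", "duration_s"))
  upd <- set_exercise_params(spec, list(inter_stimulus_s = 8), "practitioner")
  expect_equal(upd$params$inter_stimulus_s, 8)
  expect_error(set_exercise_params(spec, list(inter_stimulus_s = 8), "patient"),
               class = "eyerehab_permission_error")
  expect_error(set_exercise_params(spec, list(response_mode = "touch_target"),
                                   "practitioner"),
               class = "eyerehab_permission_error")
  # compulsory voice guidance survives parameter edits
  s13 <- set_exercise_params(catalogue_spec(13), list(n_stimuli = 6L), "practitioner")
  expect_true(s13$params$voice_guided)
})
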