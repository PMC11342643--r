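test_that("ability update is the closed-form exponential moving average", {
  spec <- catalogue_spec(2)
  m <- ability_model(prior = 0.4, alpha = 0.5)
  res <- exercise_result(2L, hits = 8, misses = 2, attempts = 18)
  m2 <- update_ability(m, res, spec)
  # (1 - 0.5) * 0.4 + 0.5 * 0.8 = 0.6 for every touched skill
  for (sk in names(spec$skills)) expect_equal(unname(m2$ability[sk]), 0.6)
  # untouched skills unchanged
  expect_equal(unname(m2$ability["face_recognition"]), 0.4)
  # result/spec mismatch rejected
  expect_error(update_ability(m, exercise_result(3L, 1, 1, 2), spec),
               class = "eyerehab_domain_error")
})

test_that("ability moves up on success, down on failure, and stays bounded", {
  spec <- catalogue_spec(4)
  m <- ability_model(prior = 0.5)
  up <- update_ability(m, exercise_result(4L, 10, 0, 20), spec)
  dn <- update_ability(m, exercise_result(4L, 0, 10, 10), spec)
  for (sk in names(spec$skills)) {
    expect_gt(unname(up$ability[sk]), 0.5)
    expect_lt(unname(dn$ability[sk]), 0.5)
  }
  # property: arbitrary result sequences keep scores in [0, 1]
  withr::with_seed(21, {
    mm <- ability_model(prior = 0.9)
    for (i in 1:100) {
      sp <- catalogue_spec(sample(c(2:11, 13), 1))
      h <- sample(0:10, 1)
      mm <- update_ability(mm, exercise_result(sp$id, h, 10 - h, 10 + h), sp)
      expect_true(all(mm$ability >= 0 & mm$ability <= 1))
    }
  })
})

test_that("reaction-time tendency is a running mean with slow/fast flags", {
  spec <- catalogue_spec(2)
  m <- ability_model()
  m <- update_ability(m, exercise_result(2L, 2, 0, 4, reaction_times = c(1, 2)), spec)
  m <- update_ability(m, exercise_result(2L, 1, 1, 3, reaction_times = 4), spec)
  expect_equal(unname(m$rt_mean["shape_recognition"]), mean(c(1, 2, 4)))
  tend <- rt_tendency(m)
  expect_identical(unname(tend["shape_recognition"]), "slow")
  expect_identical(unname(tend["face_recognition"]), "unknown")
})

test_that("difficulty self-adjusts down on failure, up on high success, holds ties", {
  spec <- catalogue_spec(3)
  d0 <- difficulty_index(spec)
  easier <- adjust_difficulty(spec, exercise_result(3L, 2, 8, 12))
  expect_lt(difficulty_index(easier), d0)
  expect_identical(attr(easier, "adjustment"), "easier")
  harder <- adjust_difficulty(spec, exercise_result(3L, 10, 0, 20))
  expect_gt(difficulty_index(harder), d0)
  expect_identical(attr(harder, "adjustment"), "harder")
  tie <- adjust_difficulty(spec, exercise_result(3L, 5, 5, 15))
  expect_equal(difficulty_index(tie), d0)
  expect_identical(attr(tie, "adjustment"), "hold")
  # 0.7 success sits inside the target band: hold as well
  mid <- adjust_difficulty(spec, exercise_result(3L, 7, 3, 17))
  expect_equal(difficulty_index(mid), d0)
})

test_that("recommendation targets slightly above ability with stable tie-breaks", {
  specs <- catalogue("revised")
  ids <- vapply(specs, function(s) s$id, integer(1))
  d <- vapply(specs, difficulty_index, numeric(1))
  # ceiling ability: the hardest enabled exercise is chosen
  top <- recommend_next(ability_model(prior = 1), specs)
  expect_equal(top$difficulty, max(d[vapply(specs, function(s) s$is_exercise, logical(1))]))
  # low ability: an easy exercise, just above ability + margin
  low <- recommend_next(ability_model(prior = 0.2), specs)
  expect_lt(low$difficulty, stats::median(d))
  expect_gte(low$difficulty, 0.2) # not trivially the easiest
  # demonstration entries are never recommended
  expect_true(low$spec$is_exercise)
  # ties break toward the lower exercise id
  twin <- function(id) exercise_spec(id, "revised", "figure_single_fixation",
                                     list(image = "circle_solid",
                                          pool = c("circle_solid", "square_solid")),
                                     "twin", c(shape_recognition = 0.3), 2L)
  rec <- recommend_next(ability_model(prior = 0.5), list(twin(9L), twin(4L)))
  expect_equal(rec$spec$id, 4L)
  # an empty enabled set is a precondition error
  expect_error(recommend_next(ability_model(), list()),
               class = "eyerehab_precondition_error")
  expect_error(recommend_next(ability_model(), list(catalogue("revised")[[1]])),
               class = "eyerehab_precondition_error")
})

test_that("a failure session never escalates the next recommendation", {
  # random-ability patients across several seeds; exhaustive scan of histories
  for (s in 1:8) {
    pat <- make_patient(list(true_ability = 0.3 + 0.1 * (s %% 4)), seed = s)
    loop <- run_selection_loop(ability_model(), catalogue("revised"), pat,
                               n_sessions = 25, seed = 50 + s)
    h <- loop$history[loop$history$completed, ]
    bad <- which(h$misses > h$hits)
    bad <- bad[bad < nrow(h)]
    if (length(bad)) {
      expect_true(all(h$difficulty[bad + 1] <= h$difficulty[bad] + 1e-9))
    }
  }
})

test_that("the selection loop records a full, seed-reproducible trace", {
  pat <- make_patient(seed = 2)
  one <- run_selection_loop(ability_model(), catalogue("revised"), pat, 1, seed = 9)
  expect_equal(nrow(one$history), 1)
  expect_true(all(c("spec_id", "difficulty", "rationale", "hits", "misses",
                    "success", "ability") %in% names(one$history)))
  expect_s3_class(one$model, "ability_model")
  a <- run_selection_loop(ability_model(), catalogue("revised"), pat, 12, seed = 9)
  b <- run_selection_loop(ability_model(), catalogue("revised"), pat, 12, seed = 9)
  expect_identical(jsonlite::toJSON(a$history, digits = NA),
                   jsonlite::toJSON(b$history, digits = NA))
  expect_error(run_selection_loop(ability_model(), catalogue("revised"), pat, 0),
               class = "eyerehab_precondition_error")
})

test_that("a failing responder truncates the history with an error record", {
  k <- 0
  responder <- function(spec, difficulty) {
    k <<- k + 1
    if (k == 3) stop("tablet battery died")
    exercise_result(spec$id, 5, 5, 15)
  }
  loop <- run_selection_loop(ability_model(), catalogue("revised"), responder,
                             10, seed = 1)
  expect_equal(nrow(loop$history), 3)
  expect_false(loop$history$completed[3])
  expect_match(loop$history$error[3], "battery")
})

test_that("compliance alerts exactly when completions fall short", {
  expect_false(check_compliance(5, 5)$alert)
  expect_true(check_compliance(3, 5)$alert)
  expect_false(check_compliance(0, 0)$alert)
  # a fully non-compliant simulated patient skips every session and alerts
  pat <- make_patient(list(compliance_prob = 0), seed = 1)
  loop <- run_selection_loop(ability_model(), catalogue("revised"), pat, 5, seed = 3)
  expect_equal(sum(loop$history$completed), 0)
  expect_true(check_compliance(loop$history, 5)$alert)
})
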