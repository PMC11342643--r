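test_that("a full test plan presents 50 stimuli at distinct in-grid cells", {
  plan <- build_test_plan(default_grid, "full", seed = 1)
  st <- plan$stimuli
  expect_equal(nrow(st), 50)
  expect_equal(nrow(unique(st[, c("row", "col")])), 50)
  expect_true(all(st$row >= 0 & st$row < 20 & st$col >= 0 & st$col < 20))
  expect_true(all(abs(st$x_cm) <= 5 & abs(st$y_cm) <= 5))
  # stratified layout: exactly two stimuli per 4x4-cell block
  block <- (st$row %/% 4) * 5 + (st$col %/% 4)
  expect_true(all(table(block) == 2))
})

test_that("plans are deterministic in the seed and differ across seeds", {
  a <- build_test_plan(seed = 7)
  b <- build_test_plan(seed = 7)
  expect_identical(
    jsonlite::toJSON(a$stimuli, digits = NA),
    jsonlite::toJSON(b$stimuli, digits = NA)
  )
  c <- build_test_plan(seed = 8)
  expect_false(identical(a$stimuli$row, c$stimuli$row) &&
                 identical(a$stimuli$col, c$stimuli$col))
})

test_that("follow-up halves the count and stays in the scotoma environment", {
  prior <- scotoma_from_cells(default_grid, block_cells())
  plan <- build_test_plan(default_grid, "followup", seed = 1, prior_scotoma = prior)
  st <- plan$stimuli
  expect_equal(nrow(st), 25)
  # every stimulus within Chebyshev distance 2 of the 3x3 block
  cheb <- mapply(function(r, c) {
    min(pmax(abs(r - block_cells()$row), abs(c - block_cells()$col)))
  }, st$row, st$col)
  expect_true(all(cheb <= 2))
  # region cells are also recorded on the plan
  expect_true(all(cellkeys(st) %in% cellkeys(plan$restriction_region)))
  # follow-up without a prior scotoma is refused
  expect_error(build_test_plan(mode = "followup", seed = 1),
               class = "eyerehab_precondition_error")
  empty <- scotoma_from_cells(default_grid, block_cells()[0, ])
  expect_error(build_test_plan(mode = "followup", seed = 1, prior_scotoma = empty),
               class = "eyerehab_precondition_error")
})

test_that("scheduled duration is display plus response window per stimulus", {
  expect_equal(test_duration(build_test_plan(seed = 1)), 300) # 5 minutes
  prior <- scotoma_from_cells(default_grid, block_cells())
  fu <- build_test_plan(mode = "followup", seed = 1, prior_scotoma = prior)
  expect_equal(test_duration(fu), 150)                        # within 2-3 minutes
  expect_equal(test_duration(build_test_plan(seed = 1, n_stimuli = 0L)), 0)
})

test_that("run_test records one outcome per stimulus and applies the window rule", {
  plan <- build_test_plan(seed = 3)
  all_seen <- run_test(plan, function(ev) list(seen = TRUE, rt_s = 1))
  expect_equal(sum(all_seen$outcomes$seen), 50)
  none <- run_test(plan, function(ev) list(seen = FALSE))
  expect_equal(sum(none$outcomes$seen), 0)
  # a response later than display + window counts as missed
  late <- run_test(plan, function(ev) list(seen = TRUE, rt_s = 6.5))
  expect_equal(sum(late$outcomes$seen), 0)
  expect_true(all(is.na(late$outcomes$rt_s)))
})

test_that("a deterministic scotoma patient misses exactly the block stimuli", {
  plan <- build_test_plan(seed = 5)
  res <- simulate_test(plan, det_patient())
  inside <- cellkeys(plan$stimuli) %in% cellkeys(block_cells())
  expect_identical(!res$outcomes$seen, inside)
  expect_true(all(res$outcomes$rt_s[res$outcomes$seen] <= 6))
})

test_that("a failing responder aborts the test but preserves partial outcomes", {
  plan <- build_test_plan(seed = 2)
  n <- 0
  flaky <- function(ev) {
    n <<- n + 1
    if (n > 10) stop("touchscreen lost")
    list(seen = TRUE, rt_s = 1)
  }
  cond <- tryCatch(run_test(plan, flaky), eyerehab_aborted_test = identity)
  expect_s3_class(cond, "eyerehab_aborted_test")
  expect_equal(nrow(cond$partial), 10)
  expect_true(all(cond$partial$seen))
})

test_that("scotoma estimation recovers the exact block under full coverage", {
  res <- simulate_test(full_coverage_plan(seed = 1), det_patient())
  map <- estimate_scotoma(res)
  expect_setequal(cellkeys(missed_cells(map)), cellkeys(block_cells()))
  expect_equal(sum(map$status == "untested"), 0)
})

test_that("estimation pools by recency and flags untested cells", {
  plan <- full_coverage_plan(seed = 1)
  seen_all <- run_test(plan, function(ev) list(seen = TRUE, rt_s = 1),
                       timestamp = 1)
  expect_equal(nrow(missed_cells(estimate_scotoma(seen_all))), 0)
  # an earlier test missed the block; the later all-seen test overrides it
  old <- simulate_test(plan, det_patient(), timestamp = 0)
  map <- estimate_scotoma(list(seen_all, old)) # order in list must not matter
  expect_equal(nrow(missed_cells(map)), 0)
  # and the reverse order of timestamps keeps the misses
  old2 <- simulate_test(plan, det_patient(), timestamp = 2)
  map2 <- estimate_scotoma(list(seen_all, old2))
  expect_setequal(cellkeys(missed_cells(map2)), cellkeys(block_cells()))
  # a partial test leaves the rest untested
  small <- run_test(build_test_plan(seed = 9), function(ev) list(seen = TRUE, rt_s = 1))
  expect_equal(sum(estimate_scotoma(small)$status == "untested"), 350)
})

test_that("results on different grids cannot be pooled", {
  r1 <- run_test(build_test_plan(seed = 1), function(ev) list(seen = TRUE, rt_s = 1))
  g2 <- grid_spec(width_cm = 8, height_cm = 8)
  r2 <- run_test(build_test_plan(g2, seed = 1, n_stimuli = 10L),
                 function(ev) list(seen = TRUE, rt_s = 1))
  expect_error(estimate_scotoma(list(r1, r2)), class = "eyerehab_domain_error")
})
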