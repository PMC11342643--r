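#' Build a seeded Amsler-grid test plan
#'
#' A full self-assessment presents 50 red-dot stimuli at 50 distinct grid
#' cells (default 3 s display + 3 s response window each, 5 minutes total).
#' A follow-up test halves the stimulus count (rounding up) and restricts the
#' sampled cells to the environment of a previously estimated scotoma,
#' shortening the test to 2-3 minutes.
#'
#' Full-test layout is stratified: when the grid divides into 4 x 4 cell
#' blocks and the stimulus count equals two per block (the 20 x 20 / 50 case),
#' exactly two distinct cells are drawn per block, giving reproducible
#' whole-field coverage; otherwise cells are drawn by simple random sampling
#' without replacement. Presentation order is shuffled. Identical arguments
#' and seed yield an identical plan.
#'
#' @param grid a [grid_spec()]
#' @param mode `"full"` or `"followup"`
#' @param seed integer seed controlling cell choice and order
#' @param prior_scotoma a [estimate_scotoma()] map; required in follow-up mode
#'   (it must contain at least one missed cell)
#' @param n_stimuli stimulus count of a full test (follow-up uses
#'   `ceiling(n_stimuli / 2)`)
#' @param display_s stimulus display duration (seconds)
#' @param response_window_s response window after display (seconds)
#' @param neighborhood_cells Chebyshev radius, in cells, of the "environment
#'   of the scotoma" sampled by a follow-up test
#' @return an object of class `test_plan`
#' @export
build_test_plan <- function(grid = grid_spec(), mode = c("full", "followup"),
                            seed = 1L, prior_scotoma = NULL, n_stimuli = 50L,
                            display_s = 3, response_window_s = 3,
                            neighborhood_cells = 2L) {
  mode <- match.arg(mode)
  if (display_s <= 0 || response_window_s < 0) {
    stop_rehab("display_s must be positive and response_window_s non-negative",
               "eyerehab_domain_error")
  }
  cells <- cell_centers(grid)
  region <- NULL

  if (mode == "full") {
    n <- as.integer(n_stimuli)
    if (n > nrow(cells)) {
      stop_rehab("more stimuli requested than grid cells", "eyerehab_domain_error")
    }
    chosen <- withr::with_seed(seed, sample_cells_full(grid, cells, n))
  } else {
    if (is.null(prior_scotoma) || !inherits(prior_scotoma, "scotoma_map")) {
      stop_rehab("follow-up test requires a prior scotoma map",
                 "eyerehab_precondition_error")
    }
    miss <- missed_cells(prior_scotoma)
    if (nrow(miss) == 0) {
      stop_rehab("follow-up test requires a prior scotoma map with at least one missed cell",
                 "eyerehab_precondition_error")
    }
    n <- as.integer(ceiling(n_stimuli / 2))
    region <- scotoma_environment(grid, miss, neighborhood_cells)
    pool <- merge(cells, region, by = c("row", "col"))
    chosen <- withr::with_seed(seed, {
      if (nrow(pool) >= n) {
        pool[sample.int(nrow(pool), n), , drop = FALSE]
      } else {
        # region smaller than the follow-up count: revisit region cells
        extra <- pool[sample.int(nrow(pool), n - nrow(pool), replace = TRUE), , drop = FALSE]
        rbind(pool, extra)[sample.int(n), , drop = FALSE]
      }
    })
  }

  stimuli <- data.frame(
    index = seq_len(nrow(chosen)),
    row = chosen$row, col = chosen$col,
    x_cm = chosen$x_cm, y_cm = chosen$y_cm,
    display_s = rep(display_s, nrow(chosen)),
    response_window_s = rep(response_window_s, nrow(chosen)),
    row.names = NULL
  )
  structure(
    list(grid = grid, mode = mode, seed = as.integer(seed), stimuli = stimuli,
         restriction_region = region),
    class = "test_plan"
  )
}

# Stratified (two cells per 4x4 block) when the geometry allows it, else SRS.
sample_cells_full <- function(grid, cells, n) {
  if (n == 0L) return(cells[0, , drop = FALSE])
  br <- grid$n_rows %/% 4L
  bc <- grid$n_cols %/% 4L
  stratified <- grid$n_rows %% 4L == 0L && grid$n_cols %% 4L == 0L &&
    n == 2L * br * bc
  if (stratified) {
    block <- (cells$row %/% 4L) * bc + (cells$col %/% 4L)
    idx <- unlist(lapply(split(seq_len(nrow(cells)), block), function(i) {
      i[sample.int(length(i), 2L)]
    }), use.names = FALSE)
  } else {
    idx <- sample.int(nrow(cells), n)
  }
  cells[idx[sample.int(length(idx))], , drop = FALSE]
}

# All cells within Chebyshev distance k of any missed cell, clipped to the grid.
scotoma_environment <- function(grid, miss, k = 2L) {
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  env <- do.call(rbind, lapply(seq_len(nrow(miss)), function(i) {
    data.frame(row = miss$row[i] + offs$dr, col = miss$col[i] + offs$dc)
  }))
  env <- unique(env)
  env <- env[env$row >= 0 & env$row < grid$n_rows &
               env$col >= 0 & env$col < grid$n_cols, , drop = FALSE]
  rownames(env) <- NULL
  env
}

#' Scheduled duration of a test plan
#'
#' Sum of display time plus response window over all stimuli: 300 s (5 min)
#' for a default full test, 150 s for a default follow-up.
#'
#' @param plan a [build_test_plan()] plan
#' @return total seconds
#' @export
test_duration <- function(plan) {
  stopifnot(inherits(plan, "test_plan"))
  sum(plan$stimuli$display_s + plan$stimuli$response_window_s)
}

#' Run a test plan against a responder
#'
#' Presents each stimulus in plan order to `responder`, a function taking the
#' stimulus event (a list with `x_cm`, `y_cm`, `display_s`,
#' `response_window_s`, `index`) and returning `list(seen =, rt_s =)`.
#' A response whose reaction time exceeds the display-plus-window interval is
#' recorded as missed. If the responder fails mid-test, an
#' `eyerehab_aborted_test` error is raised carrying the partial outcomes in its
#' `partial` field.
#'
#' @param plan a [build_test_plan()] plan
#' @param responder callback, e.g. [amsler_responder()]
#' @param patient_id,eye,timestamp metadata stored on the result (`eye` one of
#'   `"OD"`, `"OS"`, `"OU"`); `timestamp` is any orderable scalar
#' @return an object of class `test_result`
#' @export
run_test <- function(plan, responder, patient_id = "sim", eye = "OU",
                     timestamp = 0) {
  stopifnot(inherits(plan, "test_plan"), is.function(responder))
  eye <- match.arg(eye, c("OD", "OS", "OU"))
  st <- plan$stimuli
  seen <- logical(nrow(st))
  rt <- rep(NA_real_, nrow(st))
  for (i in seq_len(nrow(st))) {
    ev <- as.list(st[i, ])
    resp <- tryCatch(responder(ev), error = identity)
    if (inherits(resp, "error")) {
      partial <- cbind(st[seq_len(i - 1L), , drop = FALSE],
                       seen = seen[seq_len(i - 1L)], rt_s = rt[seq_len(i - 1L)])
      cond <- structure(
        class = c("eyerehab_aborted_test", "eyerehab_error", "error", "condition"),
        list(message = sprintf("responder failed at stimulus %d: %s",
                               i, conditionMessage(resp)),
             call = sys.call(), partial = partial)
      )
      stop(cond)
    }
    s <- isTRUE(resp$seen)
    r <- resp$rt_s %||% NA_real_
    window <- ev$display_s + ev$response_window_s
    if (s && is.finite(r) && r > window) s <- FALSE
    seen[i] <- s
    rt[i] <- if (s) r else NA_real_
  }
  outcomes <- cbind(st, seen = seen, rt_s = rt)
  structure(
    list(grid = plan$grid, mode = plan$mode, seed = plan$seed,
         outcomes = outcomes, patient_id = patient_id, eye = eye,
         timestamp = timestamp),
    class = "test_result"
  )
}

#' Estimate a scotoma map from one or more test results
#'
#' Derives a per-cell detection status (`"seen"`, `"missed"`, `"untested"`)
#' from the pooled results. When a cell was stimulated more than once, the
#' most recent outcome wins (results are ordered by `timestamp`, ties by list
#' position), so repeated testing tracks progression of the visual loss.
#'
#' @param results a `test_result` or list of them; all must share the grid
#' @param grid optional grid override (defaults to the results' grid)
#' @return an object of class `scotoma_map` with a `status` character matrix
#' @export
estimate_scotoma <- function(results, grid = NULL) {
  if (inherits(results, "test_result")) results <- list(results)
  if (length(results) == 0) stop_rehab("no test results supplied", "eyerehab_domain_error")
  grid <- grid %||% results[[1]]$grid
  ok <- vapply(results, function(r) same_grid(r$grid, grid), logical(1))
  if (!all(ok)) stop_rehab("test results use different grid specifications",
                           "eyerehab_domain_error")
  ord <- order(vapply(results, function(r) as.numeric(r$timestamp), numeric(1)))
  status <- matrix("untested", nrow = grid$n_rows, ncol = grid$n_cols)
  for (r in results[ord]) {
    oc <- r$outcomes
    for (i in seq_len(nrow(oc))) {
      status[oc$row[i] + 1L, oc$col[i] + 1L] <- if (oc$seen[i]) "seen" else "missed"
    }
  }
  structure(
    list(grid = grid, status = status,
         source = vapply(results[ord], function(r) as.character(r$patient_id), character(1)),
         n_tests = length(results)),
    class = "scotoma_map"
  )
}

#' Build a scotoma map directly from a set of missed cells
#'
#' Convenience constructor used to seed follow-up tests from externally
#' recorded missed cells (all listed cells are `"missed"`, the rest
#' `"untested"`).
#'
#' @param grid a [grid_spec()]
#' @param cells data.frame with 0-based `row`, `col` columns
#' @return a `scotoma_map`
#' @export
scotoma_from_cells <- function(grid, cells) {
  status <- matrix("untested", nrow = grid$n_rows, ncol = grid$n_cols)
  status[cbind(cells$row + 1L, cells$col + 1L)] <- "missed"
  structure(list(grid = grid, status = status, source = character(), n_tests = 0L),
            class = "scotoma_map")
}

#' Missed cells of a scotoma map
#'
#' @param map a `scotoma_map`
#' @return data.frame of 0-based `row`, `col` indices of missed cells
#' @export
missed_cells <- function(map) {
  stopifnot(inherits(map, "scotoma_map"))
  w <- which(map$status == "missed", arr.ind = TRUE)
  data.frame(row = as.integer(w[, 1]) - 1L, col = as.integer(w[, 2]) - 1L)
}

#' Tested cells of a scotoma map
#'
#' @param map a `scotoma_map`
#' @return data.frame of 0-based `row`, `col` indices of cells with any outcome
#' @export
tested_cells <- function(map) {
  stopifnot(inherits(map, "scotoma_map"))
  w <- which(map$status != "untested", arr.ind = TRUE)
  data.frame(row = as.integer(w[, 1]) - 1L, col = as.integer(w[, 2]) - 1L)
}

#' @export
print.scotoma_map <- function(x, ...) {
  n_missed <- sum(x$status == "missed")
  n_tested <- sum(x$status != "untested")
  cat(sprintf("Scotoma map (%d x %d cells): %d missed / %d tested, %d tests pooled\n",
              nrow(x$status), ncol(x$status), n_missed, n_tested, x$n_tests))
  invisible(x)
}
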