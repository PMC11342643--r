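#' Build a progress and evolution report for a patient
#'
#' Derives, purely from the stored records, the material both the patient and
#' the practitioner review: per-exercise hit/miss time series, the evolution
#' of the scotoma (missed-cell count after each successive test, pooling all
#' tests up to that point) and a compliance summary against the prescribed
#' session count, if one is recorded on the profile.
#'
#' @param store a [record_store()]
#' @param patient_id an existing patient id
#' @return an object of class `progress_report`: list with `patient_id`,
#'   `scotoma_series` (data.frame: test index, timestamp, missed and tested
#'   cell counts), `exercise_series` (data.frame: one row per session with
#'   spec id, hits, misses, attempts, success) and `compliance`
#' @export
build_report <- function(store, patient_id) {
  acc <- load_profile(store, patient_id)

  tests <- read_test_results(store, patient_id)
  if (length(tests)) {
    scotoma_series <- do.call(rbind, lapply(seq_along(tests), function(k) {
      map <- estimate_scotoma(tests[seq_len(k)])
      data.frame(test = k,
                 timestamp = as.numeric(tests[[k]]$timestamp),
                 missed_cells = nrow(missed_cells(map)),
                 tested_cells = nrow(tested_cells(map)))
    }))
  } else {
    scotoma_series <- data.frame(test = integer(), timestamp = numeric(),
                                 missed_cells = integer(), tested_cells = integer())
  }

  ex <- read_exercise_records(store, patient_id)
  if (length(ex)) {
    exercise_series <- do.call(rbind, lapply(seq_along(ex), function(i) {
      p <- ex[[i]]$payload
      total <- p$hits + p$misses
      data.frame(session = i, spec_id = p$spec_id,
                 timestamp = as.numeric(p$timestamp),
                 hits = p$hits, misses = p$misses, attempts = p$attempts,
                 success = if (total > 0) p$hits / total else NA_real_)
    }))
  } else {
    exercise_series <- data.frame(session = integer(), spec_id = integer(),
                                  timestamp = numeric(), hits = integer(),
                                  misses = integer(), attempts = integer(),
                                  success = numeric())
  }

  prescribed <- acc$profile$prescribed_sessions %||% 0L
  compliance <- check_compliance(nrow(exercise_series), prescribed)

  structure(
    list(patient_id = patient_id, scotoma_series = scotoma_series,
         exercise_series = exercise_series, compliance = compliance),
    class = "progress_report"
  )
}

#' @export
print.progress_report <- function(x, ...) {
  cat(sprintf("Progress report for %s: %d tests, %d exercise sessions\n",
              x$patient_id, nrow(x$scotoma_series), nrow(x$exercise_series)))
  if (nrow(x$scotoma_series)) {
    cat("  missed-cell evolution:",
        paste(x$scotoma_series$missed_cells, collapse = " -> "), "\n")
  }
  if (x$compliance$alert) {
    cat(sprintf("  COMPLIANCE ALERT: %d of %d prescribed sessions completed\n",
                x$compliance$completed, x$compliance$prescribed))
  }
  invisible(x)
}
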