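read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = FALSE)

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
}

require_practitioner <- function(actor_role, what) {
  if (!identical(actor_role, "practitioner")) {
    stop_rehab(sprintf("only the practitioner can %s", what),
               "eyerehab_permission_error")
  }
}

#' Open (or create) a JSON record store
#'
#' Local persistence used in place of server upload: JSON documents in a
#' directory tree, one sub-directory per patient
#' (`patients/<id>/profile.json`, `tests/*.json`, `exercises/results.jsonl`).
#' Records created offline carry `sync_pending = TRUE` until exported with
#' [export_records()].
#'
#' @param path store root directory (created if missing)
#' @return an object of class `record_store`
#' @export
record_store <- function(path) {
  dir.create(file.path(path, "patients"), recursive = TRUE, showWarnings = FALSE)
  pf <- file.path(path, "practitioners.json")
  if (!file.exists(pf)) write_json_file(stats::setNames(list(), character()), pf)
  cf <- file.path(path, "codes.json")
  if (!file.exists(cf)) write_json_file(stats::setNames(list(), character()), cf)
  structure(list(root = normalizePath(path)), class = "record_store")
}

practitioners_path <- function(store) file.path(store$root, "practitioners.json")
codes_path <- function(store) file.path(store$root, "codes.json")
patient_dir <- function(store, id) file.path(store$root, "patients", id)
profile_path <- function(store, id) file.path(patient_dir(store, id), "profile.json")

#' Register a practitioner account
#'
#' @param store a [record_store()]
#' @param id practitioner identifier
#' @return the practitioner record (invisibly)
#' @export
create_practitioner <- function(store, id) {
  pr <- read_json_file(practitioners_path(store))
  if (is.null(pr[[id]])) {
    pr[[id]] <- list(id = id, patients = list())
    write_json_file(pr, practitioners_path(store))
  }
  invisible(pr[[id]])
}

#' Create a patient account with a registration code
#'
#' The account is linked to exactly one practitioner and receives a unique
#' 6-digit numeric registration code (regenerated on collision) that the
#' practitioner sends to the patient to register. The profile must include a
#' [treatment_area()]; age, visual difficulties, the monocular/binocular
#' instruction and the enabled exercise set are optional.
#'
#' @param store a [record_store()]
#' @param practitioner_id an existing practitioner id
#' @param profile list with `treatment_area` (required) and optionally `id`,
#'   `age`, `difficulties`, `eye_mode`, `enabled_exercises`,
#'   `prescribed_sessions`
#' @return the patient account list (id, registration_code, practitioner_id,
#'   profile)
#' @export
create_patient <- function(store, practitioner_id, profile) {
  pr <- read_json_file(practitioners_path(store))
  if (is.null(pr[[practitioner_id]])) {
    stop_rehab(sprintf("unknown practitioner '%s'", practitioner_id),
               "eyerehab_not_found")
  }
  area <- profile$treatment_area
  if (is.null(area) || is.null(area$x_cm) || is.null(area$y_cm)) {
    stop_rehab("patient profile must include a treatment area",
               "eyerehab_validation_error")
  }
  codes <- read_json_file(codes_path(store))
  pid <- profile$id %||% sprintf("p%04d", length(codes) + 1L)
  if (!is.null(codes[[pid]])) {
    stop_rehab(sprintf("patient '%s' already exists", pid),
               "eyerehab_validation_error")
  }
  existing <- unlist(codes, use.names = FALSE)
  repeat {
    code <- sprintf("%06d", sample.int(1e6, 1) - 1L)
    if (!code %in% existing) break
  }
  account <- list(
    id = pid, registration_code = code, practitioner_id = practitioner_id,
    profile = list(
      age = profile$age, difficulties = profile$difficulties,
      eye_mode = profile$eye_mode %||% "binocular",
      enabled_exercises = profile$enabled_exercises,
      prescribed_sessions = profile$prescribed_sessions
    ),
    treatment_area = list(x_cm = area$x_cm, y_cm = area$y_cm,
                          extent_cm = area$extent_cm %||% 1,
                          entered_by = "practitioner"),
    area_audit = list(list(seq = 1L, actor = "practitioner",
                           x_cm = area$x_cm, y_cm = area$y_cm,
                           extent_cm = area$extent_cm %||% 1))
  )
  dir.create(file.path(patient_dir(store, pid), "tests"),
             recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(patient_dir(store, pid), "exercises"),
             recursive = TRUE, showWarnings = FALSE)
  write_json_file(account, profile_path(store, pid))
  codes[[pid]] <- code
  write_json_file(codes, codes_path(store))
  pr[[practitioner_id]]$patients <- c(pr[[practitioner_id]]$patients, pid)
  write_json_file(pr, practitioners_path(store))
  account
}

load_profile <- function(store, patient_id) {
  p <- profile_path(store, patient_id)
  if (!file.exists(p)) {
    stop_rehab(sprintf("unknown patient '%s'", patient_id), "eyerehab_not_found")
  }
  read_json_file(p)
}

#' Update a patient's treatment area (practitioner only)
#'
#' The coordinates of the trained retinal area may only be modified by the
#' practitioner as the disease or the rehabilitation evolves. Every change -
#' including a re-entry of the same value - is appended to an audit list so
#' the history of the area is preserved alongside the grid-test records.
#'
#' @param store a [record_store()]
#' @param patient_id patient id
#' @param area a [treatment_area()]
#' @param actor_role role attempting the change
#' @return the updated account (invisibly)
#' @export
set_treatment_area <- function(store, patient_id, area, actor_role) {
  require_practitioner(actor_role, "modify the treatment area")
  acc <- load_profile(store, patient_id)
  acc$treatment_area <- list(x_cm = area$x_cm, y_cm = area$y_cm,
                             extent_cm = area$extent_cm, entered_by = actor_role)
  acc$area_audit <- c(acc$area_audit, list(list(
    seq = length(acc$area_audit) + 1L, actor = actor_role,
    x_cm = area$x_cm, y_cm = area$y_cm, extent_cm = area$extent_cm
  )))
  write_json_file(acc, profile_path(store, patient_id))
  invisible(acc)
}

#' Set the exercises enabled for a patient (practitioner only)
#'
#' @param store a [record_store()]
#' @param patient_id patient id
#' @param exercise_ids integer vector of enabled exercise ids
#' @param actor_role role attempting the change
#' @return the updated account (invisibly)
#' @export
set_enabled_exercises <- function(store, patient_id, exercise_ids, actor_role) {
  require_practitioner(actor_role, "change the enabled exercise set")
  acc <- load_profile(store, patient_id)
  acc$profile$enabled_exercises <- as.list(as.integer(exercise_ids))
  write_json_file(acc, profile_path(store, patient_id))
  invisible(acc)
}

serialize_test_result <- function(result) {
  oc <- result$outcomes
  list(
    type = "test", patient_id = result$patient_id, eye = result$eye,
    timestamp = result$timestamp, seed = result$seed, mode = result$mode,
    grid = list(width_cm = result$grid$width_cm, height_cm = result$grid$height_cm,
                spacing_cm = result$grid$spacing_cm,
                working_distance_cm = result$grid$working_distance_cm),
    stimuli = lapply(seq_len(nrow(oc)), function(i) {
      list(x_cm = oc$x_cm[i], y_cm = oc$y_cm[i], row = oc$row[i], col = oc$col[i],
           display_s = oc$display_s[i], response_window_s = oc$response_window_s[i],
           seen = oc$seen[i], rt_s = if (is.na(oc$rt_s[i])) NULL else oc$rt_s[i])
    })
  )
}

deserialize_test_result <- function(payload) {
  g <- payload$grid
  grid <- grid_spec(g$width_cm, g$height_cm, g$spacing_cm, g$working_distance_cm)
  st <- payload$stimuli
  outcomes <- data.frame(
    index = seq_along(st),
    row = vapply(st, function(s) as.integer(s$row), integer(1)),
    col = vapply(st, function(s) as.integer(s$col), integer(1)),
    x_cm = vapply(st, function(s) as.numeric(s$x_cm), numeric(1)),
    y_cm = vapply(st, function(s) as.numeric(s$y_cm), numeric(1)),
    display_s = vapply(st, function(s) as.numeric(s$display_s), numeric(1)),
    response_window_s = vapply(st, function(s) as.numeric(s$response_window_s), numeric(1)),
    seen = vapply(st, function(s) isTRUE(s$seen), logical(1)),
    rt_s = vapply(st, function(s) as.numeric(s$rt_s %||% NA_real_), numeric(1))
  )
  structure(
    list(grid = grid, mode = payload$mode, seed = payload$seed,
         outcomes = outcomes, patient_id = payload$patient_id,
         eye = payload$eye, timestamp = payload$timestamp),
    class = "test_result"
  )
}

serialize_exercise_result <- function(result) {
  list(type = "exercise", spec_id = result$spec_id, hits = result$hits,
       misses = result$misses, attempts = result$attempts,
       reaction_times = as.list(result$reaction_times),
       eye_mode = result$eye_mode, timestamp = result$timestamp)
}

deserialize_exercise_result <- function(payload) {
  exercise_result(
    spec_id = payload$spec_id, hits = payload$hits, misses = payload$misses,
    attempts = payload$attempts,
    reaction_times = as.numeric(unlist(payload$reaction_times)),
    eye_mode = payload$eye_mode, timestamp = payload$timestamp
  )
}

#' Save a test or exercise result for a patient
#'
#' The record is written to the patient's sub-tree with
#' `sync_pending = TRUE`; [export_records()] clears the flag.
#'
#' @param store a [record_store()]
#' @param patient_id an existing patient id
#' @param result a `test_result` or `exercise_result`
#' @return the record id
#' @export
save_result <- function(store, patient_id, result) {
  load_profile(store, patient_id) # referential check
  if (inherits(result, "test_result")) {
    dirp <- file.path(patient_dir(store, patient_id), "tests")
    rid <- sprintf("test_%04d", length(list.files(dirp, pattern = "\\.json$")) + 1L)
    write_json_file(list(record_id = rid, sync_pending = TRUE,
                         payload = serialize_test_result(result)),
                    file.path(dirp, paste0(rid, ".json")))
  } else if (inherits(result, "exercise_result")) {
    f <- file.path(patient_dir(store, patient_id), "exercises", "results.jsonl")
    n <- if (file.exists(f)) length(readLines(f, warn = FALSE)) else 0L
    rid <- sprintf("ex_%04d", n + 1L)
    line <- jsonlite::toJSON(list(record_id = rid, sync_pending = TRUE,
                                  payload = serialize_exercise_result(result)),
                             auto_unbox = TRUE, digits = NA)
    cat(line, "\n", sep = "", file = f, append = TRUE)
  } else {
    stop_rehab("result must be a test_result or exercise_result",
               "eyerehab_domain_error")
  }
  rid
}

read_exercise_records <- function(store, patient_id) {
  f <- file.path(patient_dir(store, patient_id), "exercises", "results.jsonl")
  if (!file.exists(f)) return(list())
  lapply(readLines(f, warn = FALSE), function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
}

write_exercise_records <- function(store, patient_id, records) {
  f <- file.path(patient_dir(store, patient_id), "exercises", "results.jsonl")
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, f)
}

#' Load a patient's stored test results
#'
#' @param store a [record_store()]
#' @param patient_id patient id
#' @return list of `test_result` objects ordered by timestamp
#' @export
read_test_results <- function(store, patient_id) {
  load_profile(store, patient_id)
  dirp <- file.path(patient_dir(store, patient_id), "tests")
  files <- sort(list.files(dirp, pattern = "\\.json$", full.names = TRUE))
  res <- lapply(files, function(f) deserialize_test_result(read_json_file(f)$payload))
  res[order(vapply(res, function(r) as.numeric(r$timestamp), numeric(1)))]
}

#' List a patient's stored record ids and sync flags
#'
#' @param store a [record_store()]
#' @param patient_id patient id
#' @return data.frame with `record_id`, `type`, `sync_pending`
#' @export
list_records <- function(store, patient_id) {
  load_profile(store, patient_id)
  dirp <- file.path(patient_dir(store, patient_id), "tests")
  tests <- lapply(sort(list.files(dirp, pattern = "\\.json$", full.names = TRUE)),
                  read_json_file)
  ex <- read_exercise_records(store, patient_id)
  data.frame(
    record_id = c(vapply(tests, function(r) r$record_id, character(1)),
                  vapply(ex, function(r) r$record_id, character(1))),
    type = c(rep("test", length(tests)), rep("exercise", length(ex))),
    sync_pending = c(vapply(tests, function(r) isTRUE(r$sync_pending), logical(1)),
                     vapply(ex, function(r) isTRUE(r$sync_pending), logical(1))),
    stringsAsFactors = FALSE
  )
}

all_patient_ids <- function(store) {
  basename(list.dirs(file.path(store$root, "patients"), recursive = FALSE))
}

#' Delete a stored result (practitioner only)
#'
#' Only the practitioner can delete failed results; the patient role is always
#' refused.
#'
#' @param store a [record_store()]
#' @param patient_id patient id
#' @param result_id record id as returned by [save_result()]
#' @param actor_role role attempting the deletion
#' @return `TRUE` invisibly on success
#' @export
delete_result <- function(store, patient_id, result_id, actor_role) {
  require_practitioner(actor_role, "delete results")
  load_profile(store, patient_id)
  tf <- file.path(patient_dir(store, patient_id), "tests",
                  paste0(result_id, ".json"))
  if (file.exists(tf)) {
    unlink(tf)
    return(invisible(TRUE))
  }
  ex <- read_exercise_records(store, patient_id)
  keep <- vapply(ex, function(r) !identical(r$record_id, result_id), logical(1))
  if (any(!keep)) {
    write_exercise_records(store, patient_id, ex[keep])
    return(invisible(TRUE))
  }
  stop_rehab(sprintf("no stored result '%s' for patient '%s'",
                     result_id, patient_id), "eyerehab_not_found")
}

#' Export pending records and clear their sync flags
#'
#' Stands in for the periodic upload to the server: all records with
#' `sync_pending = TRUE` across every patient are serialized into a single
#' export document under `destination`, and only after the export file has
#' been written successfully are the source flags cleared - a failed export
#' leaves every flag untouched.
#'
#' @param store a [record_store()]
#' @param destination directory receiving the export document
#' @return manifest list with `n`, `records` (data.frame of patient/record
#'   ids) and the export `file` (`NA` when nothing was pending)
#' @export
export_records <- function(store, destination) {
  if (file.exists(destination) && !dir.exists(destination)) {
    stop_rehab("export destination is not a directory", "eyerehab_io_error")
  }
  if (!dir.exists(destination)) {
    ok <- dir.create(destination, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_rehab("cannot create export destination", "eyerehab_io_error")
  }
  pending <- list()
  for (pid in all_patient_ids(store)) {
    dirp <- file.path(patient_dir(store, pid), "tests")
    for (f in sort(list.files(dirp, pattern = "\\.json$", full.names = TRUE))) {
      rec <- read_json_file(f)
      if (isTRUE(rec$sync_pending)) {
        pending[[length(pending) + 1L]] <- list(patient_id = pid, file = f,
                                                record = rec)
      }
    }
    ex <- read_exercise_records(store, pid)
    for (i in seq_along(ex)) {
      if (isTRUE(ex[[i]]$sync_pending)) {
        pending[[length(pending) + 1L]] <- list(patient_id = pid, jsonl = i,
                                                record = ex[[i]])
      }
    }
  }
  if (length(pending) == 0) {
    return(list(n = 0L,
                records = data.frame(patient_id = character(),
                                     record_id = character()),
                file = NA_character_))
  }
  stamp <- length(list.files(destination, pattern = "^export_.*\\.json$")) + 1L
  out <- file.path(destination, sprintf("export_%04d.json", stamp))
  write_json_file(lapply(pending, function(p) {
    list(patient_id = p$patient_id, record = p$record)
  }), out)
  # export written: now clear flags atomically per source file
  for (pid in unique(vapply(pending, function(p) p$patient_id, character(1)))) {
    rows <- Filter(function(p) identical(p$patient_id, pid), pending)
    for (p in rows) {
      if (!is.null(p$file)) {
        rec <- p$record
        rec$sync_pending <- FALSE
        write_json_file(rec, p$file)
      }
    }
    idx <- unlist(lapply(rows, function(p) p$jsonl))
    if (length(idx)) {
      ex <- read_exercise_records(store, pid)
      for (i in idx) ex[[i]]$sync_pending <- FALSE
      write_exercise_records(store, pid, ex)
    }
  }
  list(
    n = length(pending),
    records = data.frame(
      patient_id = vapply(pending, function(p) p$patient_id, character(1)),
      record_id = vapply(pending, function(p) p$record$record_id, character(1)),
      stringsAsFactors = FALSE
    ),
    file = out
  )
}
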