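# Shared fixtures, all built in code.

default_grid <- grid_spec()

# 3x3 cell block centred on the grid (rows/cols 9:11), the simulator default.
block_cells <- function(rows = 9:11, cols = 9:11) {
  expand.grid(col = cols, row = rows)[, c("row", "col")]
}

cellkeys <- function(df) paste(df$row, df$col)

# Deterministic patient: never sees inside the scotoma, always sees outside.
det_patient <- function(seed = 1, scotoma = NULL) {
  cfg <- list(p_detect_inside = 0, p_detect_outside = 1)
  if (!is.null(scotoma)) cfg$scotoma <- scotoma
  make_patient(cfg, seed = seed)
}

# A plan visiting every grid cell once (400 stimuli on the default grid).
full_coverage_plan <- function(seed = 1) {
  build_test_plan(default_grid, "full", seed, n_stimuli = 400L)
}

new_store <- function() record_store(withr::local_tempdir(.local_envir = parent.frame()))

store_with_patient <- function(env = parent.frame()) {
  store <- record_store(withr::local_tempdir(.local_envir = env))
  create_practitioner(store, "dr_a")
  acc <- withr::with_seed(42, create_patient(store, "dr_a", list(
    id = "pat1", age = 67, treatment_area = treatment_area(2, 1),
    prescribed_sessions = 5
  )))
  list(store = store, account = acc)
}
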