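# eyerehab

Headless engine for tele-rehabilitation of patients with age-related macular
degeneration (AMD). AMD destroys central vision; rehabilitation trains a
functional peripheral retinal area — a preferred retinal locus (PRL) — to take
over fixation. This package implements the computational core such an
application needs, for the practitioners and engineers building or validating
one:

* **Amsler-grid self-assessment** — seeded 50-stimulus tests on the
  conceptual 10 × 10 cm grid viewed at 30 cm (each 5 mm square subtends
  `atan(0.5/30) = 0.955° ≈ 1°`), shortened follow-up tests confined to the
  environment of a known scotoma, and per-cell scotoma maps pooled by recency
  so progression can be monitored.
* **Eccentric-viewing exercises** — the initial 15-task catalogue and the
  revised 11 + demonstration catalogue produced by user testing, with seeded
  stimulus streams projected on the practitioner-entered treatment area
  relative to the active fixation point, and session scoring
  (hits / misses / attempts).
* **Closed-loop difficulty control** — a content-based recommender matching
  per-skill ability scores (EWMA of session success, learning rate α = 0.3)
  against exercise skill requirements, holding the prescribed difficulty
  slightly (δ = 0.1) above ability, with the self-adjustment rule that an
  exercise eases whenever misses exceed hits, and compliance alerting.
* **Role-gated records** — a JSON record store in which only the practitioner
  can edit the treatment area, the enabled exercise set, exercise parameters,
  or delete results; offline records carry a sync flag cleared by export.
* **A synthetic AMD patient** — Bernoulli detection field with a localized
  scotoma (defaults: central 3 × 3 cells, p = 0.05 inside / 0.98 outside) and
  a logistic psychometric function for exercises, so every property is
  testable against known ground truth.

See `vignettes/eyerehab-methods.Rmd` for the model details and design
rationale.

## Worked example

```r
library(eyerehab)

# A deterministic patient (sees nothing inside the scotoma, everything outside)
# tested at every cell: the map recovers the true 3x3 central lesion exactly.
pat  <- make_patient(list(p_detect_inside = 0, p_detect_outside = 1), seed = 1)
plan <- build_test_plan(seed = 1, n_stimuli = 400L)
map  <- estimate_scotoma(simulate_test(plan, pat))
map
#> Scotoma map (20 x 20 cells): 9 missed / 400 tested, 1 tests pooled
head(missed_cells(map), 3)
#>   row col
#> 1   9   9
#> 2  10   9
#> 3  11   9

# A follow-up test halves the stimulus count and stays near the lesion.
followup <- build_test_plan(mode = "followup", seed = 2, prior_scotoma = map)
test_duration(followup)   # 150 seconds (25 stimuli x 6 s) vs 300 s for a full test

# Thirty closed-loop training sessions with the default simulated patient.
loop <- run_selection_loop(ability_model(), catalogue("revised"),
                           make_patient(seed = 3), n_sessions = 30, seed = 7)
round(rolling_success(loop$history)[c(10, 20, 30)], 2)
#> [1] 0.75 0.75 0.68        # rolling success inside the [0.6, 0.8] target band
tail(loop$history[, c("session", "spec_id", "difficulty", "hits", "misses")], 1)
#>  session spec_id difficulty hits misses
#>       30       9      0.798    5      5
check_compliance(loop$history, 30)$alert
#> [1] FALSE
```

The rolling success rate is the mean over the last 10 completed sessions: the
controller raises difficulty while the patient over-performs and settles where
success sits in the configured [0.6, 0.8] band — challenged, not frustrated.

A command-line interface wraps the same functions
(`inst/cli/eyerehab plan-test --seed 1`, `simulate-test`, `estimate-scotoma`,
`list-exercises`, `simulate-exercise`, `recommend`, `simulate-program`,
`create-patient`, `set-area`, `export`, `report`; global `--seed`, `--config`,
`--out`).

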