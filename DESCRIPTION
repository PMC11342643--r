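Package: eyerehab
Title: Closed-Loop Engine for Amsler-Grid Scotoma Mapping and Eccentric-Viewing Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Headless computational core for tele-rehabilitation of patients with
    age-related macular degeneration (AMD). Implements visual-angle geometry for a
    10 x 10 cm conceptual Amsler grid viewed at 30 cm, seeded 50-stimulus
    self-assessment tests with shortened scotoma-environment follow-ups, per-cell
    scotoma map estimation, initial and revised eccentric-viewing exercise
    catalogues projected on a practitioner-defined treatment area, a content-based
    exercise recommender run as a closed-loop difficulty controller with
    self-adjusting parameters and compliance alerting, a role-gated JSON record
    store with offline sync flags, a synthetic AMD patient simulator for
    parameter-recovery and closed-loop testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
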