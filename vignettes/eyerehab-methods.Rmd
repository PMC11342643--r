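---
title: "Methods: scotoma mapping, eccentric-viewing training and closed-loop difficulty control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scotoma mapping, eccentric-viewing training and closed-loop difficulty control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyerehab)
```

## The problem

Age-related macular degeneration (AMD) destroys central vision while sparing
the peripheral retina. Visual rehabilitation trains patients to fixate with a
functional peripheral area — a preferred retinal locus (PRL) — instead of the
damaged fovea. `eyerehab` is the headless computational core of a
tele-rehabilitation application for this purpose: it maps scotomas from
Amsler-grid self-assessments, generates eccentric-viewing exercises projected
on the practitioner-chosen treatment area, adapts exercise difficulty in a
closed loop, and verifies the whole pipeline against a synthetic patient.
There is no GUI, audio, or networking in this package: those layers consume
the engine's JSON outputs.

## Grid geometry

The coordinate frame is the conceptual Amsler grid: 10 × 10 cm, lines every
5 mm, viewed at a working distance of 30 cm, with the fixation point at the
origin (x rightward, y upward). Offsets convert to visual angle per component
as $\theta = \arctan(\text{offset}/\text{distance})$, so one square subtends

```{r}
cm_to_deg(0.5, 30)
```

degrees — the conventional "one degree per square" (the 20-square grid is
likewise described as 20°, a per-square convention rather than an exact
arctangent claim, and the engine does not assert the latter numerically). We
use the plain arctangent per component rather than the central-angle form
$2\arctan(s/2d)$; the two differ by under 0.03 % at these eccentricities and
the component form is additive with the per-square convention. `deg_to_cm()`
is the exact inverse (round-trip error below $10^{-9}$).

The full-grid test requires a screen at least the size of the grid; exercises
do not, but stimulus positions are kept in absolute centimetres on small
screens so the retinal projection is preserved whenever the working distance
is held (`validate_screen()`).

## The self-assessment test

A full test presents 50 red-dot stimuli, each displayed 3 s with a 3 s
response window, giving the 5-minute schedule. Stimulus cells are drawn on
the 20 × 20 one-degree lattice by stratified sampling — two distinct cells in
every 4 × 4-cell block — so each test covers the whole field reproducibly;
geometries where that stratification does not divide evenly fall back to
simple random sampling. Presentation order is shuffled and everything is a
pure function of the seed.

A follow-up test halves the count (rounding up, so 25 by default, a 150 s
schedule) and restricts sampling to the *environment of the scotoma*,
operationalized as all cells within Chebyshev distance 2 of any previously
missed cell; the radius is a parameter. If that region holds fewer cells than
the follow-up count, region cells are revisited rather than leaving the
region.

Scoring is per cell: the most recent stimulus outcome at a cell wins
(recency), cells never stimulated are `untested`. Recency is what lets
repeated testing track progression — a previously missed cell seen in a later
test is counted as recovered, and vice versa. A tap later than display plus
response window is recorded as a miss.

## Exercise catalogues and the difficulty scale

The initial catalogue holds 15 tasks: a demonstration, four single-fixation
figure tasks of increasing recognition difficulty (solid figures, hollow
figures, bold letters, plain letters), the same four with alternating
fixation, real objects (drinks), two face tasks, a room-search task, and two
letter-line tasks. The revised catalogue applies the changes requested in
user testing: the demonstration is no longer counted as an exercise,
exercises 2–5 and 10 accept a touch anywhere on the screen and shorten the
default inter-stimulus interval from 10 s to 5 s, exercises 6–9 alternate
fixation sequentially (the switch is prompted after a missed target) with
voice guidance, exercise 10 must show its target at least twice at a reduced
size, the two face tasks merge into one with touch-anywhere dynamics, the
room search keeps a fixed fixation dot and compulsory voice guidance, and the
letter-line tasks are dropped — 11 exercises plus the demonstration.

Stimulus streams interleave the designated target with fillers from the same
image family (identifiers only; no bitmaps), without immediate filler
repetition, every event positioned at the treatment-area offset from the
active fixation point. Target placement is uniform given the
minimum-occurrence constraint, with a 0.3 per-event target rate before that
constraint is enforced.

Each spec maps to a scalar difficulty index in [0, 1]:

$$d = 0.5\,\frac{\text{rank}}{6} + \frac{0.3}{1 + \text{size}/2}
      + \frac{0.2}{1 + \text{interval}/5}$$

strictly increasing in the recognition rank and strictly decreasing in
stimulus size (cm) and inter-stimulus interval (s). The transforms are smooth
so self-adjustment steps always move the index; the weights spread the
revised catalogue over roughly [0.2, 0.77], leaving headroom for parameter
adjustment at both ends. Self-adjustment follows the frustration rule: when
misses exceed hits the exercise gets one step easier (size × 1.25, interval
+ 1 s); when the success rate exceeds the top of the target band it gets one
step harder (size × 0.8, interval × 0.9); ties and in-band results hold.
Size is capped to [0.2, 5] cm and the interval to [1, 15] s.

Only the practitioner may edit exercise parameters, and only the four
designed ones — inter-stimulus time, stimulus count, size, duration. The
timing field is error-corrected: an emptied or invalid entry falls back to
the recommended default (with a recorded warning for invalid values).

## The recommender as a closed-loop controller

Each exercise carries a named requirement vector over eight skills (fixation
stability and alternation, shape/letter/object/face recognition, scene
search, eccentric localization). The ability model keeps one score per skill
in [0, 1], updated after each session as an exponentially weighted moving
average of the session success rate with learning rate α = 0.3, plus a
running-mean reaction-time tendency. Age and recorded visual difficulties
lower the initial prior only (−0.005 per year over 60, −0.02 per recorded
difficulty); they have no per-session mechanics.

Selection is content-based: for each enabled exercise the
requirement-weighted mean ability is computed, a target difficulty of ability
+ δ (δ = 0.1) set, and the exercise whose index is closest to the target *from
above* chosen — keeping the challenge slightly above the current level; if
nothing lies above, the closest below (the hardest reachable) is taken, with
ties broken toward the lower id. A safety rule guarantees the frustration
property globally: after a session with more misses than hits, candidates
are restricted to difficulties at or below that session's.

The loop (recommend → execute → store → update → self-adjust) is a pure
function of the initial model, the enabled set, the responder and the seed.
With the default synthetic patient the rolling success rate (window of 10
completed sessions) settles in the [0.6, 0.8] target band; the band, δ, α
and the window are all configuration. Compliance is checked per evaluation
window: the practitioner alert fires exactly when completed sessions fall
short of the prescription (a zero prescription never alerts).

## The synthetic patient

The simulator exists so that recovery and control properties can be tested
with known ground truth. Its detection field is a localized scotoma —
default: the central 3 × 3-cell block, the typical central AMD lesion —
with detection probability 0.05 inside and 0.98 outside and an optional
linear ramp of configurable width across the border (default 0, a hard
edge). Exercise responses follow a logistic psychometric function
$P(\text{hit}) = \text{logit}^{-1}(k(a - d))$ of ability minus difficulty.
Defaults, chosen once as a realistic training patient: slope k = 8 (a
10–90 % transition width of ≈ 0.55 on the unit difficulty scale, i.e. a
sharp but not degenerate threshold) and true ability 0.9 per skill, placing
the patient's operating point near the top of the revised catalogue so the
controller has to escalate through it. Reaction times are truncated normal
(mean 0.9 s, sd 0.3 s, floor 0.2 s) — design values, as the application
study reports none. Attendance is Bernoulli per session (default 1).

What the simulator does *not* emulate: fixation instability, learning or
fatigue drift within a session, spatially correlated detection noise, and
response bias (it never taps on fillers). Tests passing against it therefore
demonstrate the engine's contracts — determinism, recovery given coverage,
control-loop behaviour — not clinical performance on real patients.

## Numerical and design choices

* Seeds: every stochastic routine takes an explicit seed and restores the
  RNG state afterwards; composite runs derive sub-seeds with a fixed
  Lehmer-style mix kept below $2^{31}$.
* Cell indexing is 0-based (row, col) from the top-left; positions are
  centred centimetres; cells are compared by exact index, never by floating
  position.
* Scotoma-recovery accuracy is evaluated on tested cells only: untested
  cells carry no evidence in a single-presentation-per-cell design, so the
  Jaccard index compares estimated missed cells with the true lesion
  restricted to cells that were stimulated at least once. With two pooled
  50-stimulus tests only ~25 % of the grid (and so ~2 of the 9 lesion cells)
  is ever visited while the 2 % outside miss rate contributes a similar
  number of false misses, which bounds the achievable Jaccard near 0.5;
  localizing a small lesion reliably requires either repeated full tests or
  the follow-up mode concentrated on the suspected region.
* Tie rule in self-adjustment (hits = misses) holds difficulty; only the
  strict inequality triggers easing.
* Registration codes are 6 decimal digits, collision-checked against the
  store.
* Problem sizes used by the test suite and acceptance checks — 20 seeds for
  the stochastic properties, 30-session programs, 10,000 draws for the
  binomial convergence checks — were chosen to make binomial standard errors
  small relative to the asserted margins.

## Limitations

The engine treats rendering, audio, authentication and synchronization as
out of scope (voice and Talkback settings are carried as inert flags; upload
is a local export with a manifest). The per-skill taxonomy and requirement
levels are design estimates to be refined against clinical data, and the
difficulty index is a fixed functional form rather than a fitted model. The
follow-up rounding rule (ceiling) and the Chebyshev-2 scotoma environment
are parameterized conventions where the clinical design names only the
concept.
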