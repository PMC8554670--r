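---
title: "An adaptive text-message check-in engine: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive text-message check-in engine: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosth)
```

## The intervention model

`mosth` implements the decision logic of an automated, transdiagnostic
mobile support program for young adults with mental-health diagnoses
transitioning to college — an ecological momentary intervention in which
all support is delivered by text message and brief web forms, with no
human in the loop. The engine is a per-participant state machine over a
whole-day clock (day 0 = enrollment, 90-day program horizon):

1. **Text check-in.** "How would you rate your emotional health this past
   week?" The five-level reply partitions into POSITIVE (excellent, very
   good, good) and SUBOPTIMAL (fair, poor).
2. **Branch.** A POSITIVE reply earns positive feedback plus a link to a
   psychoeducational video library, and the next check-in steps *down* to
   monthly (+30 days). A SUBOPTIMAL reply triggers a web check-in: a
   checklist of six common stressors, nine negative effects, and a single
   self-efficacy gate ("To what extent do you feel you can manage your
   stressors and negative effects...").
3. **Self-efficacy gate.** "Completely" (HIGH) routes back to monthly
   cadence with positive feedback. Anything less (LOW) earns a coping-skill
   message drawn round-robin from a skills library (positive psychology,
   CBT, DBT), the video link, an "ok to check in next week?" ask, and a
   step *up* to weekly cadence (+7 days).
4. **Tailored feedback.** From the second completed web check-in on, the
   stressor and effect sets are compared with the prior check-in and the
   feedback payload carries the partition into *resolved* (prior \\
   current), *persisting* (intersection), and *new* (current \\ prior)
   items, phrased as improvement or unresolved problems.
5. **Care prompts.** A repeat check-in with still-LOW self-efficacy adds a
   prompt to arrange a mental-health care appointment. Independently, the
   safety rule fires when the two most recent check-ins both show a
   SUBOPTIMAL rating with a LOW self-efficacy report **and** lie at most 14
   days apart — the operationalization of "poor mental health and low
   self-efficacy two weeks in a row".
6. **Quit.** Texting "Quit" (case-insensitive) is absorbing: the state is
   deactivated and no action is ever emitted again.

Every operation is a pure function `(state, input, clock) -> (state,
actions)`, so replaying an event stream reproduces the action stream
exactly; this is what makes the engine testable and what the
`replay_event_log()` / CLI `run` pathway relies on.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `monthly_interval` | 30 | days | step-down cadence after no detected need |
| `weekly_interval` | 7 | days | step-up cadence after a LOW self-efficacy report |
| `reprompt_delay` | 1 | days | a missing response is reprompted once, a day later |
| `missing_delay` | 2 | days | still unanswered two days after the reprompt ⇒ missed |
| `missing_reschedule` | 7 | days | a missed check-in reschedules a week from the prompt day |
| `horizon_days` | 90 | days | three-month program |
| `escalation_window` | 14 | days | maximum gap for "two weeks in a row" |
| `escalation_rating` | `"suboptimal"` | — | which ratings qualify for the safety rule |

All are configuration (`default_config()`, YAML-overridable), not code.

### Design choices where the protocol description is open

The program description fixes the branch structure but leaves several
scheduling details open; the package fixes them as follows.

* **First interval.** Check-ins start on the enrollment day itself; the
  cadence thereafter is outcome-driven (30/7 days). With an all-POSITIVE
  reply stream this yields prompts on days 0, 30, 60 — exactly three over
  the 90-day horizon, consistent with the minimum of the observed 3–10
  range of check-ins sent per participant.
* **Missing responses.** One reprompt only, everywhere. A check-in that
  stays unanswered is marked missed and rescheduled +7 days from the
  prompt day: missingness is treated conservatively, as potential need. A
  missed *web* check-in records missing web data but neither increments
  nor resets the escalation counter — there is no evidence either way.
* **"Poor mental health" in the safety rule** is read as SUBOPTIMAL (fair
  or poor), matching the partition that triggers the web check-in;
  `escalation_rating = "poor"` gives the strict variant.
* **The care prompt accompanies the skill message** on a repeat LOW
  check-in rather than replacing it (nothing says support stops when care
  seeking is suggested), and it is distinct from the safety escalation
  prompt, which has its own trigger rule.
* **Declining the weekly-consent ask does not alter scheduling**; no
  decline branch is described, so the reply is treated as logged content
  only (`consent_decline_reschedules` exists for the alternative).
* **Scheduling anchor.** After a web outcome the next check-in is anchored
  at the day the web check-in was completed (not the text prompt day), so
  intervals between prompts are always ≥ 7 days; over days 0–89 the number
  of text check-ins delivered to a non-quitting participant is therefore
  bounded by [3, 13], an invariant the test suite fuzzes.

## Instrument scoring

Three self-report instruments are scored as unweighted means of answered
items: CCAPS-62 (62 items, 0–4, eight symptom subscales with sizes
13/9/7/5/9/6/7/6; higher = more severe), MHSES (6 items, 1–10; higher =
more confident), and PSSUQ (19 items, 1–7; *lower* = more usable, with the
standard keying: usefulness 1–8, information quality 9–15, interface
quality 16–18, overall 1–19). A (sub)scale is scored when at least 2/3 of
its items are answered, otherwise it is `NA`; the same tolerance is applied
to all three instruments for consistency. The CCAPS map is *structural*:
item content and ordering are not public here, so indices are assigned
block-sequentially — a synthetic ordering, exchangeable with the real
keying up to an item permutation. Reverse scoring and normative cut-points
are deliberately out of scope.

## What the simulator emulates — and what it does not

`simulate_participant()` closes the loop between the engine and a sampled
participant: the clock jumps from engine event to engine event, and every
prompt is answered or ignored according to a `behavior_profile()`. The
default two-component mixture (`default_profiles()`) encodes the cohort's
printed engagement behavior as study conditions:

* endorsement probabilities equal to the printed per-check-in frequencies
  (school 0.51, finances 0.37, ..., feeling worn out 0.65, low motivation
  0.56, ...);
* probability 0.91 of a LOW self-efficacy report on a completed web
  check-in (low 39/43);
* text nonresponse 0 (all text check-ins were completed) and web
  nonresponse 0.22 (43/55 = 78% completed);
* an at-risk component (weight 0.75) whose rating distribution places 45%
  of mass on SUBOPTIMAL, and a mostly-well component that only ever rates
  POSITIVE. These two free quantities were calibrated once so that about
  21 of 34 intervention participants report at least one suboptimal rating
  over 90 days, the per-participant web check-in median is near 2, and the
  text check-in median falls inside the observed 3–10 band.

Numerical details worth knowing:

* **Nonresponse.** `p_*_nonresponse` is the probability that a whole
  check-in ends unanswered. The original prompt and its reprompt are
  ignored as independent draws, each with probability `sqrt(p)`, so the
  realized per-check-in nonresponse equals `p` and cohort web completion
  sits near 78% under the default.
* **Endorsement persistence.** Marginal endorsement frequencies are all
  that is known, so items are sampled independently per check-in; a
  carry-over probability (default 0.5) copies an item's previous state
  instead of redrawing it. Because the copy is of the *state* (endorsed or
  not), the marginal rate is left exactly at the profile probability while
  within-person persistence becomes positive — enough to exercise the
  resolved/persisting/new feedback branches. The true within-person
  correlation is unknowable from printed marginals; carry-over is an
  assumption, flagged in the config.
* **Seeding.** Per-participant seeds are drawn deterministically from the
  master seed; identical seeds give byte-identical JSONL logs.

What the simulator does **not** model: symptom trajectories or any
treatment effect (the enhanced-usual-care arm produces only enrollment and
video-link events), true rating autocorrelation, response latencies within
a day, or dropout dynamics (the default quit probability is 0, matching a
trial in which nobody texted Quit). Passing tests therefore demonstrate
engine correctness and calibration of *engagement behavior*, not clinical
realism of simulated symptom data.

## Analytics

`engagement_summary()`, `endorsement_frequencies()`, `retention_rate()`,
`care_use_table()`, and `longitudinal_means()` are descriptive only, by
design: model-based estimation (GEE and the like) needs individual-level
trial data and is available off the shelf elsewhere. Conventions: a
reprompt belongs to the check-in that triggered it and never enters the
prompt denominator; endorsement denominators are completed web check-ins;
percentages are integers rounded half-up (the reporting style of trial
tables — e.g. 45/52 prints as 87, not 86); cell SDs use the sample (n−1)
definition, with a single-observation cell reported as `NA`.

## Problem sizes and determinism in the test suite

The suite fuzzes the schedule-bound invariant over 10,000 random reply
streams, checks the comparison set identities exhaustively over all
64 × 64 stressor-set pairs, verifies the escalation rule against a
brute-force oracle on 300 generated histories, and checks endorsement
frequencies within ±2 percentage points on 5,000 sampled web check-ins
(1,250 carry-over chains of length 4) — sizes chosen to make sampling
error comfortably smaller than the tolerances while keeping the default
run fast. All stochastic tests run under fixed seeds and are
deterministic.

## Known limitations

* The CCAPS item map is structural; scores on real CCAPS exports require
  the licensed keying (including reverse-scored items) and must not be
  compared against published norms.
* The skills library contents are illustrative stand-ins; the program's
  actual message texts beyond the quoted fixed prompts are configuration.
* The engine's day granularity cannot express the 24/48-hour reprompt
  windows more finely than whole days.
* Simulated cohorts reproduce marginal engagement statistics; joint
  distributions (e.g. which participants both endorse many stressors and
  respond slowly) are not identified by the calibration targets.
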