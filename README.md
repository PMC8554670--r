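# mosth

An engine, simulator, and analytics toolkit for an automated mobile
mental-health support program ("MoST-MH"-style) aimed at young adults with
mental-health diagnoses transitioning to college. It is written for
digital-intervention researchers and engineers who need the intervention's
decision logic as a deterministic, replayable, testable artifact rather
than as a production SMS stack.

## What it implements

The core is a per-participant **state machine** over a whole-day clock
(day 0 = enrollment, 90-day horizon):

- Text check-ins ask for a weekly emotional-health rating
  *r ∈ {excellent, very good, good, fair, poor}*, partitioned into
  POSITIVE and SUBOPTIMAL.
- POSITIVE → positive feedback + video-library link; next check-in at
  *t + 30* (step-down to monthly).
- SUBOPTIMAL → web check-in (6-item stressor checklist, 9-item
  negative-effect checklist, self-efficacy gate). HIGH self-efficacy
  ("completely") → *t + 30*; LOW → skill message + consent ask, *t + 7*
  (step-up to weekly).
- Consecutive check-ins are compared: feedback carries the partition of
  stressors/effects into resolved (prior \ current), persisting
  (prior ∩ current), and new (current \ prior).
- A repeat LOW self-efficacy report adds a care-seeking prompt; two
  qualifying check-ins (SUBOPTIMAL + LOW) ≤ 14 days apart trigger the
  safety escalation prompt.
- Missing responses are reprompted exactly once; still-unanswered
  check-ins are marked missed and rescheduled +7 days. "Quit" is
  absorbing.

Around the engine: a message-template library with tailored-feedback
rendering; scoring for CCAPS-62 (8 subscales, items 0–4), MHSES (6 items,
1–10), and PSSUQ (19 items, 1–7, standard keying); a seeded cohort
simulator calibrated to the program's observed engagement behavior; and
descriptive engagement / endorsement / retention / care-use analytics over
JSONL event logs. See the vignette in `vignettes/checkin-engine.Rmd` for
the full model and design notes.

## Worked example

```r
library(mosth)

logs <- simulate_cohort(cohort_spec(n_mosth = 34, n_euc = 18), seed = 7)
engagement_summary(logs)
#> Engagement over 52 participant(s)
#>   text check-ins: 161 prompted, 161 completed (100%); median 4.5 (range 3-12)
#>   web check-ins:  70 prompted, 51 completed (73%); median 3 (range 1-11)

ft <- endorsement_frequencies(logs)
head(ft$table[order(-ft$table$count), ], 3)
#>              item        category count pct
#>  feeling_worn_out negative_effect    40  78
#>    low_motivation negative_effect    33  65
#>  trouble_focusing negative_effect    28  55
```

Every text check-in is completed (the cohort's calibrated text nonresponse
is zero), web completion fluctuates around its nominal 78% rate, and the
most endorsed negative effect is feeling worn out — the qualitative
engagement profile the simulator is calibrated to. Instrument scoring:

```r
score_mhses(c(2, 4, 6, 8, 10, 6))
#> [1] 6
score_ccaps(c(rep(3, 13), rep(1, 49)))[["depression"]]
#> [1] 3
```

A deterministic single-participant trace, driven by hand:

```r
st <- start_program("p1", 0)$state
st <- advance_clock(st, 0)$state                    # fires the day-0 prompt
res <- process_text_reply(st, 0, "fair")            # -> send_web_link
res <- process_web_checkin(res$state,
  web_checkin(0, stressors = "school", self_efficacy = "a_little"))
sapply(res$actions, `[[`, "kind")
#> [1] "send_skill_message"      "send_weekly_consent_ask"
res$state$next_checkin_day
#> [1] 7
```

## Command line

A thin CLI over the same functions lives at `inst/cli/most.R`:

```sh
Rscript inst/cli/most.R simulate --n-mosth 34 --n-euc 18 --seed 7 --out cohort.jsonl
Rscript inst/cli/most.R run --events cohort.jsonl --out actions.jsonl   # deterministic replay
Rscript inst/cli/most.R report --events cohort.jsonl --out report/
```

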