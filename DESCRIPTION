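Package: mosth
Title: Adaptive Text-Message Mental Health Check-In Engine, Simulator, and
    Engagement Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A deterministic per-participant state machine for an automated
    mobile mental-health support program for young adults transitioning to
    college. Text-message check-ins of weekly emotional health branch to
    web-based check-ins of stressors, negative effects, and self-efficacy;
    cadence steps down to monthly when no need is detected and up to weekly
    when self-efficacy is low, with care-seeking prompts after repeated low
    self-efficacy and a safety escalation after two qualifying weekly
    check-ins in a row. Includes tailored-feedback message rendering, scoring
    for the CCAPS, MHSES, and PSSUQ self-report instruments, a seeded
    behavior-calibrated cohort simulator, and descriptive engagement,
    endorsement, retention, and care-use analytics over JSONL event logs.
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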