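# Example engine configuration: overrides are merged over the package
# defaults (see ?default_config). All durations are whole days.
monthly_interval: 30
weekly_interval: 7
horizon_days: 90
escalation_rating: suboptimal   # or "poor" for the strict variant
carry_over: 0.5                 # simulator endorsement persistence (assumption)
video_url: "https://videos.example.org/college-mh"
resources_url: "https://resources.example.org/care"
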