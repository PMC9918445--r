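screen_times:
- 0.0
- 2.0
- 4.0
followup: 8.5
cohort_size: 74998.0
participation: 0.596
confirmation: 0.85
lead_time: 30.0
interval_cap: next_screen
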