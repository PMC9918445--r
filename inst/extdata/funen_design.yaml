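screen_times:
- 0.0
- 2.0
- 4.0
- 6.0
followup: 10.0
cohort_size: 30966.0
participation: 0.672
confirmation: 1.0
lead_time: 30.0
interval_cap: next_screen
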