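screen_times:
- 0.0
- 2.0
- 4.0
- 6.0
- 8.0
followup: 11.0
cohort_size: 5417699.0
participation: 0.7
confirmation: 1.0
lead_time: 20.0
interval_cap: next_screen
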