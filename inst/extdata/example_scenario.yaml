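# Example chronic exposure scenario (assumed, not from the study):
# a daily waterpipe user consuming 10 g tobacco/day over 30 years,
# 70 kg body weight, risks averaged over a 70-year lifetime (in days).
IR_kg_per_day: 0.01
EF_days_per_year: 365
ED_years: 30
BW_kg: 70
AT_days: 25550
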