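# Seven-day EF/fluoxetine delivery plan: EF only on Day 0, EF switching to
# fluoxetine at the 6-hour mark on Day 1, fluoxetine on the remaining days.
days: 7
window_h: 23
dose_target_mg: 0.025
day_modes: [EF, EF, FLX, FLX, FLX, FLX, FLX]
events:
  - day: 1
    hour: 6
    mode: FLX
ef_levels: [10, 0, 10, 0, 10, 0, 10, 0]
flx_levels: [0, 5, 0, 5, 0, 5, 0, 5]
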