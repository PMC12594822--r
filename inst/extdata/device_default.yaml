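# Default device electrical constants (board specification values).
v_cc: 4.7
n_adc: 12
n_dac: 8
i_max_uA: 50
r_sense_ohm: 10000
n_channels: 8
burst_n: 16
burst_spacing_s: 0.0005
sample_period_s: 0.1
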