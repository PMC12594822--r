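# Synthetic wound scenario: nominal dynamics with a dried-out capillary on
# channel 6 (50x series resistance). All magnitudes are synthetic stand-ins.
baseline_r: 200000
drift_sd: 200
movement_rate: 6
movement_magnitude: 2
movement_decay: 30
polarization_c: 1.0e-4
polarization_r: 50000
fault_channels:
  "6": 50
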