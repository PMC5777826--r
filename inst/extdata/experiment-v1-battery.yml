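version: 1
experiment: v1-battery
circuit: v1
baseline: low
options:
  grating_theta: 25.0
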