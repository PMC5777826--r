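version: 1
n_units:
- 800
- 100
- 50
- 50
p:
- - 0.02
  - 1.0
  - 1.0
  - 0.0
- - 0.01
  - 1.0
  - 0.85
  - 0.0
- - 0.01
  - 0.0
  - 0.0
  - 0.55
- - 0.01
  - 0.0
  - 0.5
  - 0.0
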