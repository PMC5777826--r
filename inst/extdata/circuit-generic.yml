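version: 1
populations:
- E
- P
- S
- V
w:
- - 2.42
  - -0.33
  - -0.8
  - 0.0
- - 2.97
  - -3.45
  - -2.13
  - 0.0
- - 4.64
  - 0.0
  - 0.0
  - -2.79
- - 0.71
  - 0.0
  - -0.16
  - 0.0
fi:
  E:
    tau_m: 0.028
    g_l: 6.25
    v_th: -50.0
    v_r: -60.0
    v_smooth: 1.0
    v_l: -70.0
  P:
    tau_m: 0.008
    g_l: 10.0
    v_th: -50.0
    v_r: -60.0
    v_smooth: 1.0
    v_l: -70.0
  S:
    tau_m: 0.016
    g_l: 5.0
    v_th: -50.0
    v_r: -60.0
    v_smooth: 1.0
    v_l: -70.0
  V:
    tau_m: 0.016
    g_l: 5.0
    v_th: -50.0
    v_r: -60.0
    v_smooth: 1.0
    v_l: -70.0
tau_r: 0.002
baseline_rates:
- 1.0
- 10.0
- 3.0
- 2.0
i_bkg:
- 114.7274955
- 233.6115779
- 94.3202738
- 89.9378861
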