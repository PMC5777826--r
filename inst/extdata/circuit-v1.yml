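version: 1
populations:
- E
- P
- S
- V
w:
- - 3.3
  - -3.48
  - -2.98
  - 0.0
- - 1.73
  - -4.25
  - -1.07
  - 0.0
- - 3.5
  - 0.0
  - 0.0
  - -4.51
- - 0.53
  - 0.0
  - -0.13
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
- 151.8874955
- 239.6715779
- 98.9002738
- 90.0278861
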