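# ratecircuit

Firing-rate models of the canonical cortical microcircuit formed by
excitatory pyramidal cells (E) and the three major interneuron classes —
parvalbumin (PV), somatostatin (SST) and vasoactive-intestinal-peptide (VIP)
expressing cells. The package is for computational neuroscientists who want
to analyse how such circuits respond to top-down modulation: in particular
the *paradoxical response reversal* of SST cells, whose steady response to a
VIP-targeted modulatory current (the locomotion signal in mouse V1) is
negative at low baseline activity (classic disinhibition) but positive at
high baseline activity, even though VIP directly inhibits SST.

## The model

Each population `i` has a rate `r_i` (Hz) driven by an effective membrane
potential `V_i` (mV) through a smoothed threshold-linear f-I curve with a
removable singularity at the threshold `V_th`:

    r_i = f(V_i) = (V_i - V_th) / (tau_m,i (V_th - V_r)) * 1 / (1 - exp(-(V_i - V_th)/v))

    V_i = V_l + (sum_j W_ij r_j + I_i + I_bkg,i) / g_l,i

    tau_r dr_i/dt = -r_i + f(V_i)

with `W` a signed connectivity matrix in pA·s, currents in pA, conductances
in nS and `tau_r = 2` ms. Background currents `I_bkg` are calibrated
directly (no fitting) so the circuit sits at a chosen spontaneous baseline.

Steady-state responses to small inputs are organised by the **response
matrix** `M = (D - W)^-1`, where `D` is diagonal with `D_ii = g_l,i /
f'(V_i)` (the inverse gain, pA·s). `M_ij` accumulates every direct and
indirect pathway from population `j` to `i`, so its sign can differ from
that of `W_ij` and can flip with the operating point: `M_SV < 0` is the
disinhibition regime, `M_SV > 0` the response-reversal regime, and reversal
requires recurrent excitation to exceed the inverse E gain (`w_EE > d_E`,
the inhibition-stabilized-network condition).

Beyond the four-population model the package provides: analytic onset
derivatives of the transient response (the SST rate always starts downward
under VIP-targeted input, in every regime); a random unit-level network
expansion (800/100/50/50 units, Bernoulli connectivity) reproducing the
response diversity seen across simultaneously recorded neurons; a mouse-V1
condition battery (darkness / gray screen / size-varying gratings crossed
with immobility / locomotion) with surround-suppression size tuning and
±10% connectivity-robustness checks; and rejection sampling of
sign-structured connectivity matrices.

## Worked example

```r
library(ratecircuit)

circ <- circuit_generic() |> calibrate_background(c(1, 10, 3, 2))
circ
#> <circuit> 4 populations: E, P, S, V
#> W (pA s):
#>      E     P     S     V
#> E 2.42 -0.33 -0.80  0.00
#> P 2.97 -3.45 -2.13  0.00
#> S 4.64  0.00  0.00 -2.79
#> V 0.71  0.00 -0.16  0.00
#> background currents (pA): E=114.73, P=233.61, S=94.32, V=89.94

classify_regime(circ)
#> # A tibble: 1 × 7
#>   regime        isn     m_sv  w_ee   d_e wee_minus_de wep_wpe
#> 1 disinhibition FALSE -0.242  2.42  9.36        -6.94   0.980
```

The calibrated background currents (114.7, 233.6, 94.3, 89.9 pA) hold the
circuit at the low spontaneous baseline of 1, 10, 3 and 2 Hz; there `M_SV =
-0.24` Hz/pA, so extra VIP input suppresses SST — disinhibition, and the
circuit is not inhibition-stabilized (`w_EE = 2.42 < d_E = 9.36` pA·s).
Recalibrating to a high baseline flips the regime:

```r
high <- circuit_generic() |> calibrate_background(c(30, 50, 30, 20))
glance(response_matrix(high))
#> # A tibble: 1 × 4
#>   c_det  m_sv regime            isn
#> 1 0.184 0.971 response_reversal TRUE

verify_onset(high, d_i = c(0, 0, 0, 10), horizon = 0.3, dt = 1e-5)$summary
#>   population baseline  min  max final dips_below settles_above reverses
#> 1          E       30 30.0 47.0  46.3      FALSE          TRUE    FALSE
#> 2          P       50 50.0 61.5  55.7      FALSE          TRUE    FALSE
#> 3          S       30 17.6 43.0  41.3       TRUE          TRUE     TRUE
#> 4          V       20 20.0 44.0  43.8      FALSE          TRUE    FALSE
```

Now `M_SV = +0.97` Hz/pA and the circuit is an ISN. The transient check
shows what a recording would see when a 10 pA top-down current switches on:
SST first dips from 30 Hz to 17.6 Hz, then recurrent excitation pulls it up
to a plateau of 41.3 Hz — below baseline first, above it at steady state.

`autoplot()` methods draw trajectories, response-matrix heat maps and
condition batteries; `simulate_circuit()`, `run_condition_battery()`,
`sample_unit_network()`/`simulate_units()`/`rate_modulation()` and
`perturb_connectivity()` cover the dynamical, V1 and unit-level analyses.
A thin command-line front end over the same functions ships at
`inst/cli/ratecircuit` (subcommands `calibrate`, `simulate`, `respmat`,
`onset`, `random-net`, `v1-battery`, `v1-robustness`, `v1-size-tuning`,
`sample-connectivity`).

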