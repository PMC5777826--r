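---
title: "Baseline-dependent response reversal in the E/PV/SST/VIP microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline-dependent response reversal in the E/PV/SST/VIP microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecircuit)
```

## The model and its assumptions

`ratecircuit` models a cortical column as four interacting populations —
excitatory cells (E) and PV, SST and VIP interneurons — each described by a
single average rate. The population nonlinearity is a smoothed
threshold-linear f-I curve

$$r_i = f_i(V_i) = \frac{V_i - V_{th}}{\tau_{m,i}(V_{th} - V_r)}
        \frac{1}{1 - e^{-(V_i - V_{th})/v}},$$

flat below threshold, linear with slope $1/(\tau_{m,i}(V_{th}-V_r))$ far
above it, and continuous through the removable singularity at $V_{th}$ with
value $v/(\tau_{m,i}(V_{th}-V_r))$. The effective potential collects leak,
recurrent, external and background currents,
$V_i = V_l + (\sum_j W_{ij} r_j + I_i + I^{bkg}_i)/g_{l,i}$, and rates relax
as $\tau_r \dot r_i = -r_i + f_i(V_i)$.

Assumptions worth keeping in mind: populations are homogeneous (one f-I
curve each), synapses are instantaneous current sources (no conductance
effects, delays or short-term plasticity), and all modulation enters as
constant currents. These are the standard simplifications of
population-rate modelling; they are exactly what makes the steady-state
response analytically tractable.

The central object is the response matrix $M = (D - W)^{-1}$ with
$D_{ii} = g_{l,i}/f_i'(V_i)$, the linearization of the fixed-point
condition: for a small current perturbation, $\delta r = M\,\delta I$.
Because $D$ depends on the operating point through the gain $f'$, the sign
of entries of $M$ can flip as the baseline moves: `classify_regime()` labels
the circuit *disinhibition* ($M_{SV}<0$) or *response reversal*
($M_{SV}>0$), alongside the inhibition-stabilized-network flag
($w_{EE} > d_E$).

## Parameters, units and defaults

All potentials are in mV ($V_{th}=-50$, $V_r=-60$, $V_l=-70$, smoothness
$v=1$), conductances in nS ($g_l$ = 6.25, 10, 5, 5 for E, PV, SST, VIP),
membrane time constants in seconds (0.028, 0.008, 0.016, 0.016), weights in
pA·s and currents in pA. With these conventions the unit algebra closes
without hidden factors: (pA·s)(Hz) = pA, pA/nS = mV, and `net_input()` of a
silent circuit returns $V_l$ exactly — a property the test suite asserts.
$\tau_r = 2$ ms sets the relaxation timescale of rates and is deliberately
much faster than the membrane constants entering the gain.

The two reference connectivities, `circuit_generic()` and `circuit_v1()`,
encode the canonical wiring (E excites everything; PV inhibits E and
itself; SST inhibits E, PV and VIP; VIP inhibits SST). Background currents
are not free parameters: `calibrate_background()` computes them in closed
form from target baseline rates by inverting the f-I curve, so a baseline
*is* the parameter. The two reference baselines are (1, 10, 3, 2) Hz
("low", spontaneous) and (30, 50, 30, 20) Hz ("high"); the first yields
background currents of 114.7, 233.6, 94.3 and 89.9 pA for the generic
circuit, which the acceptance script recomputes.

One analytic constant deserves a note. The inverse gain
$d_i(V) = g_{l,i}/f_i'(V)$ decreases monotonically to a positive floor as
input grows; since $f' \to 1/(\tau_{m,i}(V_{th}-V_r))$, that floor is
$d_i^\infty = g_{l,i}\,\tau_{m,i}\,(V_{th}-V_r)$ (1.75 pA·s for E). A
version of this constant with the conductance dividing rather than
multiplying circulates in print; it is dimensionally inconsistent with
$D_{ii} = g_{l,i}/f'$, and `d_infinity()` implements the limit that the
numerical gain actually attains, which the tests verify on a grid.

Similarly, the package ships the printed closed-form cofactor tabulation of
all sixteen entries of $M$ for this zero pattern
(`response_matrix_symbolic()`) purely as a validation layer.
`response_formula_check()` compares it entry-by-entry against the numeric
inverse over random stable parameter draws: thirteen entries agree to
machine precision, while three ($M_{PP}$, $M_{VS}$, $M_{VV}$) carry
typographic errors in their printed forms (a sign on one term in the first
two, a transposed index in the third) and are reported as discrepant rather
than silently corrected. The numeric inverse is canonical everywhere in the
package.

## Transient onset analysis

At a fixed point, a current step $\delta I$ moves potentials instantly and
rates gradually, so $\dot r_i(0^+) = (f_i(V_i + \delta I_i/g_{l,i}) -
r_i)/\tau_r$ is non-zero only for directly stimulated populations, and the
curvature $\ddot r_i(0^+)$ of the others is set by their direct connection
from the stimulated population. For a VIP-targeted step this makes the
initial SST movement negative in *every* regime — response reversal is a
steady-state phenomenon that the transient must undo, which is why the
high-baseline SST trajectory dips below baseline before settling above it.
`onset_derivatives()` evaluates these expressions for arbitrary
single- or multi-population steps (the multi-population generalization
simply keeps the full sum $\sum_j W_{ij}\dot r_j$), and `verify_onset()`
confronts them with finite differences of a fine-step simulation.
"Initial direction" is operationalized as the sign of the first
non-vanishing derivative at $t=0^+$, with absolute floors (1e-6 Hz/s,
1e-3 Hz/s²) so that fixed-point residual noise reads as flat; a dip only
counts if it exceeds 1e-3 Hz.

## Numerical choices

* **f-I evaluation.** Series branch for $|V - V_{th}| < 10^{-5}$ mV
  (second order, error $\sim 10^{-16}$ relative), asymptotic branch for
  $V - V_{th} < -33$ mV where the direct exponential would overflow;
  analytic derivative with the same branches. The inverse uses bracketed
  `uniroot` plus one Newton polish, giving round trips to 1e-10 relative.
* **Fixed points.** Damped Newton on $g(r) = r - f(V(r))$ from the
  calibration baseline, with a 2 s simulated relaxation as fallback when a
  step fails to reduce the residual; convergence at 1e-10 Hz, and
  non-convergence is always reported (`converged` attribute plus warning),
  never silent.
* **Integration.** Explicit Euler with default $dt = 0.1$ ms
  ($\tau_r/20$); the constructor refuses $dt > \tau_r/4$. Halving the step
  moves reference endpoints by far less than 1e-4 Hz (asserted), which is
  ample for trajectories whose features live on tens of milliseconds.
  Rates are never clipped: the f-I curve is non-negative by construction,
  and divergence aborts with the time of blow-up.
* **Stability.** Eigenvalues of the rate Jacobian
  $(-I + \mathrm{diag}(f'/g_l)W)/\tau_r$; the determinant of $D - W$ is
  reported alongside since a stable operating point implies a positive
  normalization $C = 1/\det(D-W)$ for the response matrix.
* **Dead-bands.** Qualitative sign predicates (the V1 locomotion pattern,
  surround-suppression detection) use a 1e-2 Hz dead-band so that
  near-zero differences are never over-interpreted.

## Synthetic circuits and networks: what they emulate

`sample_connectivity()` draws weight magnitudes log-uniformly in
[0.1, 5] pA·s on the canonical zero pattern and rejects candidates until an
acceptance predicate holds; `accept_regimes()` demands stability at both
reference baselines with disinhibition at low and reversal at high — the
full phenomenology, found within a few hundred draws. The unit-level
expansion (`sample_unit_network()`, defaults 800/100/50/50 units) replicates
each population into identical units wired by independent Bernoulli draws
with the packaged connection-probability table; realized weights are the
population weight divided by the expected in-degree $p_{ij}N_j$ (within a
population $p_{ij}(N_j-1)$, as self-connections are excluded — this makes
the deterministic $p=1$ block reproduce the population model exactly, which
is tested to 1e-10). The shipped probability table carries one negative
entry in its printed source (SST←VIP, −0.55); probabilities cannot be
negative, the sign of that pathway already lives in the weight matrix, and
the magnitude is used with a warning raised whenever the folding fires.

These synthetic objects emulate connection-count heterogeneity only. Real
cortical data also show heterogeneous cellular parameters, weight jitter,
synaptic dynamics and correlated (non-Bernoulli) wiring; none of that is
modelled, so passing tests demonstrate that random wiring *alone* suffices
to produce response diversity — including units whose modulation sign
opposes their population mean at high baseline — not that it is the only
source in tissue. Population-mean modulations track the population model
closely at the low baseline (the acceptance suite checks agreement within
three standard errors over ten network draws) but carry a visible
finite-size bias at the high baseline, where the strong gain amplifies
in-degree fluctuations; the high-baseline checks are therefore sign- and
heterogeneity-based rather than quantitative.

## The V1 battery

`run_condition_battery()` crosses three visual conditions with two
behavioral states. Stimulus currents follow the sigmoid size dependence
$I_i(\theta) = a_i/(1+e^{-\theta/b_i}) + 5$ pA for gratings
($a_E=100, b_E=2$; $a_S=20, b_S=6$; E input saturating near 20 deg, SST
near 60 deg), fixed constants for darkness (0 pA) and gray screen (50 pA to
E); the +5 pA offset belongs to the grating sigmoid only, since the
darkness and gray conditions are defined by their own constants.
Locomotion adds 10 pA onto VIP. Three defaults are package choices where no
value is published: the pre-stimulus baseline is calibrated to (1, 10, 3,
2) Hz; the unlabelled "grating" condition uses $\theta = 25$ deg (past the
E-input saturation, below SST's, where the reversal is clearest); and the
structural variants `pv_to_vip`/`pv_to_sst` default to a 0.1 pA·s added
projection, a placeholder that must be set explicitly for any scientific
claim. All three are arguments, and every robustness report states its
seed. `perturb_connectivity()` multiplies each weight by an independent
uniform factor in $[0.9, 1.1]$, re-calibrates to the same baseline, reruns
the battery and scores the qualitative pattern (SST down in darkness under
locomotion, everything else up; all populations up under gray and grating),
reporting the preservation rate with a binomial confidence interval and the
count of unstable draws rather than hiding them.

## Problem sizes

The shipped test-suite and acceptance runs use the full-size unit network
(1000 units, ten seeds, 0.6 s at $dt = 0.2$ ms) for the mean-field check,
scaled-down networks (~250 units) for structural unit tests, 100-draw
Monte-Carlo for both the closed-form comparison and the V1 robustness
check, and 0.3–0.5 s horizons for trajectory assertions — sizes at which
every stochastic criterion is comfortably resolved while the whole suite
runs in about two minutes on one core.

## Known limitations

Single-rate populations cannot express within-population correlations or
spike timing; the Euler scheme is first order (adequate here, but the
integrator is isolated in one function if higher order is ever needed);
response-matrix analysis is local, so large perturbations that move the
operating point across the threshold region need the full nonlinear solver;
and calcium-imaging measurements are related to rates nonlinearly, so
comparisons of the V1 battery with fluorescence data are meaningful at the
level of signs and orderings, not magnitudes.
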