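# Shared fixtures, built in code.

fi_e <- function() fi_curve(tau_m = 0.028, g_l = 6.25)
fi_p <- function() fi_curve(tau_m = 0.008, g_l = 10)

low_targets <- c(1, 10, 3, 2)
high_targets <- c(30, 50, 30, 20)

circ_low <- function() calibrate_background(circuit_generic(), low_targets)
circ_high <- function() calibrate_background(circuit_generic(), high_targets)

# a circuit with no recurrence: every population decoupled
circ_decoupled <- function(targets = low_targets) {
  calibrate_background(
    circuit(matrix(0, 4, 4), ratecircuit:::fi_presets()), targets)
}

# draw calibrated, linearly stable random microcircuits (rejection)
random_stable_circuits <- function(n, seed, targets_range = c(0.5, 30)) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    w <- ratecircuit:::random_microcircuit_w()
    targets <- exp(runif(4, log(targets_range[1]), log(targets_range[2])))
    cc <- tryCatch(
      calibrate_background(circuit(w, ratecircuit:::fi_presets()), targets),
      error = function(e) NULL)
    if (is.null(cc)) next
    st <- tryCatch(jacobian_stability(cc, targets), error = function(e) NULL)
    if (is.null(st) || !st$is_stable) next
    out[[length(out) + 1]] <- cc
  }
  out
}
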