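#' Visual-stimulus currents for the V1 model
#'
#' Maps a visual condition to the external current vector (pA) it injects.
#' Three conditions are modelled: `darkness` (no stimulus current at all),
#' `gray` screen (a small constant drive to the excitatory population,
#' 50 pA), and a drifting `grating` of diameter `theta` (deg), whose drive is
#' a sigmoid of stimulus size,
#' \deqn{I_i(\theta) = \frac{a_i}{1 + e^{-\theta/b_i}} + 5 \;\mathrm{pA},}
#' with \eqn{a_E = 100} pA, \eqn{b_E = 2} deg for the excitatory (center)
#' input and \eqn{a_S = 20} pA, \eqn{b_S = 6} deg for the SST (surround)
#' input: E input saturates around 20 deg, SST input around 60 deg, which is
#' what produces surround suppression. With `pv_input = TRUE` the thalamic
#' drive also reaches PV (\eqn{a_P = 20} pA, \eqn{b_P = 2} deg for gratings,
#' 10 pA for gray screen, 0 in darkness).
#'
#' @param kind One of `"darkness"`, `"gray"`, `"grating"`.
#' @param theta Grating diameter, deg (required for gratings; must be >= 0).
#' @param pv_input Also drive PV (the thalamic-input-to-PV variant)?
#' @param populations Population labels of the target circuit.
#' @return Named current vector, pA.
#' @examples
#' stimulus_current("grating", theta = 6)
#' @export
stimulus_current <- function(kind = c("darkness", "gray", "grating"),
                             theta = NULL, pv_input = FALSE,
                             populations = c("E", "P", "S", "V")) {
  kind <- match.arg(kind)
  out <- setNames(rep(0, length(populations)), populations)
  if (kind == "darkness") return(out)
  if (kind == "gray") {
    out["E"] <- 50
    if (pv_input) out["P"] <- 10
    return(out)
  }
  if (is.null(theta)) abort("`theta` is required for gratings")
  if (!is.finite(theta) || theta < 0) abort("`theta` must be >= 0")
  sig <- function(a, b) a / (1 + exp(-theta / b)) + 5
  out["E"] <- sig(100, 2)
  out["S"] <- sig(20, 6)
  if (pv_input) out["P"] <- sig(20, 2)
  out
}

v1_conditions_default <- function(grating_theta = 25) {
  tibble(
    condition = c("darkness", "gray", sprintf("grating_%gdeg", grating_theta)),
    kind = c("darkness", "gray", "grating"),
    theta = c(NA_real_, NA_real_, grating_theta)
  )
}

#' Run the V1 stimulus-by-state condition battery
#'
#' For every visual condition (darkness, gray screen, grating of diameter
#' `grating_theta`) crossed with behavioral state (immobility; locomotion,
#' modelled as `locomotion_pa` extra pA onto VIP), computes the steady-state
#' rates of the calibrated circuit and flags each operating point's linear
#' stability. Unstable or non-converged rows are flagged, not dropped.
#'
#' @param circ A calibrated [circuit()] (see [circuit_v1()]); the baseline
#'   calibration is the darkness/immobility state.
#' @param grating_theta Grating diameter, deg (default 25: past the
#'   saturation of the E input, below that of the SST input).
#' @param locomotion_pa Top-down modulatory current onto VIP, pA (default 10).
#' @param pv_input Route stimulus current to PV as well (variant batteries).
#' @param conditions Optional tibble with columns `condition`, `kind`,
#'   `theta` to override the default battery.
#' @return Tibble of class `condition_battery`: `condition`, `state`,
#'   `r_<pop>` (Hz), `stable`, `converged`.
#' @export
run_condition_battery <- function(circ, grating_theta = 25,
                                  locomotion_pa = 10, pv_input = FALSE,
                                  conditions = NULL) {
  stopifnot(inherits(circ, "circuit"))
  if (is.null(circ$i_bkg)) abort("circuit must be calibrated first")
  conditions <- conditions %||% v1_conditions_default(grating_theta)
  pops <- circ$populations
  grid <- tidyr::expand_grid(conditions,
                             state = c("immobility", "locomotion"))
  rows <- purrr::pmap(grid, function(condition, kind, theta, state) {
    i_stim <- stimulus_current(kind, theta = theta, pv_input = pv_input,
                               populations = pops)
    i_loco <- setNames(rep(0, length(pops)), pops)
    if (state == "locomotion") i_loco["V"] <- locomotion_pa
    ss <- steady_state(circ, i_ext = i_stim + i_loco)
    stable <- if (attr(ss, "converged")) {
      jacobian_stability(circ, as.numeric(ss),
                         i_ext = i_stim + i_loco)$is_stable
    } else NA
    out <- tibble(condition = condition, state = state)
    out[paste0("r_", pops)] <- as.list(as.numeric(ss))
    out$stable <- stable
    out$converged <- attr(ss, "converged")
    out
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("condition_battery", class(out)),
            populations = pops)
}

#' Bar chart of a condition battery
#'
#' Rates per population, grouped by condition, immobility as empty and
#' locomotion as filled bars.
#'
#' @param object A [run_condition_battery()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.condition_battery <- function(object, ...) {
  pops <- attr(object, "populations")
  td <- object |>
    tidyr::pivot_longer(dplyr::all_of(paste0("r_", pops)),
                        names_to = "population", names_prefix = "r_",
                        values_to = "rate") |>
    dplyr::mutate(population = factor(.data$population, levels = pops))
  ggplot2::ggplot(td, ggplot2::aes(.data$population, .data$rate,
                                   fill = .data$state,
                                   alpha = .data$state)) +
    ggplot2::geom_col(position = "dodge", colour = "grey30") +
    ggplot2::scale_alpha_manual(values = c(immobility = 0.25,
                                           locomotion = 1)) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Size tuning of the grating response
#'
#' Sweeps the grating diameter and records the steady rates for one
#' behavioral state, together with the injected currents. Because the E
#' (center) input saturates at smaller diameters than the SST (surround)
#' input, the excitatory rate can rise and then fall with stimulus size —
#' surround suppression; the attribute `e_nonmonotone` reports whether that
#' signature (a rise followed by a drop exceeding `tol`) is present.
#'
#' @param circ A calibrated [circuit()].
#' @param thetas Increasing grid of grating diameters, deg.
#' @param state `"immobility"` or `"locomotion"`.
#' @param locomotion_pa Locomotion current onto VIP, pA.
#' @param pv_input Route stimulus current to PV as well.
#' @param tol Detection threshold for non-monotonicity, Hz (default 1e-2).
#' @return Tibble: `theta`, `i_E`, `i_S`, `r_<pop>`, `stable`; attribute
#'   `e_nonmonotone`.
#' @export
size_tuning <- function(circ, thetas = c(2, 6, 10, 20, 40, 60),
                        state = c("immobility", "locomotion"),
                        locomotion_pa = 10, pv_input = FALSE, tol = 1e-2) {
  stopifnot(inherits(circ, "circuit"))
  if (is.null(circ$i_bkg)) abort("circuit must be calibrated first")
  state <- match.arg(state)
  if (is.unsorted(thetas, strictly = TRUE)) {
    abort("`thetas` must be strictly increasing")
  }
  pops <- circ$populations
  rows <- purrr::map(thetas, function(th) {
    i_stim <- stimulus_current("grating", theta = th, pv_input = pv_input,
                               populations = pops)
    if (state == "locomotion") i_stim["V"] <- i_stim["V"] + locomotion_pa
    ss <- steady_state(circ, i_ext = i_stim)
    out <- tibble(theta = th, i_E = i_stim[["E"]], i_S = i_stim[["S"]])
    out[paste0("r_", pops)] <- as.list(as.numeric(ss))
    out$stable <- jacobian_stability(circ, as.numeric(ss),
                                     i_ext = i_stim)$is_stable
    out
  })
  out <- dplyr::bind_rows(rows)
  re <- out$r_E
  peak <- which.max(re)
  nonmono <- peak > 1 && peak < length(re) &&
    (re[peak] - re[1]) > tol && (re[peak] - re[length(re)]) > tol
  structure(out, e_nonmonotone = nonmono)
}

# predicate: does a battery show the canonical V1 locomotion pattern?
# darkness: SST down, E/PV/VIP up; gray + grating: all four up.
battery_pattern_ok <- function(bat, dead_band = 1e-2) {
  pops <- c("E", "P", "S", "V")
  if (any(!bat$converged) || any(!bat$stable)) return(FALSE)
  wide <- bat |>
    tidyr::pivot_longer(dplyr::all_of(paste0("r_", pops)),
                        names_to = "population", names_prefix = "r_",
                        values_to = "rate") |>
    tidyr::pivot_wider(names_from = "state", values_from = "rate") |>
    dplyr::mutate(delta = .data$locomotion - .data$immobility)
  ok <- TRUE
  for (i in seq_len(nrow(wide))) {
    dark <- grepl("darkness", wide$condition[i])
    sst <- wide$population[i] == "S"
    d <- wide$delta[i]
    ok <- ok && if (dark && sst) d < -dead_band else d > dead_band
  }
  ok
}

#' Robustness of the V1 pattern to connectivity perturbations
#'
#' Each draw multiplies every connection weight independently by a uniform
#' factor in \eqn{[1 - \mathrm{fraction},\, 1 + \mathrm{fraction}]} (signs
#' preserved), re-calibrates the background currents to the same baseline
#' rates, reruns the condition battery and checks the qualitative locomotion
#' pattern (SST down in darkness, everything else up; all populations up
#' under gray screen and gratings, with a `dead_band` of 1e-2 Hz). Draws
#' whose operating points are unstable are counted and reported, not hidden.
#'
#' @param circ A calibrated [circuit()].
#' @param fraction Relative perturbation half-width (default 0.10).
#' @param n_draws Number of Monte-Carlo draws (default 100).
#' @param seed RNG seed.
#' @param grating_theta,locomotion_pa,pv_input Passed to
#'   [run_condition_battery()].
#' @param dead_band Sign dead-band, Hz.
#' @return List of class `robustness_report`: `draws` (tibble: `draw`,
#'   `all_stable`, `preserved`) and `summary` (tibble: counts, preservation
#'   rate among stable draws with an exact binomial 95% CI).
#' @export
perturb_connectivity <- function(circ, fraction = 0.10, n_draws = 100, seed,
                                 grating_theta = 25, locomotion_pa = 10,
                                 pv_input = FALSE, dead_band = 1e-2) {
  stopifnot(inherits(circ, "circuit"))
  if (is.null(circ$baseline)) abort("circuit must be calibrated first")
  if (fraction < 0 || fraction >= 1) abort("`fraction` must be in [0, 1)")
  if (missing(seed)) abort("`seed` must be given explicitly")
  set.seed(seed)
  base_w <- circ$w
  rows <- purrr::map(seq_len(n_draws), function(k) {
    fac <- matrix(runif(length(base_w), 1 - fraction, 1 + fraction),
                  nrow(base_w))
    pc <- circuit(base_w * fac, circ$fi, populations = circ$populations,
                  tau_r = circ$tau_r)
    pc <- calibrate_background(pc, circ$baseline)
    bat <- tryCatch(
      run_condition_battery(pc, grating_theta = grating_theta,
                            locomotion_pa = locomotion_pa,
                            pv_input = pv_input),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(bat)) {
      return(tibble(draw = k, all_stable = FALSE, preserved = FALSE))
    }
    tibble(draw = k,
           all_stable = all(bat$stable & bat$converged),
           preserved = battery_pattern_ok(bat, dead_band))
  })
  draws <- dplyr::bind_rows(rows)
  n_stable <- sum(draws$all_stable)
  n_pres <- sum(draws$preserved & draws$all_stable)
  ci <- if (n_stable > 0) {
    stats::binom.test(n_pres, n_stable)$conf.int
  } else c(NA_real_, NA_real_)
  summary <- tibble(
    n_draws = n_draws, n_stable = n_stable, n_unstable = n_draws - n_stable,
    n_preserved = n_pres,
    preservation_rate = if (n_stable > 0) n_pres / n_stable else NA_real_,
    ci_lower = ci[1], ci_upper = ci[2])
  structure(list(draws = draws, summary = summary, fraction = fraction,
                 seed = seed),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<robustness_report> +/-%.0f%% perturbations: %d/%d stable, %d preserved (%.1f%%, 95%% CI %.1f-%.1f%%)\n",
    100 * x$fraction, s$n_stable, s$n_draws, s$n_preserved,
    100 * s$preservation_rate, 100 * s$ci_lower, 100 * s$ci_upper))
  invisible(x)
}

#' @export
glance.robustness_report <- function(x, ...) x$summary

#' Condition battery for alternative microcircuit wirings
#'
#' Runs the same battery on structural variants reported across anatomy
#' studies: an added PV->VIP projection, an added PV->SST projection (both
#' with magnitude `extra_weight`, since no weight is published for them), or
#' thalamic stimulus input routed to PV as well as E/SST. Weight variants are
#' re-calibrated to the base circuit's baseline before running. A variant
#' with `extra_weight = 0` reproduces the base battery exactly.
#'
#' @param circ A calibrated [circuit()].
#' @param variant One of `"pv_to_vip"`, `"pv_to_sst"`, `"thalamic_to_pv"`.
#' @param extra_weight Magnitude of the added inhibitory projection, pA·s
#'   (default 0.1; set explicitly for any scientific use).
#' @param ... Passed to [run_condition_battery()].
#' @return A `condition_battery` tibble with a `variant` attribute.
#' @export
variant_battery <- function(circ, variant = c("pv_to_vip", "pv_to_sst",
                                              "thalamic_to_pv"),
                            extra_weight = 0.1, ...) {
  stopifnot(inherits(circ, "circuit"))
  if (is.null(circ$baseline)) abort("circuit must be calibrated first")
  variant <- match.arg(variant)
  if (extra_weight < 0) abort("`extra_weight` is a magnitude, must be >= 0")
  vc <- circ
  pv_input <- FALSE
  if (variant == "pv_to_vip") {
    w <- circ$w
    w["V", "P"] <- w["V", "P"] - extra_weight
    vc <- calibrate_background(
      circuit(w, circ$fi, populations = circ$populations,
              tau_r = circ$tau_r),
      circ$baseline)
  } else if (variant == "pv_to_sst") {
    w <- circ$w
    w["S", "P"] <- w["S", "P"] - extra_weight
    vc <- calibrate_background(
      circuit(w, circ$fi, populations = circ$populations,
              tau_r = circ$tau_r),
      circ$baseline)
  } else {
    pv_input <- TRUE
  }
  out <- run_condition_battery(vc, pv_input = pv_input, ...)
  attr(out, "variant") <- variant
  out
}
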