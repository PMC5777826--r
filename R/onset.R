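#' Analytic rate derivatives at the onset of a current step
#'
#' With the circuit resting at a fixed point, a current step \eqn{\delta I}
#' applied at \eqn{t = 0} instantly shifts the membrane potentials by
#' \eqn{\delta I_i / g_{l,i}} while the rates are still at baseline, so
#' \deqn{\dot r_i(0^+) = \big(f_i(V_i + \delta I_i/g_{l,i}) - r_i\big)/\tau_r,}
#' non-zero only for directly stimulated populations (to linear order
#' \eqn{f'_i(V_i)\,\delta I_i/(g_{l,i}\tau_r)}). The curvature follows from
#' differentiating the dynamics once more:
#' \deqn{\ddot r_i(0^+) = \frac{1}{\tau_r}\Big(-\dot r_i(0^+) +
#'   \frac{f'_i(V_i^+)}{g_{l,i}} \sum_j W_{ij}\, \dot r_j(0^+)\Big).}
#' For a step onto VIP only, the sum collapses to the \eqn{W_{iV}} term, so
#' the initial direction of every unstimulated population is set by the sign
#' of its direct connection from VIP: the SST population, inhibited by VIP,
#' always starts downward — in every regime — even when its steady-state
#' response is positive (response reversal). The "initial direction" reported
#' is the sign of the first non-vanishing derivative at \eqn{t = 0^+}.
#'
#' @param circ A calibrated [circuit()].
#' @param rates Pre-onset fixed-point rates, Hz ([steady_state()] if omitted).
#' @param d_i Step currents, pA, one per population.
#' @param i_ext Constant external currents already present before the step.
#' @return A tibble of class `onset_report` with columns `population`,
#'   `dr_dt` (Hz/s), `d2r_dt2` (Hz/s^2) and `direction` (`"up"`, `"down"`,
#'   `"flat"`).
#' @export
onset_derivatives <- function(circ, rates = NULL, d_i, i_ext = 0) {
  stopifnot(inherits(circ, "circuit"))
  n <- length(circ$populations)
  if (length(d_i) != n) abort("`d_i` must have one entry per population")
  i_ext <- .check_iext(circ, i_ext)
  if (is.null(rates)) rates <- steady_state(circ, i_ext = i_ext)
  v0 <- net_input(circ, rates, i_ext)
  if (max(abs(rates - rates_fn(circ, v0))) > 1e-6) {
    abort("`rates` is not a fixed point of the pre-step system")
  }
  gl <- .glv(circ)
  v_plus <- v0 + d_i / gl             # rates unchanged at t = 0+
  dr <- as.numeric(rates_fn(circ, v_plus) - rates) / circ$tau_r
  d2r <- as.numeric(-dr + gains_fn(circ, v_plus) / gl *
                      as.vector(circ$w %*% dr)) / circ$tau_r
  # absolute + relative floors so fixed-point residual noise in
  # unstimulated populations reads as flat, not as a spurious direction
  tol_dr <- max(1e-6, 1e-9 * max(abs(dr)))
  tol_d2r <- max(1e-3, 1e-9 * max(abs(d2r)))
  direction <- dplyr::case_when(
    abs(dr) > tol_dr ~ ifelse(dr > 0, "up", "down"),
    abs(d2r) > tol_d2r ~ ifelse(d2r > 0, "up", "down"),
    TRUE ~ "flat"
  )
  out <- tibble(population = circ$populations, dr_dt = as.numeric(dr),
                d2r_dt2 = as.numeric(d2r), direction = direction)
  structure(out, class = c("onset_report", class(out)),
            step = setNames(as.numeric(d_i), circ$populations))
}

#' Confront the analytic onset derivatives with a fine simulation
#'
#' Integrates the stepped system at a fine time step and differentiates the
#' early trajectory numerically (forward differences at `t = 0`), then
#' compares against [onset_derivatives()]. The full horizon is also summarized
#' per population (baseline, minimum, maximum, final rate, and whether the
#' trajectory dips below baseline before settling above it — the transient
#' signature of response reversal). Excursions smaller than `dip_tol` are
#' ignored as numerical noise.
#'
#' @inheritParams onset_derivatives
#' @param horizon Simulation length, s (default 0.5).
#' @param dt Euler step for the fine run, s (default 1e-5).
#' @param dip_tol Minimum excursion, Hz, for a dip/rise to count (default
#'   1e-3).
#' @return List of class `onset_check`: `derivatives` (tibble: analytic vs
#'   numeric first/second derivatives with relative errors) and `summary`
#'   (tibble per population: `baseline`, `min`, `max`, `final`, `dips_below`,
#'   `settles_above`, `reverses`).
#' @export
verify_onset <- function(circ, rates = NULL, d_i, i_ext = 0, horizon = 0.5,
                         dt = 1e-5, dip_tol = 1e-3) {
  i_ext <- .check_iext(circ, i_ext)
  if (is.null(rates)) rates <- steady_state(circ, i_ext = i_ext)
  rep_ <- onset_derivatives(circ, rates = rates, d_i = d_i, i_ext = i_ext)
  traj <- simulate_circuit(circ, schedule = NULL, i_ext = i_ext + d_i,
                           r0 = as.numeric(rates), t_max = horizon, dt = dt)
  pops <- circ$populations
  rmat <- as.matrix(traj[, paste0("r_", pops)])
  # forward differences on the first frames (first derivative O(dt) like Euler;
  # the second difference at the origin matches the scheme's curvature)
  dr_num <- (rmat[2, ] - rmat[1, ]) / dt
  d2r_num <- (rmat[3, ] - 2 * rmat[2, ] + rmat[1, ]) / dt^2
  deriv <- rep_ |>
    dplyr::mutate(
      dr_dt_sim = as.numeric(dr_num),
      d2r_dt2_sim = as.numeric(d2r_num),
      rel_err_dr = abs(.data$dr_dt_sim - .data$dr_dt) /
        pmax(abs(.data$dr_dt), 1e-9),
      rel_err_d2r = abs(.data$d2r_dt2_sim - .data$d2r_dt2) /
        pmax(abs(.data$d2r_dt2), 1e-9))
  base <- as.numeric(rates)
  summary <- tibble(
    population = pops,
    baseline = base,
    min = apply(rmat, 2, min),
    max = apply(rmat, 2, max),
    final = rmat[nrow(rmat), ]
  ) |>
    dplyr::mutate(
      dips_below = .data$min < .data$baseline - dip_tol,
      settles_above = .data$final > .data$baseline + dip_tol,
      reverses = .data$dips_below & .data$settles_above)
  list(derivatives = deriv, summary = summary)
}
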