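#' Piecewise-constant external input schedule
#'
#' External currents are specified as non-overlapping time segments, each with
#' one current value (pA) per population; outside all segments the external
#' input is zero. `step_input()` is the common special case of a constant step
#' switched on at `t_on` (e.g. the 10 pA top-down modulatory current onto VIP
#' cells that models locomotion).
#'
#' @param segments A data frame with columns `t_start`, `t_end` (s) and one
#'   column per population current, named `I_<pop>` (pA).
#' @return An object of class `input_schedule` (a tibble).
#' @examples
#' step_input(c(0, 0, 0, 10), t_on = 0.1)
#' @export
input_schedule <- function(segments) {
  segments <- as_tibble(segments)
  if (!all(c("t_start", "t_end") %in% names(segments))) {
    abort("`segments` needs `t_start` and `t_end` columns")
  }
  if (any(segments$t_start < 0) || any(segments$t_end <= segments$t_start)) {
    abort("segments must have 0 <= t_start < t_end")
  }
  seg <- segments[order(segments$t_start), ]
  if (nrow(seg) > 1 &&
      any(seg$t_start[-1] < seg$t_end[-nrow(seg)] - 1e-12)) {
    abort("segments must not overlap")
  }
  structure(seg, class = c("input_schedule", class(seg)))
}

#' @rdname input_schedule
#' @param currents Step currents, pA, one per population.
#' @param t_on,t_off Step onset/offset times, s (`t_off = Inf` keeps the step
#'   on for the whole run).
#' @param populations Population labels used to name the current columns.
#' @export
step_input <- function(currents, t_on = 0, t_off = Inf,
                       populations = c("E", "P", "S", "V")) {
  stopifnot(length(currents) == length(populations))
  seg <- tibble(t_start = t_on, t_end = t_off)
  seg[paste0("I_", populations)] <- as.list(as.numeric(currents))
  input_schedule(seg)
}

schedule_currents <- function(schedule, t, populations) {
  n <- length(populations)
  if (is.null(schedule)) return(rep(0, n))
  hit <- which(t >= schedule$t_start & t < schedule$t_end)
  if (length(hit) == 0) return(rep(0, n))
  cols <- paste0("I_", populations)
  missing <- setdiff(cols, names(schedule))
  if (length(missing) > 0) {
    abort(paste0("schedule lacks column(s): ", paste(missing, collapse = ", ")))
  }
  as.numeric(schedule[hit[1], cols])
}

#' Integrate the rate dynamics
#'
#' Explicit-Euler integration of \eqn{\tau_r \dot r_i = -r_i + f_i(V_i)} from
#' `r0` over `[0, t_max]`. The default step (0.1 ms, i.e. \eqn{\tau_r/20}) is
#' well inside the stability region of the scheme; halving it moves the final
#' state of the reference circuits by far less than 1e-4 Hz. Divergence (any
#' non-finite rate) aborts with the time of blow-up rather than returning
#' garbage.
#'
#' @param circ A calibrated [circuit()].
#' @param schedule An [input_schedule()], or `NULL` for no time-varying input.
#' @param i_ext Additional constant external current, pA (added to the
#'   schedule; default 0).
#' @param r0 Initial rates, Hz (default: the calibration baseline).
#' @param t_max Duration, s.
#' @param dt Euler step, s; must satisfy `dt <= tau_r / 4`.
#' @param record_every Record one frame every this many steps (default 1;
#'   `Inf` records only the first and last frame).
#' @return A tibble of class `rate_trajectory` with columns `time` (s),
#'   `r_<pop>` (Hz) and `v_<pop>` (mV), plus attributes `populations`, `dt`
#'   and `final_rates`.
#' @export
simulate_circuit <- function(circ, schedule = NULL, i_ext = 0, r0 = NULL,
                             t_max = 0.5, dt = 1e-4, record_every = 1) {
  stopifnot(inherits(circ, "circuit"))
  if (t_max <= 0) abort("`t_max` must be positive")
  if (dt > circ$tau_r / 4) abort("`dt` must be <= tau_r / 4")
  pops <- circ$populations
  n <- length(pops)
  i_ext <- .check_iext(circ, i_ext)
  r <- r0 %||% circ$baseline %||% rep(1, n)
  if (length(r) != n) abort("`r0` must have one entry per population")
  n_steps <- ceiling(t_max / dt)
  keep <- if (is.infinite(record_every)) c(0L, n_steps) else
    seq(0L, n_steps, by = as.integer(record_every))
  if (keep[length(keep)] != n_steps) keep <- c(keep, n_steps)
  rates_out <- matrix(NA_real_, length(keep), n)
  v_out <- matrix(NA_real_, length(keep), n)
  row <- 1L
  v <- net_input(circ, r, i_ext + schedule_currents(schedule, 0, pops))
  for (k in 0:n_steps) {
    if (k == keep[row]) {
      rates_out[row, ] <- r
      v_out[row, ] <- v
      row <- row + 1L
    }
    if (k == n_steps) break
    r <- r + dt * (-r + rates_fn(circ, v)) / circ$tau_r
    if (any(!is.finite(r))) {
      abort(sprintf("integration diverged at t = %.6f s", (k + 1) * dt))
    }
    v <- net_input(circ, r,
                   i_ext + schedule_currents(schedule, (k + 1) * dt, pops))
  }
  out <- tibble(time = keep * dt)
  out[paste0("r_", pops)] <- as.data.frame(rates_out)
  out[paste0("v_", pops)] <- as.data.frame(v_out)
  structure(out, class = c("rate_trajectory", class(out)),
            populations = pops, dt = dt,
            final_rates = setNames(r, pops))
}

#' @export
tidy.rate_trajectory <- function(x, ...) {
  pops <- attr(x, "populations")
  dplyr::select(x, "time", dplyr::all_of(paste0("r_", pops))) |>
    tidyr::pivot_longer(-"time", names_to = "population", names_prefix = "r_",
                        values_to = "rate") |>
    dplyr::mutate(population = factor(.data$population, levels = pops))
}

#' Plot a rate trajectory
#'
#' One line per population, rate (Hz) against time (s).
#'
#' @param object A `rate_trajectory` from [simulate_circuit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy.rate_trajectory(object),
                  ggplot2::aes(.data$time, .data$rate,
                               colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "rate (Hz)", colour = NULL) +
    ggplot2::theme_minimal()
}
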