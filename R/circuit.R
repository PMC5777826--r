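#' Four-population microcircuit
#'
#' Bundles an ordered set of populations, one [fi_curve()] per population, a
#' signed connectivity matrix `W` (pA·s; rows are targets, columns sources),
#' optional background currents `i_bkg` (pA) and the rate relaxation time
#' constant `tau_r` (s). The dynamics are
#' \deqn{\tau_r \dot r_i = -r_i + f_i(V_i), \qquad
#'       V_i = V_l + \Big(\sum_j W_{ij} r_j + I_i + I^{bkg}_i\Big)/g_{l,i}.}
#'
#' Sign structure is enforced at construction: columns of inhibitory
#' populations (any label other than `"E"`) must be non-positive and the
#' excitatory column non-negative.
#'
#' @param w Square numeric connectivity matrix, pA·s.
#' @param fi List of [fi_curve()] objects, one per population (recycled if a
#'   single curve is given).
#' @param populations Character labels, default taken from `colnames(w)` or
#'   `c("E", "P", "S", "V")` for a 4x4 matrix.
#' @param i_bkg Optional background currents, pA. Usually set by
#'   [calibrate_background()].
#' @param tau_r Rate time constant, s (default 0.002).
#' @return An object of class `circuit`.
#' @seealso [circuit_generic()], [circuit_v1()], [calibrate_background()],
#'   [steady_state()]
#' @export
circuit <- function(w, fi, populations = NULL, i_bkg = NULL, tau_r = 0.002) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (ncol(w) != n) abort("`w` must be square")
  populations <- populations %||% colnames(w) %||%
    (if (n == 4) c("E", "P", "S", "V") else paste0("pop", seq_len(n)))
  if (length(populations) != n) abort("`populations` must match dim(w)")
  dimnames(w) <- list(populations, populations)
  if (inherits(fi, "fi_curve")) fi <- rep(list(fi), n)
  if (length(fi) != n || !all(vapply(fi, inherits, logical(1), "fi_curve"))) {
    abort("`fi` must be one fi_curve per population")
  }
  names(fi) <- populations
  exc <- populations == "E"
  if (any(w[, exc] < 0)) abort("excitatory column of `w` must be >= 0")
  if (any(w[, !exc] > 0)) abort("inhibitory columns of `w` must be <= 0")
  if (!is.null(i_bkg)) {
    if (length(i_bkg) != n) abort("`i_bkg` must have one entry per population")
    i_bkg <- setNames(as.numeric(i_bkg), populations)
  }
  if (tau_r <= 0) abort("`tau_r` must be positive")
  structure(
    list(populations = populations, fi = fi, w = w, i_bkg = i_bkg,
         tau_r = tau_r),
    class = "circuit"
  )
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("<circuit> %d populations: %s\n", length(x$populations),
              paste(x$populations, collapse = ", ")))
  cat("W (pA s):\n")
  print(round(x$w, 3))
  if (is.null(x$i_bkg)) {
    cat("background currents: not calibrated\n")
  } else {
    cat("background currents (pA):",
        paste(sprintf("%s=%.2f", x$populations, x$i_bkg), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Membrane / f-I parameters of the four populations (E, PV, SST, VIP):
# g_l = 6.25, 10, 5, 5 nS; tau_m = 28, 8, 16, 16 ms.
fi_presets <- function() {
  list(
    E = fi_curve(tau_m = 0.028, g_l = 6.25),
    P = fi_curve(tau_m = 0.008, g_l = 10),
    S = fi_curve(tau_m = 0.016, g_l = 5),
    V = fi_curve(tau_m = 0.016, g_l = 5)
  )
}

#' Reference microcircuits
#'
#' `circuit_generic()` is the canonical E/PV/SST/VIP microcircuit used for the
#' disinhibition vs response-reversal analysis; `circuit_v1()` is the variant
#' connectivity used for the mouse V1 condition battery. Both use the standard
#' per-population membrane parameters (g_l = 6.25, 10, 5, 5 nS; tau_m = 28, 8,
#' 16, 16 ms) and come uncalibrated: pipe into [calibrate_background()] to fix
#' a baseline.
#'
#' @return A [circuit()].
#' @examples
#' circ <- circuit_generic() |> calibrate_background(c(1, 10, 3, 2))
#' steady_state(circ)
#' @export
circuit_generic <- function() {
  w <- matrix(c(
    2.42, -0.33, -0.80,  0,
    2.97, -3.45, -2.13,  0,
    4.64,  0,     0,    -2.79,
    0.71,  0,    -0.16,  0
  ), 4, 4, byrow = TRUE, dimnames = rep(list(c("E", "P", "S", "V")), 2))
  circuit(w, fi_presets())
}

#' @rdname circuit_generic
#' @export
circuit_v1 <- function() {
  w <- matrix(c(
    3.30, -3.48, -2.98,  0,
    1.73, -4.25, -1.07,  0,
    3.50,  0,     0,    -4.51,
    0.53,  0,    -0.13,  0
  ), 4, 4, byrow = TRUE, dimnames = rep(list(c("E", "P", "S", "V")), 2))
  circuit(w, fi_presets())
}

.glv <- function(circ) vapply(circ$fi, `[[`, numeric(1), "g_l")
.vl <- function(circ) vapply(circ$fi, `[[`, numeric(1), "v_l")

.check_iext <- function(circ, i_ext) {
  n <- length(circ$populations)
  if (length(i_ext) == 1) i_ext <- rep(i_ext, n)
  if (length(i_ext) != n) abort("`i_ext` must have one entry per population")
  setNames(as.numeric(i_ext), circ$populations)
}

#' Effective membrane potentials for a given activity
#'
#' Evaluates the input equation
#' \eqn{V_i = V_l + (\sum_j W_{ij} r_j + I_i + I^{bkg}_i)/g_{l,i}}.
#' Units compose as (pA·s)(Hz) = pA and pA/nS = mV, so zero activity with zero
#' currents returns the leak potential exactly.
#'
#' @param circ A [circuit()].
#' @param rates Rates per population, Hz.
#' @param i_ext External currents, pA (scalar or per population; default 0).
#' @return Named vector of membrane potentials, mV.
#' @export
net_input <- function(circ, rates, i_ext = 0) {
  stopifnot(inherits(circ, "circuit"))
  n <- length(circ$populations)
  if (length(rates) != n) abort("`rates` must have one entry per population")
  i_ext <- .check_iext(circ, i_ext)
  i_bkg <- circ$i_bkg %||% rep(0, n)
  v <- .vl(circ) + (as.vector(circ$w %*% rates) + i_ext + i_bkg) / .glv(circ)
  setNames(v, circ$populations)
}

rates_fn <- function(circ, v) {
  vapply(seq_along(v), function(i) fi_rate(v[i], circ$fi[[i]]), numeric(1))
}
gains_fn <- function(circ, v) {
  vapply(seq_along(v), function(i) fi_derivative(v[i], circ$fi[[i]]),
         numeric(1))
}

#' Calibrate background currents to a target baseline
#'
#' The baseline of the circuit is controlled by constant background currents.
#' Because each target rate pins its population's operating potential through
#' the (invertible) f-I curve, the calibration is a direct formula rather than
#' a fit:
#' \deqn{I^{bkg}_i = g_{l,i}(f_i^{-1}(r^t_i) - V_l) - \sum_j W_{ij} r^t_j - I_i.}
#' Plugging the result back, [steady_state()] reproduces the targets. For the
#' canonical microcircuit with targets (1, 10, 3, 2) Hz at zero external input
#' this yields (114.7, 233.6, 94.3, 89.9) pA.
#'
#' @param circ A [circuit()].
#' @param target_rates Desired baseline rates, Hz (all > 0).
#' @param i_ext External currents present during baseline, pA (default 0).
#' @return The circuit with `$i_bkg` set (pipe-friendly) and the calibration
#'   targets recorded in `$baseline`.
#' @export
calibrate_background <- function(circ, target_rates, i_ext = 0) {
  stopifnot(inherits(circ, "circuit"))
  n <- length(circ$populations)
  if (length(target_rates) != n || any(!is.finite(target_rates)) ||
      any(target_rates <= 0)) {
    abort("`target_rates` must be positive and finite, one per population")
  }
  i_ext <- .check_iext(circ, i_ext)
  v <- vapply(seq_len(n),
              function(i) fi_inverse(target_rates[i], circ$fi[[i]]),
              numeric(1))
  i_bkg <- .glv(circ) * (v - .vl(circ)) -
    as.vector(circ$w %*% target_rates) - i_ext
  circ$i_bkg <- setNames(i_bkg, circ$populations)
  circ$baseline <- setNames(as.numeric(target_rates), circ$populations)
  circ
}

#' Steady state of the rate dynamics
#'
#' Solves the fixed-point system \eqn{r_i = f_i(V_i(r))} by damped Newton
#' iteration on \eqn{g(r) = r - f(V(r))}, starting from `r0` (the calibration
#' baseline when available). If Newton stalls, falls back to a long simulated
#' relaxation before a final Newton polish. Convergence is declared at a
#' residual below `tol`.
#'
#' @param circ A calibrated [circuit()].
#' @param i_ext External currents, pA (scalar or vector; default 0).
#' @param r0 Initial rates, Hz. Defaults to the calibration baseline, else
#'   1 Hz per population.
#' @param tol Residual tolerance, Hz (default 1e-10).
#' @param max_iter Newton iteration budget.
#' @return Named rate vector (Hz) with attributes `converged` (logical),
#'   `residual` (Hz) and `v` (operating potentials, mV). Non-convergence is
#'   reported through `converged = FALSE` and a warning, never silently.
#' @export
steady_state <- function(circ, i_ext = 0, r0 = NULL, tol = 1e-10,
                         max_iter = 100) {
  stopifnot(inherits(circ, "circuit"))
  n <- length(circ$populations)
  i_ext <- .check_iext(circ, i_ext)
  r <- r0 %||% circ$baseline %||% rep(1, n)
  if (length(r) != n) abort("`r0` must have one entry per population")
  gl <- .glv(circ)

  resid <- function(r) {
    v <- net_input(circ, r, i_ext)
    list(g = r - rates_fn(circ, v), v = v)
  }
  st <- resid(r)
  for (iter in seq_len(max_iter)) {
    if (max(abs(st$g)) < tol) break
    jac <- diag(n) - (gains_fn(circ, st$v) / gl) * circ$w
    dr <- tryCatch(solve(jac, st$g), error = function(e) st$g)
    step <- 1
    repeat {
      rn <- pmax(r - step * dr, 0)
      stn <- resid(rn)
      if (sum(stn$g^2) < sum(st$g^2) || step < 1e-6) break
      step <- step / 2
    }
    if (step < 1e-6 && sum(stn$g^2) >= sum(st$g^2)) {
      # Newton stalled: relax by simulating the dynamics for a while
      traj <- simulate_circuit(circ, i_ext = i_ext, r0 = r, t_max = 2,
                               dt = circ$tau_r / 10, record_every = Inf)
      r <- attr(traj, "final_rates")
      st <- resid(r)
      next
    }
    r <- rn
    st <- stn
  }
  converged <- max(abs(st$g)) < max(tol, 1e-8)
  if (!converged) {
    warn(sprintf("steady_state did not converge (residual %.3g Hz)",
                 max(abs(st$g))))
  }
  structure(setNames(r, circ$populations), converged = converged,
            residual = max(abs(st$g)), v = st$v)
}

#' Linear stability of a fixed point
#'
#' Linearizes the rate dynamics around a fixed point `rates`:
#' \eqn{J_{ij} = (-\delta_{ij} + f'_i(V_i) W_{ij} / g_{l,i}) / \tau_r}.
#' The point is stable iff every eigenvalue has negative real part. For
#' four-population circuits the determinant of \eqn{D - W} (whose inverse is
#' the response-matrix normalization `C`) is reported alongside: a stable
#' operating point has `det(D - W) > 0`.
#'
#' @param circ A [circuit()].
#' @param rates Fixed-point rates, Hz (residual checked to 1e-6).
#' @param i_ext External currents at the fixed point, pA.
#' @return List with `eigenvalues`, `is_stable`, `jacobian` and `det_dw`.
#' @export
jacobian_stability <- function(circ, rates, i_ext = 0) {
  stopifnot(inherits(circ, "circuit"))
  v <- net_input(circ, rates, i_ext)
  if (max(abs(rates - rates_fn(circ, v))) > 1e-6) {
    abort("`rates` is not a fixed point (residual > 1e-6 Hz)")
  }
  gl <- .glv(circ)
  fp <- gains_fn(circ, v)
  jac <- (-diag(length(rates)) + (fp / gl) * circ$w) / circ$tau_r
  ev <- eigen(jac, only.values = TRUE)$values
  d <- gl / fp
  list(eigenvalues = ev, is_stable = all(Re(ev) < 0), jacobian = jac,
       det_dw = det(diag(d) - circ$w))
}
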