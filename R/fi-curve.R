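#' Population f-I curve
#'
#' Constructs the static nonlinearity mapping the effective membrane potential
#' of a population (mV) to its firing rate (Hz). The curve is a smoothed
#' threshold-linear function,
#' \deqn{f(V) = \frac{V - V_{th}}{\tau_m (V_{th} - V_r)}
#'       \frac{1}{1 - e^{-(V - V_{th})/v}},}
#' which is flat well below threshold, has a removable singularity at
#' \eqn{V = V_{th}} with value \eqn{v / (\tau_m (V_{th} - V_r))}, and tends to
#' a straight line of slope \eqn{1/(\tau_m (V_{th} - V_r))} at high input.
#' The gain therefore grows with input: the same current perturbation moves a
#' population much more when it sits above threshold than below it, which is
#' the nonlinearity behind the baseline-dependent circuit responses this
#' package analyses.
#'
#' @param tau_m Membrane time constant, in seconds (e.g. `0.028` for the
#'   excitatory population).
#' @param g_l Leak conductance, in nS. Not used by the curve itself but by the
#'   input equation \eqn{V = V_l + I/g_l}; stored here so a population is one
#'   object.
#' @param v_th,v_r Threshold and reset potentials, in mV. Defaults -50 and -60.
#' @param v_smooth Smoothness scale \eqn{v} of the exponential, in mV.
#' @param v_l Leak (reversal) potential of the input equation, in mV.
#'
#' @return An object of class `fi_curve`.
#' @examples
#' p <- fi_curve(tau_m = 0.028, g_l = 6.25)
#' fi_rate(c(-60, -50, -40), p)
#' @export
fi_curve <- function(tau_m, g_l, v_th = -50, v_r = -60, v_smooth = 1,
                     v_l = -70) {
  stopifnot(is.numeric(tau_m), is.numeric(g_l))
  if (!all(is.finite(c(tau_m, g_l, v_th, v_r, v_smooth, v_l)))) {
    abort("all f-I parameters must be finite")
  }
  if (v_th <= v_r) abort("`v_th` must exceed `v_r`")
  if (tau_m <= 0 || g_l <= 0 || v_smooth <= 0) {
    abort("`tau_m`, `g_l` and `v_smooth` must be positive")
  }
  structure(
    list(tau_m = tau_m, g_l = g_l, v_th = v_th, v_r = v_r,
         v_smooth = v_smooth, v_l = v_l),
    class = "fi_curve"
  )
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf(
    "<fi_curve> tau_m=%g s, g_l=%g nS, V_th=%g mV, V_r=%g mV, v=%g mV, V_l=%g mV\n",
    x$tau_m, x$g_l, x$v_th, x$v_r, x$v_smooth, x$v_l))
  invisible(x)
}

# s/(1 - exp(-s)) and its derivative, stable across the removable singularity
# at s = 0 and for large |s| (direct evaluation overflows below s ~ -700).
.softplus_ratio <- function(s) {
  out <- numeric(length(s))
  tiny <- abs(s) < 1e-5
  low <- !tiny & s < -33
  mid <- !tiny & !low
  out[tiny] <- 1 + s[tiny] / 2 + s[tiny]^2 / 12
  out[low] <- -s[low] * exp(s[low])
  out[mid] <- s[mid] / (1 - exp(-s[mid]))
  out
}

.softplus_ratio_deriv <- function(s) {
  out <- numeric(length(s))
  tiny <- abs(s) < 1e-5
  low <- !tiny & s < -33
  mid <- !tiny & !low
  out[tiny] <- 1 / 2 + s[tiny] / 6
  out[low] <- -exp(s[low]) * (1 + s[low])
  e <- exp(-s[mid])
  out[mid] <- ((1 - e) - s[mid] * e) / (1 - e)^2
  out
}

#' Evaluate the f-I curve
#'
#' `fi_rate()` returns the firing rate (Hz) at membrane potential `v` (mV);
#' `fi_derivative()` returns the analytic gain \eqn{f'(V)} (Hz/mV). Both are
#' evaluated with series branches around the removable singularity at
#' \eqn{V_{th}} and asymptotic branches deep below threshold, so they are
#' continuous, strictly positive where they must be, and overflow-free.
#'
#' @param v Membrane potential(s), mV. Must be finite.
#' @param p An [fi_curve()].
#' @return Numeric vector of rates (Hz) or gains (Hz/mV), same length as `v`.
#' @examples
#' p <- fi_curve(tau_m = 0.028, g_l = 6.25)
#' fi_rate(-50, p)          # v / (tau_m * (v_th - v_r))
#' fi_derivative(-40, p)    # close to the asymptotic slope 1/(tau_m * 10)
#' @export
fi_rate <- function(v, p) {
  stopifnot(inherits(p, "fi_curve"))
  if (!all(is.finite(v))) abort("`v` must be finite")
  scale <- 1 / (p$tau_m * (p$v_th - p$v_r))
  p$v_smooth * scale * .softplus_ratio((v - p$v_th) / p$v_smooth)
}

#' @rdname fi_rate
#' @export
fi_derivative <- function(v, p) {
  stopifnot(inherits(p, "fi_curve"))
  if (!all(is.finite(v))) abort("`v` must be finite")
  scale <- 1 / (p$tau_m * (p$v_th - p$v_r))
  scale * .softplus_ratio_deriv((v - p$v_th) / p$v_smooth)
}

#' Invert the f-I curve
#'
#' Finds the membrane potential (mV) at which the population fires at rate `r`
#' (Hz). Since the curve is strictly increasing the inverse is unique; it is
#' located by bracketed root finding and polished to machine precision, so the
#' round trip `fi_rate(fi_inverse(r, p), p)` reproduces `r` to a relative
#' error of 1e-10 or better. Used to pin the operating potentials during
#' background-current calibration.
#'
#' @param r Target rate(s), Hz; strictly positive.
#' @inheritParams fi_rate
#' @return Membrane potential(s), mV.
#' @export
fi_inverse <- function(r, p) {
  stopifnot(inherits(p, "fi_curve"))
  if (!all(is.finite(r)) || any(r <= 0)) abort("`r` must be finite and > 0")
  vapply(r, function(ri) {
    # bracket: below threshold rate decays ~exponentially; above, linearly
    slope <- 1 / (p$tau_m * (p$v_th - p$v_r))
    hi <- p$v_th + ri / slope + 5 * p$v_smooth
    lo <- p$v_th - p$v_smooth * (log1p(slope * p$v_smooth / ri) + 50)
    root <- uniroot(function(v) fi_rate(v, p) - ri, c(lo, hi),
                    tol = .Machine$double.eps^0.8)$root
    # one Newton polish
    root - (fi_rate(root, p) - ri) / fi_derivative(root, p)
  }, numeric(1))
}

#' High-input limit of the inverse gain
#'
#' The inverse gain \eqn{d(V) = g_l / f'(V)} (pA·s) of a population diverges
#' far below threshold and decreases monotonically towards a positive constant
#' as input grows. `d_infinity()` returns that limit,
#' \eqn{d_\infty = g_l\,\tau_m\,(V_{th} - V_r)}, i.e. the leak conductance
#' divided by the asymptotic slope of the f-I curve. Whether the recurrent
#' excitatory weight exceeds this floor decides whether the circuit can ever
#' enter the inhibition-stabilized / response-reversal regime.
#'
#' @inheritParams fi_rate
#' @return The limit, pA·s.
#' @examples
#' d_infinity(fi_curve(tau_m = 0.028, g_l = 6.25))  # 1.75 pA s
#' @export
d_infinity <- function(p) {
  stopifnot(inherits(p, "fi_curve"))
  p$g_l * p$tau_m * (p$v_th - p$v_r)
}
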