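#' Acceptance predicates for connectivity sampling
#'
#' Building blocks for [sample_connectivity()]. Each returns a function of a
#' signed weight matrix that evaluates to `TRUE` when the candidate passes.
#'
#' * `accept_always()` accepts every draw.
#' * `accept_regimes()` requires a stable calibrated fixed point at both the
#'   low and the high baseline, a negative \eqn{M_{SV}} (disinhibition) at
#'   low baseline, and a positive \eqn{M_{SV}} (response reversal) at high
#'   baseline — the full phenomenology of the reference circuit.
#'
#' @param low,high Baseline rate targets, Hz.
#' @param fi List of [fi_curve()]s for the candidate circuit (default: the
#'   standard four-population parameters).
#' @return A predicate `function(w) -> logical`.
#' @export
accept_always <- function() function(w) TRUE

#' @rdname accept_always
#' @export
accept_regimes <- function(low = c(1, 10, 3, 2), high = c(30, 50, 30, 20),
                           fi = fi_presets()) {
  function(w) {
    ok <- tryCatch({
      circ <- circuit(w, fi)
      pass <- TRUE
      for (cond in list(list(r = low, sgn = -1), list(r = high, sgn = 1))) {
        cc <- calibrate_background(circ, cond$r)
        st <- jacobian_stability(cc, cond$r)
        if (!st$is_stable) return(FALSE)
        m <- response_matrix(cc, rates = cond$r)
        pass <- pass && (sign(m$m["S", "V"]) == cond$sgn)
      }
      pass
    }, error = function(e) FALSE)
    isTRUE(ok)
  }
}

#' Rejection-sample a connectivity matrix
#'
#' Draws sign-structured random weight matrices (magnitudes log-uniform in
#' `range` on the canonical microcircuit zero pattern) and keeps the first
#' one satisfying the acceptance predicate — typically [accept_regimes()],
#' which demands the full disinhibition/response-reversal phenomenology at
#' the two reference baselines. Fails loudly with attrition statistics when
#' the try budget is exhausted.
#'
#' @param acceptance Predicate on the signed weight matrix (default
#'   [accept_regimes()]).
#' @param seed RNG seed (explicit; sampling must be reproducible).
#' @param max_tries Draw budget (default 5000).
#' @param range Magnitude range, pA·s (default `c(0.1, 5)`).
#' @return List of class `connectivity_sample`: `w` (signed matrix),
#'   `draws` (number of candidates inspected), `accepted` (logical).
#' @export
sample_connectivity <- function(acceptance = accept_regimes(), seed,
                                max_tries = 5000, range = c(0.1, 5)) {
  if (missing(seed)) abort("`seed` must be given explicitly")
  set.seed(seed)
  for (k in seq_len(max_tries)) {
    w <- random_microcircuit_w(range)
    if (isTRUE(acceptance(w))) {
      return(structure(list(w = w, draws = k, accepted = TRUE, seed = seed),
                       class = "connectivity_sample"))
    }
  }
  abort(sprintf(
    "rejection sampling exhausted %d tries without an accepted matrix",
    max_tries),
    class = "ratecircuit_sampling_exhausted")
}

#' @export
print.connectivity_sample <- function(x, ...) {
  cat(sprintf("<connectivity_sample> accepted after %d draw(s), seed %s\n",
              x$draws, format(x$seed)))
  print(round(x$w, 3))
  invisible(x)
}
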