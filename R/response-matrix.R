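#' Steady-state linear response matrix
#'
#' At a stable fixed point, a small constant perturbation of the external
#' currents \eqn{\delta I} shifts the steady rates by
#' \eqn{\delta r = M \delta I} with
#' \deqn{M = (D - W)^{-1}, \qquad D_{ii} = g_{l,i} / f'_i(V_i).}
#' Unlike the connectivity matrix, `M` accumulates every direct and indirect
#' pathway between populations, so its entries can take either sign and flip
#' with the operating point — the mechanism behind the paradoxical sign
#' reversal of the SST response to VIP-targeted input.
#'
#' @param circ A calibrated [circuit()].
#' @param rates Fixed-point rates, Hz. Computed via [steady_state()] when
#'   omitted.
#' @param i_ext External currents at the operating point, pA.
#' @return Object of class `response_matrix`: list with `m` (Hz/pA), diagonal
#'   inverse gains `d` (pA·s), normalization `c_det` (\eqn{1/\det(D-W)}),
#'   operating `rates` and potentials `v`, and `populations`.
#' @seealso [classify_regime()], [response_matrix_symbolic()],
#'   [ei_response_matrix()]
#' @export
response_matrix <- function(circ, rates = NULL, i_ext = 0) {
  stopifnot(inherits(circ, "circuit"))
  if (is.null(rates)) {
    rates <- steady_state(circ, i_ext = i_ext)
    if (!attr(rates, "converged")) abort("no converged operating point")
  }
  v <- net_input(circ, rates, i_ext)
  gl <- .glv(circ)
  d <- gl / gains_fn(circ, v)
  a <- diag(d) - circ$w
  det_a <- det(a)
  if (abs(det_a) < 1e-12 * prod(pmax(abs(d), 1))) {
    abort("critical point: D - W is singular, response diverges")
  }
  m <- solve(a)
  dimnames(m) <- dimnames(circ$w)
  structure(
    list(m = m, d = setNames(d, circ$populations), c_det = 1 / det_a,
         rates = setNames(as.numeric(rates), circ$populations),
         v = setNames(as.numeric(v), circ$populations),
         populations = circ$populations, w = circ$w),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> M = (D - W)^-1 (Hz/pA), operating rates (Hz):",
      paste(sprintf("%s=%.3g", x$populations, x$rates), collapse = ", "), "\n")
  print(round(x$m, 4))
  invisible(x)
}

#' @export
tidy.response_matrix <- function(x, ...) {
  tidyr::expand_grid(target = x$populations, source = x$populations) |>
    dplyr::mutate(
      value = purrr::map2_dbl(.data$target, .data$source,
                              ~ x$m[.x, .y]),
      sign = sign(.data$value))
}

#' @export
glance.response_matrix <- function(x, ...) {
  reg <- tryCatch(
    regime_from_matrix(x),
    error = function(e) tibble(regime = NA_character_, isn = NA)
  )
  tibble(
    c_det = x$c_det,
    m_sv = if (all(c("S", "V") %in% x$populations)) x$m["S", "V"] else NA_real_,
    regime = reg$regime, isn = reg$isn
  )
}

#' Heat-map of a response matrix
#'
#' Tile plot of \eqn{M_{ij}}: the steady-state rate change of the target
#' population (rows) per pA of extra input to the source population (columns).
#'
#' @param object A [response_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_matrix <- function(object, ...) {
  td <- tidy.response_matrix(object) |>
    dplyr::mutate(
      target = factor(.data$target, levels = rev(object$populations)),
      source = factor(.data$source, levels = object$populations))
  ggplot2::ggplot(td, ggplot2::aes(.data$source, .data$target,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "input to", y = "response of", fill = "Hz/pA") +
    ggplot2::theme_minimal()
}

# ---- closed-form entries (printed cofactor table) --------------------------

microcircuit_zero_pattern <- function() {
  matrix(c(
    1, 1, 1, 0,
    1, 1, 1, 0,
    1, 0, 0, 1,
    1, 0, 1, 0
  ), 4, 4, byrow = TRUE, dimnames = rep(list(c("E", "P", "S", "V")), 2))
}

#' Closed-form response matrix for the canonical microcircuit
#'
#' Evaluates the 16 published cofactor formulas for \eqn{M = (D - W)^{-1}} on
#' the canonical four-population zero pattern, in terms of the weight
#' magnitudes \eqn{w = |W|}, the inverse gains `d`, and
#' \eqn{C = 1/\det(D - W)}. The formulas are transcribed verbatim from their
#' printed source; [response_formula_check()] compares them entry-by-entry
#' against the numeric inverse and reports the ones that disagree (three
#' entries -- `M_PP`, `M_VS` and `M_VV` -- carry typesetting errors; the
#' numeric inverse is canonical throughout this package).
#'
#' @param w Signed 4x4 connectivity matrix (pA·s) on the canonical zero
#'   pattern, or a matrix of magnitudes with the same pattern.
#' @param d Positive inverse gains \eqn{d_i = g_{l,i}/f'(V_i)}, length 4.
#' @return 4x4 matrix of closed-form entries (Hz/pA).
#' @export
response_matrix_symbolic <- function(w, d) {
  w <- as.matrix(w)
  if (!identical(dim(w), c(4L, 4L))) abort("`w` must be 4x4")
  if (length(d) != 4 || any(d <= 0)) abort("`d` must be 4 positive values")
  pat <- microcircuit_zero_pattern()
  if (any(w[pat == 0] != 0)) {
    abort("`w` must have the canonical microcircuit zero pattern")
  }
  aw <- abs(w)
  dimnames(aw) <- dimnames(pat)
  cdet <- 1 / det(diag(d) - aw * sign_pattern_canonical())
  wEE <- aw["E", "E"]; wEP <- aw["E", "P"]; wES <- aw["E", "S"]
  wPE <- aw["P", "E"]; wPP <- aw["P", "P"]; wPS <- aw["P", "S"]
  wSE <- aw["S", "E"]; wSV <- aw["S", "V"]
  wVE <- aw["V", "E"]; wVS <- aw["V", "S"]
  dE <- d[1]; dP <- d[2]; dS <- d[3]; dV <- d[4]
  m <- matrix(0, 4, 4, dimnames = dimnames(pat))
  m["E", "E"] <- cdet * (wPP + dP) * (dS * dV - wSV * wVS)
  m["P", "E"] <- cdet * (wPE * (dS * dV - wSV * wVS) -
                           wPS * (wSE * dV - wSV * wVE))
  m["S", "E"] <- cdet * (wPP + dP) * (wSE * dV - wSV * wVE)
  m["V", "E"] <- cdet * (wPP + dP) * (wVE * dS - wSE * wVS)
  m["E", "P"] <- -cdet * wEP * (dS * dV - wSV * wVS)
  m["P", "P"] <- -cdet * ((wEE - dE) * (dS * dV - wSV * wVS) +
                            wES * (wSE * dV - wSV * wVE))
  m["S", "P"] <- -cdet * wEP * (wSE * dV - wSV * wVE)
  m["V", "P"] <- -cdet * wEP * (wVE * dS - wSE * wVS)
  m["E", "S"] <- -cdet * dV * (wES * (wPP + dP) - wEP * wPS)
  m["P", "S"] <- -cdet * dV * (wES * wPE - (wEE - dE) * wPS)
  m["S", "S"] <- -cdet * dV * ((wEE - dE) * (wPP + dP) - wEP * wPE)
  m["V", "S"] <- -cdet * (wVE * (wES * (wPP + dP) - wEP * wPS) +
                            wVS * ((wEE - dE) * (wPP + dP) - wEP * wPE))
  m["E", "V"] <- cdet * wSV * (wES * (wPP + dP) - wEP * wPS)
  m["P", "V"] <- cdet * wSV * (wES * wPE - (wEE - dE) * wPS)
  m["S", "V"] <- cdet * wSV * ((wEE - dE) * (wPP + dP) - wEP * wPE)
  m["V", "V"] <- cdet * (wES * (wES * (wPP + dP) - wEP * wPS) -
                           dS * ((wEE - dE) * (wPP + dP) - wEP * wPE))
  m
}

sign_pattern_canonical <- function() {
  s <- microcircuit_zero_pattern()
  s[, c("P", "S", "V")] <- -s[, c("P", "S", "V")]
  s
}

#' Draw a random sign-respecting microcircuit connectivity
#'
#' Magnitudes log-uniform in `range` on the canonical zero pattern, excitatory
#' column positive, interneuron columns negative. Used by the property checks
#' and by rejection sampling.
#'
#' @param range Magnitude range, pA·s.
#' @return Signed 4x4 matrix.
#' @keywords internal
random_microcircuit_w <- function(range = c(0.1, 5)) {
  pat <- microcircuit_zero_pattern()
  mag <- matrix(exp(runif(16, log(range[1]), log(range[2]))), 4, 4)
  w <- mag * pat * sign_pattern_canonical()
  dimnames(w) <- dimnames(pat)
  w
}

#' Compare the closed-form entries against the numeric inverse
#'
#' Draws random stable parameter sets (sign-respecting magnitudes, positive
#' inverse gains, linearized dynamics stable) and measures, per entry, the
#' worst relative discrepancy between [response_matrix_symbolic()] and the
#' direct inverse of \eqn{D - W}. Entries whose discrepancy exceeds `tol` are
#' flagged as suspected misprints of the published table; the numeric inverse
#' is canonical.
#'
#' @param n_draws Number of random stable draws (default 100).
#' @param range Magnitude range for weights and inverse gains, pA·s.
#' @param tol Relative agreement threshold (default 1e-8).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `target`, `source`, `entry`, `max_rel_err`,
#'   `discrepant`; attribute `n_draws` records the draws actually used.
#' @export
response_formula_check <- function(n_draws = 100, range = c(0.1, 5),
                                   tol = 1e-8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- c("E", "P", "S", "V")
  worst <- matrix(0, 4, 4, dimnames = list(pops, pops))
  got <- 0
  tries <- 0
  while (got < n_draws && tries < 100 * n_draws) {
    tries <- tries + 1
    w <- random_microcircuit_w(range)
    d <- exp(runif(4, log(range[1]), log(range[2])))
    # stability of tau_r * dr/dt = -r + ... linearized: eig(-I + D^-1 W) < 0
    ev <- eigen(-diag(4) + (1 / d) * w, only.values = TRUE)$values
    if (any(Re(ev) >= 0)) next
    got <- got + 1
    m_num <- solve(diag(d) - w)
    m_sym <- response_matrix_symbolic(w, d)
    rel <- abs(m_sym - m_num) / pmax(abs(m_num), 1e-12)
    worst <- pmax(worst, rel)
  }
  if (got < n_draws) {
    warn(sprintf("only %d stable draws obtained (%d tries)", got, tries))
  }
  out <- tidyr::expand_grid(target = pops, source = pops) |>
    dplyr::mutate(
      entry = paste0("M_", .data$target, .data$source),
      max_rel_err = purrr::map2_dbl(.data$target, .data$source,
                                    ~ worst[.x, .y]),
      discrepant = .data$max_rel_err > tol)
  attr(out, "n_draws") <- got
  out
}

#' Classify the operating regime of the microcircuit
#'
#' The sign of \eqn{M_{SV}} (the steady SST response to excitatory input onto
#' VIP) splits the canonical microcircuit into the disinhibition regime
#' (\eqn{M_{SV} < 0}: exciting VIP suppresses SST and releases E and PV) and
#' the response-reversal regime (\eqn{M_{SV} > 0}). The ISN flag records
#' whether recurrent excitation exceeds the inverse E gain at the operating
#' point (\eqn{w_{EE} > d_E}), the inhibition-stabilized condition. The
#' components of the reversal condition, \eqn{(w_{EE} - d_E)(w_{PP} + d_P)}
#' versus \eqn{w_{EP} w_{PE}}, are reported so one can see how far the circuit
#' sits from the sign boundary.
#'
#' @inheritParams response_matrix
#' @return A tibble with one row: `regime`, `isn`, `m_sv`, `w_ee`, `d_e`,
#'   `wee_minus_de`, `wep_wpe`.
#' @export
classify_regime <- function(circ, rates = NULL, i_ext = 0) {
  rm_ <- response_matrix(circ, rates = rates, i_ext = i_ext)
  regime_from_matrix(rm_)
}

regime_from_matrix <- function(rm_) {
  if (!all(c("E", "P", "S", "V") %in% rm_$populations)) {
    abort("regime classification needs populations E, P, S, V")
  }
  m_sv <- rm_$m["S", "V"]
  regime <- if (abs(m_sv) < 1e-12) "indeterminate"
            else if (m_sv < 0) "disinhibition" else "response_reversal"
  w_ee <- abs(rm_$w["E", "E"])
  d_e <- rm_$d[["E"]]
  tibble(
    regime = regime,
    isn = w_ee > d_e,
    m_sv = m_sv,
    w_ee = w_ee,
    d_e = d_e,
    wee_minus_de = w_ee - d_e,
    wep_wpe = abs(rm_$w["E", "P"]) * abs(rm_$w["P", "E"])
  )
}

#' Response matrix of a two-population E-I network
#'
#' For the fully connected excitatory-inhibitory network the inverse is
#' available in closed form:
#' \deqn{M = C \begin{pmatrix} w_{II} + d_I & -w_{EI} \\
#'       w_{IE} & d_E - w_{EE} \end{pmatrix}, \quad
#'       C = \big((d_E - w_{EE})(w_{II} + d_I) + w_{EI} w_{IE}\big)^{-1}.}
#' With `C > 0`, \eqn{M_{EE}} and \eqn{M_{IE}} are always positive and
#' \eqn{M_{EI}} always negative; only \eqn{M_{II}} can change sign, and it
#' does exactly when \eqn{w_{EE} > d_E} — the same condition that defines the
#' inhibition-stabilized regime, which is why in E-I networks the paradoxical
#' inhibitory response and the ISN property are equivalent.
#'
#' @param w_ee,w_ei,w_ie,w_ii Non-negative weight magnitudes, pA·s.
#' @param d_e,d_i Positive inverse gains, pA·s.
#' @return List with `m` (2x2, Hz/pA), `c_det`, and `paradoxical`
#'   (`sign(m["I","I"]) < 0`).
#' @export
ei_response_matrix <- function(w_ee, w_ei, w_ie, w_ii, d_e, d_i) {
  if (any(c(w_ee, w_ei, w_ie, w_ii) < 0)) abort("weights must be >= 0")
  if (d_e <= 0 || d_i <= 0) abort("inverse gains must be > 0")
  c_det <- (d_e - w_ee) * (w_ii + d_i) + w_ei * w_ie
  if (c_det <= 0) abort("unstable/invalid operating point (C <= 0)")
  m <- matrix(c(w_ii + d_i, w_ie, -w_ei, d_e - w_ee), 2, 2,
              dimnames = list(c("E", "I"), c("E", "I"))) / c_det
  list(m = m, c_det = 1 / c_det, paradoxical = m["I", "I"] < 0)
}
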