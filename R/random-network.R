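#' Unit-to-unit connection probabilities of the canonical microcircuit
#'
#' Probability that a unit of the source population (columns) connects onto a
#' unit of the target population (rows). The published table carries a minus
#' sign on the SST<-VIP entry (-0.55), a typographic carry-over of the
#' inhibitory sign of that pathway: probabilities cannot be negative, so the
#' magnitude is used and the sign of the interaction lives in the weight
#' matrix. [sample_unit_network()] surfaces a warning whenever this
#' normalization fires.
#'
#' @param signed If `TRUE`, return the table as printed (with the -0.55);
#'   default `FALSE` returns magnitudes.
#' @return 4x4 matrix of probabilities.
#' @export
connection_probabilities <- function(signed = FALSE) {
  p <- matrix(c(
    0.02, 1,    1,     0,
    0.01, 1,    0.85,  0,
    0.01, 0,    0,    -0.55,
    0.01, 0,    0.5,   0
  ), 4, 4, byrow = TRUE, dimnames = rep(list(c("E", "P", "S", "V")), 2))
  if (!signed) p <- abs(p)
  p
}

#' Expand a population circuit into a random unit network
#'
#' Each population is replicated into `n_units` identical rate units (defaults
#' 800 E, 100 PV, 50 SST, 50 VIP). A connection from unit v (population j) to
#' unit u (population i) exists independently with probability `p[i, j]`; each
#' realized connection carries weight \eqn{W_{ij} / m_{ij}} with
#' \eqn{m_{ij} = p_{ij} N_j} the expected in-degree (within a population,
#' \eqn{p_{ij}(N_j - 1)}, as self-connections are excluded), so the average
#' total input from population j onto a unit of i equals the population
#' weight \eqn{W_{ij}} exactly. Background and external
#' currents are broadcast per population, so heterogeneity across units comes
#' from the sampled adjacency alone.
#'
#' @param circ A calibrated [circuit()].
#' @param p Connection probability matrix (default
#'   [connection_probabilities()]). Negative entries are folded to their
#'   magnitude with a warning.
#' @param n_units Units per population.
#' @param seed RNG seed (required: sampling is reproducible by construction).
#' @param normalize How to scale realized weights: `"expected"` divides by
#'   \eqn{p_{ij} N_j} (default), `"realized"` by each unit's realized
#'   in-degree (units with zero in-degree keep zero input from that source).
#' @return Object of class `unit_network`: `w_units` (dense unit weight
#'   matrix, pA·s), `membership` (factor), `circuit`, `p`, `n_units`, `seed`.
#' @export
sample_unit_network <- function(circ, p = connection_probabilities(),
                                n_units = c(800, 100, 50, 50), seed,
                                normalize = c("expected", "realized")) {
  stopifnot(inherits(circ, "circuit"))
  normalize <- match.arg(normalize)
  pops <- circ$populations
  n_pop <- length(pops)
  p <- as.matrix(p)
  if (!identical(dim(p), dim(circ$w))) abort("`p` must match dim(w)")
  if (any(p < 0)) {
    warn("negative connection probabilities folded to their magnitude ",
         class = "ratecircuit_signed_probability")
    p <- abs(p)
  }
  if (any(p > 1)) abort("connection probabilities must be in [0, 1]")
  if (length(n_units) != n_pop || any(n_units < 1)) {
    abort("`n_units` must have one positive count per population")
  }
  if (missing(seed)) abort("`seed` must be given explicitly")
  set.seed(seed)
  n_tot <- sum(n_units)
  membership <- factor(rep(pops, n_units), levels = pops)
  w_units <- matrix(0, n_tot, n_tot)
  offs <- c(0, cumsum(n_units))
  for (i in seq_len(n_pop)) {
    rows <- (offs[i] + 1):offs[i + 1]
    for (j in seq_len(n_pop)) {
      if (p[i, j] == 0 || circ$w[i, j] == 0) next
      cols <- (offs[j] + 1):offs[j + 1]
      adj <- matrix(rbinom(length(rows) * length(cols), 1, p[i, j]),
                    length(rows), length(cols))
      if (i == j) diag(adj) <- 0
      # expected in-degree; the self pair is never a candidate within a
      # population, so the within-block expectation is p * (N - 1)
      m_ij <- p[i, j] * (n_units[j] - (i == j))
      if (m_ij <= 0) next
      wij <- if (normalize == "expected") {
        adj * (circ$w[i, j] / m_ij)
      } else {
        deg <- rowSums(adj)
        sweep(adj, 1, ifelse(deg > 0, circ$w[i, j] / deg, 0), `*`)
      }
      w_units[rows, cols] <- wij
    }
  }
  structure(
    list(w_units = w_units, membership = membership, circuit = circ,
         p = p, n_units = setNames(as.integer(n_units), pops), seed = seed,
         normalize = normalize),
    class = "unit_network"
  )
}

#' @export
print.unit_network <- function(x, ...) {
  cat(sprintf("<unit_network> %d units (%s), seed %s, %d connections\n",
              length(x$membership),
              paste(x$n_units, collapse = "/"), format(x$seed),
              sum(x$w_units != 0)))
  invisible(x)
}

#' Integrate the unit-level rate dynamics
#'
#' Same dynamics as [simulate_circuit()] but one equation per unit, with the
#' sampled unit weight matrix providing the recurrent input. Background and
#' scheduled currents are identical for all units of a population. Frames are
#' recorded every `record_every` steps to keep trajectories of a thousand
#' units manageable.
#'
#' @param net A [sample_unit_network()] result.
#' @param schedule An [input_schedule()] (population-level currents,
#'   broadcast), or `NULL`.
#' @param i_ext Constant population-level external currents, pA.
#' @param r0 Initial unit rates (default: population baseline broadcast).
#' @param t_max Duration, s.
#' @param dt Euler step, s.
#' @param record_every Recording stride in steps (default 10).
#' @return Object of class `unit_trajectory`: `time` (s), `rates` (frames x
#'   units, Hz), `membership`, `net`.
#' @export
simulate_units <- function(net, schedule = NULL, i_ext = 0, r0 = NULL,
                           t_max = 0.5, dt = 1e-4, record_every = 10) {
  stopifnot(inherits(net, "unit_network"))
  circ <- net$circuit
  if (dt > circ$tau_r / 4) abort("`dt` must be <= tau_r / 4")
  pops <- circ$populations
  idx <- as.integer(net$membership)
  n_tot <- length(idx)
  i_ext <- .check_iext(circ, i_ext)
  i_bkg <- circ$i_bkg %||% rep(0, length(pops))
  gl <- .glv(circ)[idx]
  vl <- .vl(circ)[idx]
  tau_m <- vapply(circ$fi, `[[`, numeric(1), "tau_m")[idx]
  v_th <- vapply(circ$fi, `[[`, numeric(1), "v_th")[idx]
  v_sm <- vapply(circ$fi, `[[`, numeric(1), "v_smooth")[idx]
  v_r <- vapply(circ$fi, `[[`, numeric(1), "v_r")[idx]
  scale <- 1 / (tau_m * (v_th - v_r))
  f_units <- function(v) v_sm * scale * .softplus_ratio((v - v_th) / v_sm)

  r <- r0 %||% (circ$baseline %||% rep(1, length(pops)))[idx]
  if (length(r) != n_tot) abort("`r0` must have one entry per unit")
  n_steps <- ceiling(t_max / dt)
  keep <- seq(0L, n_steps, by = as.integer(record_every))
  if (keep[length(keep)] != n_steps) keep <- c(keep, n_steps)
  out <- matrix(NA_real_, length(keep), n_tot)
  row <- 1L
  for (k in 0:n_steps) {
    if (k == keep[row]) {
      out[row, ] <- r
      row <- row + 1L
    }
    if (k == n_steps) break
    i_t <- i_ext + schedule_currents(schedule, k * dt, pops)
    v <- vl + (as.vector(net$w_units %*% r) + (i_t + i_bkg)[idx]) / gl
    r <- r + dt * (-r + f_units(v)) / circ$tau_r
    if (any(!is.finite(r))) {
      abort(sprintf("unit integration diverged at t = %.6f s", (k + 1) * dt))
    }
  }
  structure(
    list(time = keep * dt, rates = out, membership = net$membership,
         net = net),
    class = "unit_trajectory"
  )
}

#' Per-unit rate modulation between two epochs
#'
#' The rate modulation of a unit is its mean rate in the modulated window
#' minus its mean rate in the baseline window (positive: the unit is more
#' active under top-down modulation). Windows must be stationary: a drift of
#' the population-mean rate larger than `drift_tol` inside either window
#' raises a warning condition (`ratecircuit_nonstationary`).
#'
#' @param traj A [simulate_units()] result.
#' @param baseline_window,modulated_window Length-2 time windows, s.
#' @param drift_tol Allowed within-window drift, Hz (default 1e-3).
#' @return Tibble of class `rate_modulation`: `unit`, `population`, `delta`
#'   (Hz); attribute `population_means` (tibble).
#' @export
rate_modulation <- function(traj, baseline_window, modulated_window,
                            drift_tol = 1e-3) {
  stopifnot(inherits(traj, "unit_trajectory"))
  win_mean <- function(w) {
    sel <- traj$time >= w[1] & traj$time <= w[2]
    if (sum(sel) < 2) abort("window must contain at least two frames")
    first <- which(sel)[1]
    last <- which(sel)[sum(sel)]
    drift <- abs(mean(traj$rates[last, ]) - mean(traj$rates[first, ]))
    if (drift > drift_tol) {
      warn(sprintf("window [%g, %g] s not stationary (drift %.2g Hz)",
                   w[1], w[2], drift),
           class = "ratecircuit_nonstationary")
    }
    colMeans(traj$rates[sel, , drop = FALSE])
  }
  delta <- win_mean(modulated_window) - win_mean(baseline_window)
  out <- tibble(unit = seq_along(delta), population = traj$membership,
                delta = as.numeric(delta))
  means <- out |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mean_delta = mean(.data$delta),
                     sd_delta = stats::sd(.data$delta),
                     n = dplyr::n(), .groups = "drop")
  structure(out, class = c("rate_modulation", class(out)),
            population_means = means)
}

#' Scatter per-unit rate modulations for two conditions
#'
#' Reproduces the unit-level scatter of modulations: each point is one unit,
#' x the modulation under the first condition, y under the second; white
#' diamonds mark population means.
#'
#' @param mod_x,mod_y Two [rate_modulation()] tibbles over the same network
#'   (e.g. low- and high-baseline runs).
#' @param labels Axis labels.
#' @return A ggplot object.
#' @export
plot_rate_modulation <- function(mod_x, mod_y,
                                 labels = c("low baseline Δ (Hz)",
                                            "high baseline Δ (Hz)")) {
  stopifnot(nrow(mod_x) == nrow(mod_y))
  df <- tibble(population = mod_x$population, dx = mod_x$delta,
               dy = mod_y$delta)
  means <- df |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(dx = mean(.data$dx), dy = mean(.data$dy),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$dx, .data$dy,
                                   colour = .data$population)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = means, shape = 23, fill = "white", size = 3) +
    ggplot2::labs(x = labels[1], y = labels[2], colour = NULL) +
    ggplot2::theme_minimal()
}
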