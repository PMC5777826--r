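test_that("deterministic blocks deliver the population weight exactly", {
  circ <- circ_low()
  suppressWarnings(
    net <- sample_unit_network(circ, n_units = c(40, 10, 8, 6), seed = 1))
  # E <- PV block has p = 1: every E unit receives all 10 PV units at W/10
  e_rows <- which(net$membership == "E")
  p_cols <- which(net$membership == "P")
  block <- net$w_units[e_rows, p_cols]
  expect_true(all(block == circ$w["E", "P"] / 10))
  expect_equal(unname(rowSums(block)), rep(circ$w["E", "P"], 40))
  # zero-probability pairs never connect
  v_cols <- which(net$membership == "V")
  expect_true(all(net$w_units[e_rows, v_cols] == 0))
})

test_that("sampling is reproducible under a fixed seed", {
  circ <- circ_low()
  suppressWarnings(a <- sample_unit_network(circ, seed = 42,
                                            n_units = c(50, 20, 10, 10)))
  suppressWarnings(b <- sample_unit_network(circ, seed = 42,
                                            n_units = c(50, 20, 10, 10)))
  expect_identical(a$w_units, b$w_units)
  suppressWarnings(c_ <- sample_unit_network(circ, seed = 43,
                                             n_units = c(50, 20, 10, 10)))
  expect_false(identical(a$w_units, c_$w_units))
})

test_that("the signed probability table is folded with a warning", {
  expect_warning(
    sample_unit_network(circ_low(), p = connection_probabilities(signed = TRUE),
                        n_units = c(20, 10, 5, 5), seed = 1),
    class = "ratecircuit_signed_probability")
  expect_error(
    suppressWarnings(sample_unit_network(
      circ_low(), p = matrix(2, 4, 4), n_units = c(20, 10, 5, 5), seed = 1)))
})

test_that("realized in-degrees match the Bernoulli expectation", {
  circ <- circ_low()
  degs <- numeric(0)
  for (s in 1:5) {
    suppressWarnings(net <- sample_unit_network(circ, seed = s))
    p_rows <- which(net$membership == "P")
    e_cols <- which(net$membership == "E")
    degs <- c(degs, rowSums(net$w_units[p_rows, e_cols] != 0))
  }
  # PV <- E: p = 0.01, N_E = 800, so mean in-degree 8
  m <- 0.01 * 800
  expect_lt(abs(mean(degs) - m),
            3 * sqrt(m * 0.99 / length(degs)))
})

test_that("an all-to-all network reproduces the population model exactly", {
  circ <- circ_low()
  p1 <- (circ$w != 0) * 1  # p = 1 wherever a pathway exists
  net <- sample_unit_network(circ, p = p1, n_units = c(12, 6, 5, 4), seed = 9)
  sched <- step_input(c(0, 0, 0, 10), t_on = 0.05)
  utraj <- simulate_units(net, schedule = sched, t_max = 0.12, dt = 1e-4,
                          record_every = 50)
  ptraj <- simulate_circuit(circ, schedule = sched, t_max = 0.12, dt = 1e-4,
                            record_every = 50)
  pops <- circ$populations
  for (k in seq_along(pops)) {
    cols <- which(net$membership == pops[k])
    expect_lt(max(abs(utraj$rates[, cols] -
                        as.matrix(ptraj[, paste0("r_", pops[k])])[, 1])),
              1e-10)
  }
})

test_that("rate modulations recover the disinhibition pattern at small size", {
  circ <- circ_low()
  suppressWarnings(
    net <- sample_unit_network(circ, n_units = c(200, 25, 13, 13), seed = 3))
  traj <- simulate_units(net, schedule = step_input(c(0, 0, 0, 10), t_on = 0.25),
                         t_max = 0.5, dt = 2e-4)
  mods <- rate_modulation(traj, baseline_window = c(0.15, 0.25),
                          modulated_window = c(0.4, 0.5))
  pm <- attr(mods, "population_means")
  d_pop <- steady_state(circ, i_ext = c(0, 0, 0, 10)) - steady_state(circ)
  expect_lt(pm$mean_delta[pm$population == "S"], 0)
  expect_true(all(pm$mean_delta[pm$population != "S"] > 0))
  # small networks already track the population model reasonably
  expect_lt(max(abs(pm$mean_delta - as.numeric(d_pop))), 0.35)
})

test_that("high-baseline units disagree in sign within a population", {
  circ <- circ_high()
  suppressWarnings(
    net <- sample_unit_network(circ, n_units = c(200, 25, 13, 13), seed = 5))
  traj <- simulate_units(net, schedule = step_input(c(0, 0, 0, 10), t_on = 0.25),
                         t_max = 0.5, dt = 2e-4)
  mods <- rate_modulation(traj, baseline_window = c(0.15, 0.25),
                          modulated_window = c(0.4, 0.5))
  mixed <- dplyr::summarise(
    dplyr::group_by(mods, population),
    mixed = any(delta > 0) && any(delta < 0))
  expect_true(any(mixed$mixed))
})

test_that("rate modulation is null without modulation and warns off-equilibrium", {
  circ <- circ_low()
  suppressWarnings(
    net <- sample_unit_network(circ, n_units = c(60, 15, 8, 8), seed = 2))
  traj <- simulate_units(net, t_max = 0.3, dt = 2e-4)
  mods <- rate_modulation(traj, baseline_window = c(0.1, 0.2),
                          modulated_window = c(0.2, 0.3))
  expect_lt(max(abs(mods$delta)), 1e-6)
  # a window straddling the initial relaxation is flagged as non-stationary
  expect_warning(
    rate_modulation(traj, baseline_window = c(0, 0.02),
                    modulated_window = c(0.2, 0.3)),
    class = "ratecircuit_nonstationary")
})
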