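test_that("stimulus currents match their sigmoid size dependence", {
  # sigmoid midpoint and saturation of the grating drive
  expect_equal(stimulus_current("grating", theta = 0)[["E"]], 55)
  i6 <- stimulus_current("grating", theta = 6)
  expect_equal(i6[["E"]], 100 / (1 + exp(-3)) + 5, tolerance = 1e-12)
  expect_equal(i6[["S"]], 20 / (1 + exp(-1)) + 5, tolerance = 1e-12)
  big <- stimulus_current("grating", theta = 1e4)
  expect_equal(big[["E"]], 105, tolerance = 1e-9)
  expect_equal(big[["S"]], 25, tolerance = 1e-9)
  # fixed conditions
  expect_equal(unname(stimulus_current("darkness")), rep(0, 4))
  expect_equal(unname(stimulus_current("gray")), c(50, 0, 0, 0))
  # thalamic-input-to-PV variant
  expect_equal(stimulus_current("gray", pv_input = TRUE)[["P"]], 10)
  expect_equal(stimulus_current("darkness", pv_input = TRUE)[["P"]], 0)
  expect_equal(stimulus_current("grating", theta = 1e4,
                                pv_input = TRUE)[["P"]], 25, tolerance = 1e-9)
  expect_error(stimulus_current("grating", theta = -1))
  expect_error(stimulus_current("grating"))
})

test_that("grating currents grow with diameter and saturate center-first", {
  thetas <- c(2, 6, 10, 20, 40, 60)
  ie <- vapply(thetas, function(t) stimulus_current("grating", t)[["E"]],
               numeric(1))
  is_ <- vapply(thetas, function(t) stimulus_current("grating", t)[["S"]],
                numeric(1))
  expect_true(all(diff(ie) > 0))
  expect_true(all(diff(is_) > 0))
  # E (center) input is saturated by ~20 deg; SST (surround) is not
  expect_gt(ie[thetas == 20] / 105, 0.999)
  expect_lt(is_[thetas == 20] / 25, 0.98)
  expect_gt(is_[thetas == 60] / 25, 0.999)
})

test_that("locomotion raises all populations except SST in darkness", {
  v1 <- calibrate_background(circuit_v1(), low_targets)
  bat <- run_condition_battery(v1)
  expect_true(all(bat$converged))
  expect_true(all(bat$stable))
  get <- function(cond, state, pop) {
    bat[[paste0("r_", pop)]][grepl(cond, bat$condition) & bat$state == state]
  }
  # darkness: SST suppressed by locomotion, E/PV/VIP enhanced
  expect_lt(get("darkness", "locomotion", "S"),
            get("darkness", "immobility", "S"))
  for (pop in c("E", "P", "V")) {
    expect_gt(get("darkness", "locomotion", pop),
              get("darkness", "immobility", pop))
  }
  # gray screen and grating: everything, including SST, goes up
  for (cond in c("gray", "grating")) {
    for (pop in c("E", "P", "S", "V")) {
      expect_gt(get(cond, "locomotion", pop), get(cond, "immobility", pop))
    }
  }
  expect_true(ratecircuit:::battery_pattern_ok(bat))
  # deterministic on a fixed configuration
  expect_equal(as.data.frame(run_condition_battery(v1)), as.data.frame(bat))
})

test_that("a weak grating reverses the SST immobility/locomotion ordering", {
  v1 <- calibrate_background(circuit_v1(), low_targets)
  bat <- run_condition_battery(v1, grating_theta = 6)
  sst <- function(cond, state) {
    bat$r_S[grepl(cond, bat$condition) & bat$state == state]
  }
  # before stimulation SST is higher when immobile...
  expect_gt(sst("darkness", "immobility"), sst("darkness", "locomotion"))
  # ...but during the stimulus the order flips
  expect_gt(sst("grating", "locomotion"), sst("grating", "immobility"))
})

test_that("the excitatory rate is size-tuned with surround suppression", {
  v1 <- calibrate_background(circuit_v1(), low_targets)
  st <- size_tuning(v1)
  expect_true(attr(st, "e_nonmonotone"))
  peak <- which.max(st$r_E)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(st))
  expect_error(size_tuning(v1, thetas = c(10, 5)))
})

test_that("steady-state reversal diagnostics agree with the battery", {
  # cross-module coherence: the sign of M_SV at the stimulated operating
  # point predicts the sign of the locomotion effect on SST
  v1 <- calibrate_background(circuit_v1(), low_targets)
  bat <- run_condition_battery(v1)
  for (cond in c("darkness", "gray")) {
    i_stim <- stimulus_current(if (cond == "darkness") "darkness" else "gray")
    rates <- steady_state(v1, i_ext = i_stim)
    m <- response_matrix(v1, rates = as.numeric(rates), i_ext = i_stim)
    d_sst <- bat$r_S[grepl(cond, bat$condition) & bat$state == "locomotion"] -
      bat$r_S[grepl(cond, bat$condition) & bat$state == "immobility"]
    expect_identical(sign(m$m["S", "V"]), sign(d_sst))
  }
})

test_that("zero-width perturbations preserve the pattern trivially", {
  v1 <- calibrate_background(circuit_v1(), low_targets)
  rob <- perturb_connectivity(v1, fraction = 0, n_draws = 3, seed = 1)
  expect_equal(rob$summary$preservation_rate, 1)
  expect_equal(rob$summary$n_stable, 3)
  expect_error(perturb_connectivity(v1, fraction = 1.5, n_draws = 1,
                                    seed = 1))
})

test_that("moderate connectivity jitter usually preserves the pattern", {
  v1 <- calibrate_background(circuit_v1(), low_targets)
  rob <- perturb_connectivity(v1, fraction = 0.10, n_draws = 20, seed = 2)
  expect_gt(rob$summary$preservation_rate, 0.5)
  expect_s3_class(glance(rob), "tbl_df")
})

test_that("wiring variants reduce to the base battery at zero extra weight", {
  plain <- function(x) {
    df <- as.data.frame(x)
    attributes(df) <- attributes(df)[c("names", "row.names", "class")]
    rownames(df) <- NULL
    df
  }
  v1 <- calibrate_background(circuit_v1(), low_targets)
  base <- run_condition_battery(v1)
  for (variant in c("pv_to_vip", "pv_to_sst")) {
    vb <- variant_battery(v1, variant, extra_weight = 0)
    expect_equal(plain(vb), plain(base), tolerance = 1e-8)
    vb2 <- variant_battery(v1, variant, extra_weight = 0.1)
    expect_false(isTRUE(all.equal(plain(vb2), plain(base))))
  }
  tb <- variant_battery(v1, "thalamic_to_pv")
  expect_true(all(tb$converged))
  # darkness rows are untouched by the PV drive (I_P = 0 there)
  expect_equal(
    plain(tb[grepl("darkness", tb$condition), ]),
    plain(base[grepl("darkness", base$condition), ]),
    tolerance = 1e-8)
})
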