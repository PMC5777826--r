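#' Read and write circuit definition files
#'
#' Circuits are stored as YAML with keys `populations`, `w` (row-major list
#' of rows, pA·s; rows = targets), `fi` (per population: `tau_m` s, `g_l` nS
#' and optionally `v_th`, `v_r`, `v_smooth`, `v_l`, mV), and optionally
#' `baseline_rates` (Hz), `i_bkg` (pA) and `tau_r` (s). The reader validates
#' the class sign structure (excitatory column non-negative, interneuron
#' columns non-positive); if `baseline_rates` is present and `i_bkg` is not,
#' the circuit is calibrated on load. Packaged definitions of the generic and
#' V1 reference circuits live under `inst/extdata/`.
#'
#' @param path File path.
#' @return [read_circuit()]: a [circuit()]. [write_circuit()]: `path`,
#'   invisibly.
#' @examples
#' path <- system.file("extdata", "circuit-generic.yml",
#'                     package = "ratecircuit")
#' read_circuit(path)
#' @export
read_circuit <- function(path) {
  if (!file.exists(path)) abort(sprintf("circuit file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (key in c("populations", "w", "fi")) {
    if (is.null(cfg[[key]])) abort(sprintf("circuit file lacks key `%s`", key))
  }
  pops <- as.character(cfg$populations)
  w <- do.call(rbind, lapply(cfg$w, as.numeric))
  fi <- lapply(pops, function(pn) {
    f <- cfg$fi[[pn]]
    if (is.null(f)) abort(sprintf("no f-I parameters for population %s", pn))
    do.call(fi_curve, c(list(tau_m = f$tau_m, g_l = f$g_l),
                        f[intersect(names(f),
                                    c("v_th", "v_r", "v_smooth", "v_l"))]))
  })
  circ <- circuit(w, fi, populations = pops,
                  i_bkg = cfg$i_bkg, tau_r = cfg$tau_r %||% 0.002)
  if (!is.null(cfg$baseline_rates)) {
    if (is.null(cfg$i_bkg)) {
      circ <- calibrate_background(circ, as.numeric(cfg$baseline_rates))
    } else {
      circ$baseline <- setNames(as.numeric(cfg$baseline_rates), pops)
    }
  }
  circ
}

#' @rdname read_circuit
#' @param circ A [circuit()].
#' @export
write_circuit <- function(circ, path) {
  stopifnot(inherits(circ, "circuit"))
  cfg <- list(
    version = 1L,
    populations = circ$populations,
    w = apply(unname(circ$w), 1, as.numeric, simplify = FALSE),
    fi = setNames(lapply(circ$fi, function(f) {
      list(tau_m = f$tau_m, g_l = f$g_l, v_th = f$v_th, v_r = f$v_r,
           v_smooth = f$v_smooth, v_l = f$v_l)
    }), circ$populations),
    tau_r = circ$tau_r
  )
  if (!is.null(circ$baseline)) cfg$baseline_rates <- as.numeric(circ$baseline)
  if (!is.null(circ$i_bkg)) cfg$i_bkg <- as.numeric(circ$i_bkg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns `time_s` then one rate column per population (`r_E`, `r_P`, ...),
#' RFC-4180 CSV.
#'
#' @param traj A [simulate_circuit()] trajectory.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "rate_trajectory"))
  pops <- attr(traj, "populations")
  df <- as.data.frame(traj[, c("time", paste0("r_", pops))])
  names(df)[1] <- "time_s"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a unit network adjacency
#'
#' Sparse coordinate-triplet CSV (`row`, `col`, `weight`; 1-based unit
#' indices) plus a JSON sidecar (`<path>.json`) recording seed, unit counts
#' and connection probabilities.
#'
#' @param net A [sample_unit_network()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_unit_network <- function(net, path) {
  stopifnot(inherits(net, "unit_network"))
  nz <- which(net$w_units != 0, arr.ind = TRUE)
  df <- data.frame(row = nz[, 1], col = nz[, 2],
                   weight = net$w_units[nz])
  df <- df[order(df$row, df$col), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = net$seed, n_units = as.list(net$n_units),
         p = apply(unname(net$p), 1, as.numeric, simplify = FALSE),
         normalize = net$normalize),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resolve_circuit <- function(spec_) {
  if (inherits(spec_, "circuit")) return(spec_)
  if (identical(spec_, "generic")) return(circuit_generic())
  if (identical(spec_, "v1")) return(circuit_v1())
  read_circuit(spec_)
}

#' Run a configured experiment to disk
#'
#' Dispatches one named experiment over the package's functions and writes a
#' deterministic result bundle (CSV/JSON plus a `log.json` echoing the
#' configuration, seed, package version and a content hash of the config).
#' The configuration is a YAML file (or an equivalent list) with keys:
#' `experiment` (one of `calibrate`, `simulate`, `respmat`, `onset`,
#' `random-net`, `v1-battery`, `v1-robustness`, `v1-size-tuning`,
#' `sample-connectivity`), `circuit` (`"generic"`, `"v1"` or a circuit file
#' path), `baseline` (`"low"`, `"high"` or a rate vector), an explicit `seed`
#' where randomness is involved, and experiment-specific `options`. Rerunning
#' the same configuration reproduces the same files; failures exit with an
#' error after removing partial output of the failed step.
#'
#' @param config Path to a YAML config, or a list.
#' @param out_dir Output directory (created; default taken from the config's
#'   `out`, else a tempdir).
#' @return Invisibly, a character vector of the files written.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config))
    }
    yaml::read_yaml(config)
  } else config
  if (is.null(cfg$experiment)) abort("config lacks `experiment`")
  out_dir <- out_dir %||% cfg$out %||% tempfile("ratecircuit-run-")
  opts <- cfg$options %||% list()
  circ <- resolve_circuit(cfg$circuit %||% "generic")
  baseline <- cfg$baseline %||% "low"
  targets <- if (is.numeric(baseline)) baseline
             else if (identical(baseline, "high")) c(30, 50, 30, 20)
             else c(1, 10, 3, 2)
  if (is.null(circ$i_bkg)) circ <- calibrate_background(circ, targets)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, p)
  }

  switch(
    cfg$experiment,
    "calibrate" = {
      emit_csv(tibble(population = circ$populations,
                      i_bkg_pA = as.numeric(circ$i_bkg),
                      target_Hz = as.numeric(circ$baseline)),
               "background-currents.csv")
    },
    "simulate" = {
      step <- as.numeric(opts$step_pa %||% c(0, 0, 0, 10))
      traj <- simulate_circuit(
        circ, schedule = step_input(step, populations = circ$populations),
        t_max = opts$t_max %||% 0.5, dt = opts$dt %||% 1e-4,
        record_every = opts$record_every %||% 10)
      p <- file.path(out_dir, "trajectory.csv")
      write_trajectory(traj, p)
      written <- c(written, p)
    },
    "respmat" = {
      m <- response_matrix(circ)
      emit_csv(cbind(tibble(population = m$populations),
                     as.data.frame(m$m)), "response-matrix.csv")
      emit_json(as.list(classify_regime(circ)), "regime.json")
    },
    "onset" = {
      step <- as.numeric(opts$step_pa %||% c(0, 0, 0, 10))
      rep_ <- onset_derivatives(circ, d_i = step)
      emit_json(purrr::transpose(as.list(rep_)), "onset.json")
    },
    "random-net" = {
      if (is.null(cfg$seed)) abort("random-net experiment needs `seed`")
      net <- sample_unit_network(
        circ, n_units = as.numeric(opts$n_units %||% c(800, 100, 50, 50)),
        seed = cfg$seed)
      epoch <- opts$epoch %||% 0.3
      step <- as.numeric(opts$step_pa %||% c(0, 0, 0, 10))
      traj <- simulate_units(
        net, schedule = step_input(step, t_on = epoch,
                                   populations = circ$populations),
        t_max = 2 * epoch, dt = opts$dt %||% 2e-4)
      mods <- rate_modulation(traj,
                              baseline_window = c(epoch - 0.1, epoch),
                              modulated_window = c(2 * epoch - 0.1, 2 * epoch))
      emit_csv(mods, "rate-modulations.csv")
      emit_csv(attr(mods, "population_means"), "population-means.csv")
    },
    "v1-battery" = {
      bat <- run_condition_battery(
        circ, grating_theta = opts$grating_theta %||% 25,
        pv_input = isTRUE(opts$pv_input))
      emit_csv(bat, "battery.csv")
    },
    "v1-robustness" = {
      if (is.null(cfg$seed)) abort("v1-robustness experiment needs `seed`")
      rob <- perturb_connectivity(
        circ, fraction = opts$fraction %||% 0.10,
        n_draws = opts$n_draws %||% 100, seed = cfg$seed,
        grating_theta = opts$grating_theta %||% 25)
      emit_csv(rob$draws, "robustness-draws.csv")
      emit_json(as.list(rob$summary), "robustness-summary.json")
    },
    "v1-size-tuning" = {
      st <- size_tuning(circ,
                        thetas = as.numeric(opts$thetas %||%
                                              c(2, 6, 10, 20, 40, 60)))
      emit_csv(st, "size-tuning.csv")
      emit_json(list(e_nonmonotone = attr(st, "e_nonmonotone")),
                "size-tuning-summary.json")
    },
    "sample-connectivity" = {
      if (is.null(cfg$seed)) abort("sample-connectivity needs `seed`")
      samp <- sample_connectivity(seed = cfg$seed,
                                  max_tries = opts$max_tries %||% 5000)
      emit_csv(as.data.frame(samp$w), "connectivity.csv")
      emit_json(list(draws = samp$draws, seed = samp$seed),
                "sampling.json")
    },
    abort(sprintf("unknown experiment `%s`", cfg$experiment))
  )
  emit_json(list(config = cfg, config_hash = rlang::hash(cfg),
                 package_version = as.character(utils::packageVersion(
                   "ratecircuit")),
                 r_version = as.character(getRversion())),
            "log.json")
  invisible(written)
}
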