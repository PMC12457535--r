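#' Registry of perturbable physiological parameters
#'
#' The 37 membrane and neuromuscular-junction parameters of the model,
#' one row per parameter: its compartment, a description, the accessor
#' path into the channel or calcium parameter lists, and whether the
#' parameter is flagged as influential on model outputs (16 of 37).
#'
#' @return Data frame with columns `compartment`, `parameter`, `accessor`,
#'   `significant`.
#' @export
param_registry <- function() {
  rows <- list(
    c("dendrite", "Membrane capacitance", "dend.cm", FALSE),
    c("dendrite", "Reversal potential of leak channels", "dend.e_leak", TRUE),
    c("dendrite", "Peak conductance of leak channels", "dend.g_leak", TRUE),
    c("dendrite", "Peak conductance of L-type calcium channels", "dend.g_cal", TRUE),
    c("dendrite", "Reversal potential of calcium channels", "dend.e_ca", FALSE),
    c("dendrite", "Peak conductance of calcium-dependent potassium channels", "dend.g_kca", TRUE),
    c("hillock", "Membrane capacitance", "hillock.cm", FALSE),
    c("hillock", "Reversal potential of leak channels", "hillock.e_leak", FALSE),
    c("hillock", "Reversal potential of potassium channels", "hillock.e_k", FALSE),
    c("hillock", "Reversal potential of sodium channels", "hillock.e_na", FALSE),
    c("hillock", "Peak conductance of leak channels", "hillock.g_leak", FALSE),
    c("hillock", "Peak conductance of potassium delayed rectifier channels", "hillock.g_kdr", FALSE),
    c("hillock", "Peak conductance of persistent sodium channels", "hillock.g_nap", FALSE),
    c("hillock", "Peak conductance of fast sodium channels", "hillock.g_naf", FALSE),
    c("initial_segment", "Membrane capacitance", "initseg.cm", FALSE),
    c("initial_segment", "Reversal potential of leak channels", "initseg.e_leak", FALSE),
    c("initial_segment", "Reversal potential of potassium channels", "initseg.e_k", FALSE),
    c("initial_segment", "Reversal potential of sodium channels", "initseg.e_na", FALSE),
    c("initial_segment", "Peak conductance of leak channels", "initseg.g_leak", TRUE),
    c("initial_segment", "Peak conductance of potassium delayed rectifier channels", "initseg.g_kdr", FALSE),
    c("initial_segment", "Peak conductance of fast sodium channels", "initseg.g_naf", FALSE),
    c("initial_segment", "Peak conductance of persistent sodium channels", "initseg.g_nap", FALSE),
    c("soma", "Membrane capacitance", "soma.cm", FALSE),
    c("soma", "Reversal potential of leak channels", "soma.e_leak", TRUE),
    c("soma", "Reversal potential of potassium channels", "soma.e_k", TRUE),
    c("soma", "Reversal potential of sodium channels", "soma.e_na", TRUE),
    c("soma", "Reversal potential of calcium channels", "soma.e_ca", TRUE),
    c("soma", "Peak conductance of leak channels", "soma.g_leak", TRUE),
    c("soma", "Peak conductance of n-type calcium current", "soma.g_can", FALSE),
    c("soma", "Peak conductance of calcium-dependent potassium channels", "soma.g_kca", TRUE),
    c("soma", "Peak conductance of potassium delayed rectifier channels", "soma.g_kdr", TRUE),
    c("soma", "Peak conductance of fast sodium channels", "soma.g_naf", FALSE),
    c("nmj", "Rate constant determining calcium concentration in the sarcoplasm (k1)", "nmj.k1", FALSE),
    c("nmj", "Release of calcium rate constant (k2)", "nmj.k2", TRUE),
    c("nmj", "Time constant used to determine reuptake", "nmj.tau_reuptake", TRUE),
    c("nmj", "Reuptake of calcium rate constant (k5)", "nmj.k5", TRUE),
    c("nmj", "Reuptake of calcium rate constant (k6)", "nmj.k6", TRUE))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("compartment", "parameter", "accessor", "significant")
  df$significant <- as.logical(df$significant)
  df
}

# Accessor resolution: "nmj.<field>" lives in the calcium parameters, all
# others in the flat channel list.
get_param <- function(channels, ca, accessor) {
  if (startsWith(accessor, "nmj.")) {
    field <- sub("^nmj\\.", "", accessor)
    if (is.null(ca[[field]])) stop("unknown NMJ parameter: ", accessor)
    ca[[field]]
  } else {
    if (is.null(channels[[accessor]])) stop("unknown channel parameter: ", accessor)
    channels[[accessor]]
  }
}

set_param <- function(channels, ca, accessor, value) {
  if (startsWith(accessor, "nmj.")) {
    field <- sub("^nmj\\.", "", accessor)
    if (is.null(ca[[field]])) stop("unknown NMJ parameter: ", accessor)
    ca[[field]] <- value
  } else {
    if (is.null(channels[[accessor]])) stop("unknown channel parameter: ", accessor)
    channels[[accessor]] <- value
  }
  list(channels = channels, ca = ca)
}

#' Sensitivity sweep scenario
#'
#' A frozen 60 %MVC simulation context: pool specification, CSI drive,
#' gain, one realized noise matrix (common random numbers, so every
#' perturbation level sees identical noise), calcium parameters and the
#' plateau analysis window.
#'
#' @param pool A [build_pool()] pool (a reduced pool, e.g. 50 neurons with
#'   scaled fiber fractions, keeps sweeps fast).
#' @param csi A `csi_signal` at 60 %MVC.
#' @param gain_nA Pool gain.
#' @param noise A [noise_model()]; realized once here.
#' @param ca A [calcium_params()] (calibrated).
#' @param plateau `c(t0, t1)` plateau window in seconds.
#' @param dt_ms Integrator step.
#' @param dt_act Activation sample interval.
#' @return An object of class `sweep_scenario`.
#' @export
sweep_scenario <- function(pool, csi, gain_nA, noise, ca,
                           plateau, dt_ms = 0.05, dt_act = 0.001) {
  t_end <- max(csi$t)
  nm <- noise_matrix(noise, nrow(pool), t_end)
  structure(list(pool = pool, csi = csi, gain_nA = gain_nA,
                 noise = nm, noise_dt = 1 / noise$update_hz, ca = ca,
                 plateau = plateau, dt_ms = dt_ms, dt_act = dt_act,
                 t_end = t_end),
            class = "sweep_scenario")
}

# Simulate the scenario with given channel/calcium parameters and return
# the outcome metrics: mean pool discharge rate and mean fiber-type
# activation over the plateau window. Pool spikes can be supplied to skip
# re-integration (NMJ-only perturbations).
scenario_metrics <- function(sc, channels, ca, spikes = NULL) {
  pool <- sc$pool
  attr(pool, "channels") <- channels
  if (is.null(spikes)) {
    spikes <- simulate_pool(pool,
                            pool_input(sc$csi, gain_nA = sc$gain_nA,
                                       noise = sc$noise, noise_dt = sc$noise_dt),
                            dt_ms = sc$dt_ms)
  }
  width <- sc$plateau[2] - sc$plateau[1]
  rates <- vapply(spikes$spikes, function(s)
    sum(s >= sc$plateau[1] & s < sc$plateau[2]) / width, numeric(1))
  act <- spikes_to_activation(spikes, pool, ca, dt = sc$dt_act)
  keep <- act$t >= sc$plateau[1] & act$t < sc$plateau[2]
  a_cols <- grep("^a_", names(act), value = TRUE)
  a_mean <- vapply(a_cols, function(cn) mean(act[[cn]][keep]), numeric(1))
  list(discharge_rate = mean(rates), activation = a_mean, spikes = spikes)
}

#' Run a perturbation sweep over one parameter
#'
#' The parameter is multiplied by `1 + level/100` at each level (reversal
#' potentials included: the perturbation acts on the signed value, so a
#' -70 mV reversal at +20 % becomes -84 mV), the scenario is re-simulated
#' with identical CSI and noise, and percent changes of the plateau
#' discharge rate and fiber-type activations versus baseline are reported.
#' NMJ parameters reuse the baseline pool spikes and only re-run the
#' calcium stage. A failing level is marked failed and the sweep continues.
#'
#' @param accessor Registry accessor (see [param_registry()]).
#' @param scenario A [sweep_scenario()].
#' @param levels Percent offsets (default -20 to +20 in 5 % steps).
#' @return An object of class `sweep_result`: data frame with one row per
#'   level (`level_pct`, `delta_discharge_pct`, `delta_a_I`, `delta_a_IIa`,
#'   `delta_a_IIb`, `failed`).
#' @export
run_sweep <- function(accessor, scenario, levels = seq(-20, 20, by = 5)) {
  sc <- scenario
  base_channels <- attr(sc$pool, "channels")
  base <- scenario_baseline(sc)
  is_nmj <- startsWith(accessor, "nmj.")
  out <- lapply(levels, function(lv) {
    if (lv == 0) {
      return(data.frame(level_pct = 0, delta_discharge_pct = 0,
                        delta_a_I = 0, delta_a_IIa = 0, delta_a_IIb = 0,
                        failed = FALSE))
    }
    val <- get_param(base_channels, sc$ca, accessor)
    pert <- set_param(base_channels, sc$ca, accessor, val * (1 + lv / 100))
    res <- tryCatch(
      scenario_metrics(sc, pert$channels, pert$ca,
                       spikes = if (is_nmj) base$spikes else NULL),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(level_pct = lv, delta_discharge_pct = NA_real_,
                        delta_a_I = NA_real_, delta_a_IIa = NA_real_,
                        delta_a_IIb = NA_real_, failed = TRUE))
    }
    pct <- function(x, x0) if (x0 == 0) NA_real_ else 100 * (x - x0) / x0
    da <- mapply(pct, res$activation, base$activation)
    data.frame(level_pct = lv,
               delta_discharge_pct = pct(res$discharge_rate,
                                         base$discharge_rate),
               delta_a_I = da[["a_I"]], delta_a_IIa = da[["a_IIa"]],
               delta_a_IIb = da[["a_IIb"]], failed = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "accessor") <- accessor
  class(res) <- c("sweep_result", "data.frame")
  res
}

# Baseline metrics of a scenario, cached inside the scenario environment
# across sweeps (common random numbers: identical noise at every level).
scenario_baseline <- function(sc) {
  key <- object_key("baseline", attr(sc$pool, "channels"),
                    sc$pool$diameter_um, unclass(sc$ca), sc$gain_nA,
                    dim(sc$noise), sum(sc$noise), sc$plateau, sc$dt_ms)
  cache_get_or(key, function()
    scenario_metrics(sc, attr(sc$pool, "channels"), sc$ca))
}

#' Tabulate and rank sweep results
#'
#' @param results Named list of [run_sweep()] results (names = accessors).
#' @return List with `long` (one row per level/metric, plot-ready) and
#'   `ranking` (parameters ordered by maximal absolute effect). Failed
#'   levels are carried as missing values, not zeros.
#' @export
sweep_report <- function(results) {
  stopifnot(length(results) >= 1)
  reg <- param_registry()
  long <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    comp <- reg$compartment[match(nm, reg$accessor)]
    do.call(rbind, lapply(c("delta_discharge_pct", "delta_a_I",
                            "delta_a_IIa", "delta_a_IIb"), function(metric)
      data.frame(parameter = nm, compartment = comp,
                 level_pct = r$level_pct,
                 metric = sub("^delta_", "", metric),
                 delta_pct = r[[metric]],
                 failed = r$failed, stringsAsFactors = FALSE)))
  }))
  ranking <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    deltas <- unlist(r[, c("delta_discharge_pct", "delta_a_I",
                           "delta_a_IIa", "delta_a_IIb")])
    data.frame(parameter = nm,
               max_abs_delta_pct = if (all(is.na(deltas))) NA_real_
                                   else max(abs(deltas), na.rm = TRUE),
               n_failed_levels = sum(r$failed),
               stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(-ranking$max_abs_delta_pct), ]
  rownames(ranking) <- NULL
  list(long = long, ranking = ranking)
}

#' Write a sweep report as long-format CSV
#'
#' @param report A [sweep_report()].
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(report, path) {
  write.csv(report$long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
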