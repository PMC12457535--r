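#' Default channel parameters of the reduced motoneuron model
#'
#' Flat named list of the membrane parameters of the four-compartment
#' (lumped dendrite - soma - axon hillock - initial segment) motoneuron.
#' Names follow `compartment.parameter`; conductance densities are in
#' mS/cm2, reversal potentials in mV, capacitances in uF/cm2. Kinetics
#' derive from published mammalian spinal motoneuron models: the delayed
#' rectifier deactivates slowly (an interspike K current), somatic fast Na
#' activates 8 mV above the axonal channels (no subthreshold window), and
#' the Ca-dependent K (AHP) current sets the steady discharge rate. All 32
#' neural entries are individually perturbable (see [param_registry()]).
#'
#' @return Named list of 32 channel parameters.
#' @export
channel_defaults <- function() {
  list(
    # lumped dendrite: passive + L-type Ca (persistent inward current) + Ca-K
    "dend.cm" = 1, "dend.g_leak" = 0.3, "dend.e_leak" = -65,
    "dend.g_cal" = 0.2, "dend.e_ca" = 80, "dend.g_kca" = 0.6,
    # soma: spike currents, N-type Ca and the Ca-dependent K (AHP) current
    "soma.cm" = 1, "soma.g_leak" = 0.5, "soma.e_leak" = -65,
    "soma.e_k" = -80, "soma.e_na" = 55, "soma.e_ca" = 80,
    "soma.g_naf" = 250, "soma.g_kdr" = 20, "soma.g_can" = 4, "soma.g_kca" = 10,
    # axon hillock
    "hillock.cm" = 1, "hillock.g_leak" = 0.5, "hillock.e_leak" = -65,
    "hillock.e_k" = -80, "hillock.e_na" = 55,
    "hillock.g_kdr" = 40, "hillock.g_nap" = 0.15, "hillock.g_naf" = 150,
    # initial segment: spike initiation zone (highest Na density)
    "initseg.cm" = 1, "initseg.g_leak" = 0.5, "initseg.e_leak" = -65,
    "initseg.e_k" = -80, "initseg.e_na" = 55,
    "initseg.g_kdr" = 50, "initseg.g_naf" = 350, "initseg.g_nap" = 0.4)
}

# Geometry and calcium-handling constants (not part of the perturbation
# registry): compartment areas relative to the soma, coupling conductances
# (mS per cm2 of soma area), and the soma/dendrite Ca pool dynamics.
pool_fixed <- function() {
  list(ad_ratio = 12, ah_ratio = 0.08, ai_ratio = 0.12,
       gc_ds = 1.0, gc_sh = 5, gc_hi = 3,
       alpha_ca = 0.025, tau_ca = 60, kd_kca = 5,
       ninf_half = -42, ninf_slope = 15, taun_scale = 8,
       mcan_half = -30, mcan_slope = 5, soma_na_shift = 8)
}

#' Motoneuron pool specification
#'
#' @param n_neurons Pool size.
#' @param d_min,d_max Smallest and largest soma diameter (um); diameters
#'   follow a geometric (exponential) progression between them.
#' @param twitch_ratio Ratio of largest to smallest peak twitch scale
#'   (exponential distribution across the pool).
#' @param rheobase_range Nominal ratio of the largest to smallest rheobase.
#'   Membrane area alone (d^2) gives about 4; the default widens the span
#'   by additionally grading specific excitability with size (smaller
#'   cells have higher specific membrane resistance, as in real
#'   motoneurons whose rheobase range far exceeds their conductance
#'   range). The default nominal value 8 realizes a rheobase span close
#'   to 10 once the calcium-dependent AHP scaling is included.
#' @param fiber_fractions Named fractions of type I, IIa and IIb fibers
#'   (must sum to 1); types are assigned by size, smallest first.
#' @param seed Optional seed recorded for provenance.
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(n_neurons = 200, d_min = 48.8, d_max = 99.7,
                      twitch_ratio = 100, rheobase_range = 8,
                      fiber_fractions = c(I = 0.73, IIa = 0.21, IIb = 0.06),
                      seed = NULL) {
  if (abs(sum(fiber_fractions) - 1) > 1e-8)
    stop("fiber_fractions must sum to 1")
  stopifnot(d_min < d_max, n_neurons >= 1, twitch_ratio > 0,
            rheobase_range > 1)
  structure(list(n_neurons = as.integer(n_neurons), d_min = d_min,
                 d_max = d_max, twitch_ratio = twitch_ratio,
                 rheobase_range = rheobase_range,
                 fiber_fractions = fiber_fractions, seed = seed),
            class = "pool_spec")
}

# Deterministic largest-remainder apportionment of fiber-type counts.
fiber_type_counts <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Build a motoneuron pool
#'
#' Soma diameters follow `d_i = d_min * (d_max/d_min)^((i-1)/(N-1))` and
#' twitch scales `P_i = twitch_ratio^((i-1)/(N-1))`, giving the size
#' principle: membrane area (hence total conductance) grows with `d^2`, so
#' rheobase increases with diameter and small neurons are recruited first
#' under a common drive. Fiber types are assigned by index: the smallest
#' fraction to type I, then IIa, then IIb.
#'
#' @param spec A [pool_spec()].
#' @param channels Channel parameter list, see [channel_defaults()].
#' @return An object of class `motoneuron_pool`: a data frame with one row
#'   per neuron (`index`, `diameter_um`, `twitch_scale`, `fiber_type`) and
#'   the channel/geometry parameters as attributes.
#' @export
build_pool <- function(spec = pool_spec(), channels = channel_defaults()) {
  n <- spec$n_neurons
  idx <- seq_len(n)
  frac <- if (n == 1) 0 else (idx - 1) / (n - 1)
  d <- spec$d_min * (spec$d_max / spec$d_min)^frac
  p <- spec$twitch_ratio^frac
  # conductance densities are additionally graded with size so that the
  # rheobase range (ratio largest/smallest) matches spec$rheobase_range:
  # rheobase ~ exc * d^2, d^2 contributes (d_max/d_min)^2 of the range
  dr <- spec$d_max / spec$d_min
  kappa <- log(spec$rheobase_range / dr^2) / log(dr)
  exc <- (d / spec$d_min)^kappa
  counts <- fiber_type_counts(n, spec$fiber_fractions)
  ft <- rep(names(counts), counts)
  pool <- data.frame(index = idx, diameter_um = d, twitch_scale = p,
                     excitability_scale = exc,
                     fiber_type = factor(ft, levels = names(counts)))
  attr(pool, "channels") <- channels
  attr(pool, "fixed") <- pool_fixed()
  attr(pool, "spec") <- spec
  class(pool) <- c("motoneuron_pool", "data.frame")
  pool
}

#' @export
print.motoneuron_pool <- function(x, ...) {
  counts <- table(x$fiber_type)
  cat(sprintf("Motoneuron pool: %d neurons, soma %.1f-%.1f um, twitch ratio %.0f\n",
              nrow(x), min(x$diameter_um), max(x$diameter_um),
              max(x$twitch_scale) / min(x$twitch_scale)))
  cat("  fiber types:", paste(sprintf("%s=%d", names(counts), counts),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Pool input specification for the integrator
#'
#' @param drive Numeric drive vector in `[0, 1]` (a single value means a
#'   constant drive) or a `csi_signal`.
#' @param drive_dt Sample interval of `drive` in seconds (ignored for a
#'   `csi_signal`, which carries its own grid).
#' @param gain_nA Synaptic gain: input current is `gain_nA * drive`.
#' @param noise Optional noise matrix from [noise_model()] machinery
#'   (update steps x neurons, nA) or a `noise_model` to realize.
#' @param noise_dt Noise update interval in seconds.
#' @return An object of class `pool_input`.
#' @export
pool_input <- function(drive, drive_dt = 0.01, gain_nA = 1,
                       noise = NULL, noise_dt = NULL) {
  if (inherits(drive, "csi_signal")) {
    drive_dt <- drive$t[2] - drive$t[1]
    drive <- drive$drive
  }
  structure(list(drive = as.numeric(drive), drive_dt = drive_dt,
                 gain_nA = gain_nA, noise = noise, noise_dt = noise_dt),
            class = "pool_input")
}

#' Simulate the motoneuron pool
#'
#' Integrates the four-compartment membrane equations of every neuron under
#' the common drive plus per-neuron noise and returns the detected spike
#' trains. Numerical blow-up aborts with the offending neuron and time.
#'
#' @param pool A [build_pool()] object.
#' @param input A [pool_input()].
#' @param dt_ms Macro time step in ms (must be <= 0.1; spike upstrokes are
#'   refined internally).
#' @param t_end Simulation horizon in seconds; defaults to the drive span.
#' @param record_neuron Optional 1-based neuron index whose compartment
#'   voltages are recorded (for diagnostics).
#' @return An object of class `pool_spikes`: list with `spikes` (list of
#'   numeric vectors, seconds), `n_neurons`, `t_end`, `dt_ms` and
#'   optionally `trace`.
#' @export
simulate_pool <- function(pool, input, dt_ms = 0.025, t_end = NULL,
                          record_neuron = 0) {
  stopifnot(inherits(pool, "motoneuron_pool"), inherits(input, "pool_input"))
  if (dt_ms > 0.1) stop("dt_ms must be <= 0.1 ms")
  if (is.null(t_end)) {
    if (length(input$drive) < 2)
      stop("t_end required for constant-drive input")
    t_end <- (length(input$drive) - 1) * input$drive_dt
  }
  noise <- input$noise
  noise_dt <- input$noise_dt
  if (inherits(noise, "noise_model")) {
    noise_dt <- 1 / noise$update_hz
    noise <- noise_matrix(noise, nrow(pool), t_end)
  }
  if (is.null(noise)) {
    noise <- matrix(0, 0, 0)
    noise_dt <- 1
  }
  res <- sim_pool_cpp(attr(pool, "channels"), attr(pool, "fixed"),
                      pool$diameter_um, pool$excitability_scale,
                      input$drive, input$drive_dt * 1000, input$gain_nA,
                      noise, noise_dt * 1000,
                      dt_ms, t_end * 1000,
                      as.integer(record_neuron), 40L)
  structure(list(spikes = res$spikes, n_neurons = nrow(pool),
                 t_end = t_end, dt_ms = dt_ms, trace = res$trace),
            class = "pool_spikes")
}

#' @export
print.pool_spikes <- function(x, ...) {
  n_active <- sum(lengths(x$spikes) > 0)
  cat(sprintf("Pool spikes: %d/%d neurons active, %d spikes over %.2f s\n",
              n_active, x$n_neurons, sum(lengths(x$spikes)), x$t_end))
  invisible(x)
}

# Does a single neuron fire repetitively at constant current I_nA?
# Criterion: at least 2 spikes in the second half of a 2-s simulation.
fires_at <- function(pool1, I_nA, dt_ms = 0.05) {
  sp <- tryCatch(
    simulate_pool(pool1, pool_input(1, gain_nA = I_nA),
                  dt_ms = dt_ms, t_end = 2)$spikes[[1]],
    # divergence far above the operating range counts as suprathreshold
    error = function(e) c(1.5, 1.6))
  sum(sp > 1) >= 2
}

#' Rheobase of one neuron
#'
#' Minimal constant current (nA) sustaining repetitive firing, found by
#' bisection to a relative tolerance.
#'
#' @param pool A pool; `index` selects the neuron.
#' @param index Neuron index.
#' @param lo,hi Initial bracket in nA (expanded upward if needed).
#' @param tol Relative tolerance of the bisection.
#' @return Rheobase current in nA.
#' @export
rheobase <- function(pool, index = nrow(pool), lo = 0.05, hi = 60,
                     tol = 0.01) {
  p1 <- pool[index, , drop = FALSE]
  attr(p1, "channels") <- attr(pool, "channels")
  attr(p1, "fixed") <- attr(pool, "fixed")
  class(p1) <- class(pool)
  while (!fires_at(p1, hi)) {
    hi <- hi * 2
    if (hi > 2000) stop("neuron does not fire at any tested current")
  }
  if (fires_at(p1, lo)) stop("lower bracket already fires; decrease lo")
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (fires_at(p1, mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Calibrate the pool gain
#'
#' Sets the synaptic gain (nA per unit drive) so that the largest neuron is
#' recruited at drive 1, i.e. at the plateau of the 60 %MVC trapezoid the
#' whole pool is just recruited. Deterministic given the pool; results are
#' cached per session.
#'
#' @param pool A [build_pool()] object.
#' @param tol Relative bisection tolerance.
#' @return Gain in nA.
#' @export
calibrate_gain <- function(pool, tol = 0.01) {
  key <- object_key("gain", attr(pool, "channels"), attr(pool, "fixed"),
                    pool$diameter_um[nrow(pool)],
                    pool$excitability_scale[nrow(pool)], tol)
  cache_get_or(key, function() rheobase(pool, nrow(pool), tol = tol))
}

#' Serialize a pool as JSON
#'
#' @param pool A pool object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pool_json <- function(pool, path) {
  x <- list(spec = unclass(attr(pool, "spec")),
            channels = attr(pool, "channels"),
            neurons = lapply(seq_len(nrow(pool)), function(i)
              list(index = pool$index[i], diameter_um = pool$diameter_um[i],
                   twitch_scale = pool$twitch_scale[i],
                   fiber_type = as.character(pool$fiber_type[i]))))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Export simulated pool spikes in the spike-train CSV dialect
#'
#' Simulated trains re-enter the same analysis path as experimental input;
#' a nominal PNR of 40 dB marks them as clean.
#'
#' @param spikes A [simulate_pool()] result.
#' @param path Output CSV path.
#' @param subject_id,trial_id Identifiers written to the file.
#' @param min_spikes Neurons with fewer discharges are omitted (a train
#'   needs at least 2 discharges to define an ISI).
#' @return Invisibly, `path`.
#' @export
write_pool_spikes_csv <- function(spikes, path, subject_id = "SIM",
                                  trial_id = "T1", min_spikes = 2) {
  rows <- list()
  for (i in seq_along(spikes$spikes)) {
    st <- spikes$spikes[[i]]
    if (length(st) < min_spikes) next
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = subject_id, trial_id = trial_id,
      mu_id = sprintf("MN%03d", i),
      discharge_time_s = sprintf("%.6f", st), pnr_db = "40.00",
      stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

# Convert simulated pool spikes to a mu_decomposition (for CST metrics).
pool_spikes_to_decomposition <- function(spikes, subject_id = "SIM",
                                         trial_id = "T1", mvc_level = 60,
                                         min_spikes = 2) {
  mus <- list()
  for (i in seq_along(spikes$spikes)) {
    st <- spikes$spikes[[i]]
    if (length(st) < min_spikes) next
    mus[[length(mus) + 1]] <- mu_spike_train(sprintf("MN%03d", i), st, 40,
                                             subject_id = subject_id,
                                             trial_id = trial_id,
                                             mvc_level = mvc_level)
  }
  if (!length(mus)) stop("no simulated neuron produced >= 2 spikes")
  mu_decomposition(mus, duration = spikes$t_end)
}
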