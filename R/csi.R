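#' Trapezoidal target-force profile
#'
#' Ramp-and-hold isometric target: force rises at `ramp_rate` %MVC/s to
#' `mvc_level`, holds for a level-dependent plateau, and descends
#' symmetrically. Plateau defaults are 30, 30, 20, 15 and 10 s at 5, 10,
#' 20, 40 and 60 %MVC. For simulation efficiency the profile can be
#' compressed in time (`sim_ramp_s`, `sim_plateau_s`); analysis windows are
#' scaled accordingly by the callers.
#'
#' @param mvc_level Target level, percent of MVC.
#' @param mvc_force Subject MVC force in newtons.
#' @param ramp_rate Ramp slope, percent MVC per second.
#' @param plateau_s Plateau duration in seconds; required (with a warning)
#'   for levels outside the standard set.
#' @param sim_ramp_s,sim_plateau_s Compressed durations used when the
#'   trapezoid is materialized with `compressed = TRUE`.
#' @return An object of class `target_profile`.
#' @export
target_profile <- function(mvc_level, mvc_force, ramp_rate = 5,
                           plateau_s = NULL, sim_ramp_s = 2,
                           sim_plateau_s = 3) {
  defaults <- c("5" = 30, "10" = 30, "20" = 20, "40" = 15, "60" = 10)
  key <- as.character(mvc_level)
  if (is.null(plateau_s)) {
    if (!key %in% names(defaults)) {
      warning("no default plateau duration for mvc_level = ", mvc_level,
              "; supply plateau_s explicitly")
      stop("plateau_s required for non-standard MVC level")
    }
    plateau_s <- unname(defaults[key])
  }
  structure(list(mvc_level = mvc_level, mvc_force = mvc_force,
                 ramp_rate = ramp_rate, ramp_s = mvc_level / ramp_rate,
                 plateau_s = plateau_s, sim_ramp_s = sim_ramp_s,
                 sim_plateau_s = sim_plateau_s),
            class = "target_profile")
}

#' Materialize a trapezoid as a sampled series
#'
#' @param profile A [target_profile()].
#' @param dt Sample interval in seconds.
#' @param compressed Use the compressed (simulation) time base?
#' @return Data frame with `t` (s), `pct` (%MVC) and `newtons`; attributes
#'   `ramp_s` and `plateau_s` give the segment durations actually used.
#' @export
make_trapezoid <- function(profile, dt = 0.01, compressed = FALSE) {
  stopifnot(inherits(profile, "target_profile"), dt > 0)
  ramp <- if (compressed) profile$sim_ramp_s else profile$ramp_s
  plat <- if (compressed) profile$sim_plateau_s else profile$plateau_s
  total <- 2 * ramp + plat
  t <- seq(0, total, by = dt)
  pct <- ifelse(t < ramp, profile$mvc_level * t / ramp,
         ifelse(t <= ramp + plat, profile$mvc_level,
                pmax(0, profile$mvc_level * (total - t) / ramp)))
  out <- data.frame(t = t, pct = pct,
                    newtons = pct / 100 * profile$mvc_force)
  attr(out, "ramp_s") <- ramp
  attr(out, "plateau_s") <- plat
  attr(out, "mvc_level") <- profile$mvc_level
  attr(out, "mvc_force") <- profile$mvc_force
  attr(out, "landmarks") <- c(0, ramp, ramp + plat, total)
  out
}

# Plateau time bounds of a materialized trapezoid.
trapezoid_plateau <- function(trap) {
  r <- attr(trap, "ramp_s"); p <- attr(trap, "plateau_s")
  c(r, r + p)
}

#' Common synaptic input (CSI)
#'
#' The shared drive to every motoneuron in the pool, built as a weighted
#' average of the normalized target trapezoid and the normalized smoothed
#' CST discharge rate (weights 0.90 and 0.20). The weights are applied
#' literally (they sum to 1.1) and the result is rescaled to peak 1, so
#' the weights set the relative contribution of each shape only.
#'
#' @param target Data frame with `t` and a shape column (`pct` or `rate` or
#'   `drive`): typically a [make_trapezoid()] result.
#' @param cst_rate Data frame from [smoothed_cst_rate()]; resampled onto
#'   the target grid when the grids differ (with a message).
#' @param w_target,w_cst Weights of the two normalized shapes.
#' @return An object of class `csi_signal`: data frame `t`, `drive` in
#'   `[0, 1]`, with the weights stored as attributes.
#' @export
build_csi <- function(target, cst_rate, w_target = 0.90, w_cst = 0.20) {
  shape_col <- intersect(c("pct", "rate", "drive", "newtons"), names(target))[1]
  if (is.na(shape_col)) stop("target must have a shape column")
  tg <- target[[shape_col]]
  if (max(tg) <= 0) stop("target shape is identically zero")
  cr <- cst_rate$rate
  if (!isTRUE(all.equal(cst_rate$t, target$t))) {
    message("build_csi: resampling CST rate onto the target time grid")
    cr <- approx(cst_rate$t, cst_rate$rate, xout = target$t, rule = 2)$y
  }
  tg_n <- tg / max(tg)
  if (max(cr) <= 0) {
    warning("all-zero CST rate; CSI equals the normalized target")
    drive <- tg_n
  } else {
    cr_n <- cr / max(cr)
    drive <- w_target * tg_n + w_cst * cr_n
    drive <- drive / max(drive)
  }
  out <- data.frame(t = target$t, drive = drive)
  attr(out, "w_target") <- w_target
  attr(out, "w_cst") <- w_cst
  class(out) <- c("csi_signal", "data.frame")
  out
}

#' Independent motoneuron input noise
#'
#' Gaussian noise truncated to `[-bound_nA, +bound_nA]`, regenerated at
#' `update_hz` and held constant between updates (band-limited, like
#' synaptic noise). The default SD is `bound_nA / 3`.
#'
#' @param bound_nA Hard truncation bound in nA.
#' @param sigma_nA Standard deviation before truncation.
#' @param update_hz Regeneration rate in Hz.
#' @param seed Base seed; each neuron gets an independent substream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(bound_nA = 1, sigma_nA = bound_nA / 3,
                        update_hz = 100, seed = 1) {
  stopifnot(bound_nA >= 0, update_hz > 0)
  structure(list(bound_nA = bound_nA, sigma_nA = sigma_nA,
                 update_hz = update_hz, seed = as.integer(seed)),
            class = "noise_model")
}

# Truncated-Gaussian samples for one neuron's substream: inverse-CDF
# sampling restricted to [-bound, bound], exact truncation.
neuron_noise <- function(noise, n, neuron_index) {
  if (noise$bound_nA == 0 || noise$sigma_nA == 0) return(rep(0, n))
  s <- derive_seed(noise$seed, neuron_index)
  with_seed(s, function() {
    plo <- pnorm(-noise$bound_nA / noise$sigma_nA)
    phi <- pnorm(noise$bound_nA / noise$sigma_nA)
    qnorm(runif(n, plo, phi)) * noise$sigma_nA
  })
}

# Noise matrix for the pool integrator: update steps x neurons (nA).
noise_matrix <- function(noise, n_neurons, t_end_s) {
  n_steps <- ceiling(t_end_s * noise$update_hz) + 1
  vapply(seq_len(n_neurons), function(i) neuron_noise(noise, n_steps, i),
         numeric(n_steps))
}

#' Input current for one motoneuron
#'
#' `I_i(t) = gain_nA * drive(t) + eta_i(t)` where `eta_i` is the neuron's
#' truncated-Gaussian noise substream, held between updates. The same seed
#' and neuron index always reproduce the same stream.
#'
#' @param csi A [build_csi()] signal.
#' @param noise A [noise_model()].
#' @param neuron_index 1-based neuron index.
#' @param gain_nA Pool gain calibrated by [calibrate_gain()].
#' @return Data frame with `t` (s) and `current_nA`.
#' @export
neuron_input <- function(csi, noise, neuron_index, gain_nA) {
  t_end <- max(csi$t)
  eta <- neuron_noise(noise, ceiling(t_end * noise$update_hz) + 1, neuron_index)
  idx <- pmin(floor(csi$t * noise$update_hz) + 1L, length(eta))
  data.frame(t = csi$t, current_nA = gain_nA * csi$drive + eta[idx])
}

#' @export
print.csi_signal <- function(x, ...) {
  cat(sprintf("CSI signal: %d samples over %.2f s, weights %.2f/%.2f, peak %.3f\n",
              nrow(x), max(x$t), attr(x, "w_target"), attr(x, "w_cst"),
              max(x$drive)))
  invisible(x)
}
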