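#' Synthetic-subject configuration
#'
#' Parameters of the generator that emulates decomposed HD-EMG output for
#' one subject/trial: a set of recruitment-ordered MUs following the
#' trapezoidal target with linear rate coding, gamma-distributed
#' interspike intervals with a controlled CoV, per-MU PNR values, and a
#' noisy force trace.
#'
#' Default recruitment thresholds are skewed toward low forces
#' (`0.75 * mvc_level * u^1.5` on a uniform index grid), mirroring the
#' dense low-threshold recruitment of human muscles; all MUs are recruited
#' below the target level so every train is active on the plateau.
#'
#' @param n_mus Number of MUs (at least 11).
#' @param mvc_force_N Subject MVC force in newtons. The default (170 N) is
#'   a typical adult isometric dorsiflexion maximum.
#' @param mvc_level Trial target, percent MVC.
#' @param recruitment_thresholds Optional explicit thresholds (%MVC).
#' @param rate_min Discharge rate at recruitment (pulses/s).
#' @param rate_peak Saturation discharge rate (pulses/s).
#' @param rate_gain Rate increase per %MVC above threshold.
#' @param isi_cov_target ISI coefficient of variation, percent.
#' @param pnr_range PNR sampling range, dB.
#' @param force_noise_cov Plateau CoV of the synthetic force trace, percent.
#' @param seed Subject seed.
#' @return An object of class `synth_subject_config`.
#' @export
synth_subject_config <- function(n_mus = 14, mvc_force_N = 170,
                                 mvc_level = 60,
                                 recruitment_thresholds = NULL,
                                 rate_min = 8, rate_peak = 35,
                                 rate_gain = 0.4, isi_cov_target = 20,
                                 pnr_range = c(32, 42),
                                 force_noise_cov = 1.24, seed = 1) {
  if (n_mus < 11) stop("need at least 11 motor units per trial")
  if (is.null(recruitment_thresholds)) {
    u <- (seq_len(n_mus) - 0.5) / n_mus
    recruitment_thresholds <- 0.75 * mvc_level * u^1.5
  }
  if (any(recruitment_thresholds >= mvc_level))
    stop("all recruitment thresholds must lie below the target level")
  stopifnot(rate_min >= 4, rate_peak <= 35, rate_peak > rate_min,
            isi_cov_target >= 0, force_noise_cov >= 0)
  structure(list(n_mus = as.integer(n_mus), mvc_force_N = mvc_force_N,
                 mvc_level = mvc_level,
                 recruitment_thresholds = recruitment_thresholds,
                 rate_min = rate_min, rate_peak = rate_peak,
                 rate_gain = rate_gain, isi_cov_target = isi_cov_target,
                 pnr_range = pnr_range, force_noise_cov = force_noise_cov,
                 seed = as.integer(seed)),
            class = "synth_subject_config")
}

# Instantaneous discharge rate of MU with threshold thr at target pct.
synth_rate <- function(cfg, pct, thr) {
  ifelse(pct >= thr,
         pmin(pmax(cfg$rate_min + cfg$rate_gain * (pct - thr), 4), cfg$rate_peak),
         0)
}

# One gamma-renewal ISI (seconds) at mean 1/rate with the configured CoV,
# redrawn until it falls inside the valid 20-250 ms band so synthetic
# trains pass the default quality filter by construction.
synth_isi <- function(cfg, rate) {
  mean_isi <- 1 / rate
  cov <- cfg$isi_cov_target / 100
  if (cov == 0) return(max(0.020, min(0.250, mean_isi)))
  shape <- 1 / cov^2
  for (i in 1:1000) {
    isi <- stats::rgamma(1, shape = shape, scale = mean_isi / shape)
    if (isi >= 0.020 && isi <= 0.250) return(isi)
  }
  stop("infeasible rate/ISI-CoV combination: no valid ISI in 1000 draws")
}

#' Generate a synthetic MU decomposition
#'
#' Each MU starts firing when the target crosses its recruitment threshold
#' on the up-ramp and derecruits symmetrically on the down-ramp; discharge
#' times follow a gamma renewal process whose instantaneous mean rate
#' tracks the target level (linear rate coding clipped to 4-35 pulses/s).
#'
#' @param cfg A [synth_subject_config()].
#' @param target A materialized trapezoid from [make_trapezoid()].
#' @param subject_id,trial_id Identifiers stamped on the MUs.
#' @return A [mu_decomposition()] that passes the default quality filter
#'   with zero exclusions.
#' @export
synth_decomposition <- function(cfg, target, subject_id = NULL,
                                trial_id = "T1") {
  stopifnot(inherits(cfg, "synth_subject_config"))
  if (is.null(subject_id)) subject_id <- sprintf("SYN%02d", cfg$seed)
  pct_at <- function(t) approx(target$t, target$pct, xout = t, rule = 2)$y
  t_total <- max(target$t)
  mus <- with_seed(derive_seed(cfg$seed, 101), function() {
    pnrs <- runif(cfg$n_mus, cfg$pnr_range[1], cfg$pnr_range[2])
    lapply(seq_len(cfg$n_mus), function(i) {
      thr <- cfg$recruitment_thresholds[i]
      above <- target$pct >= thr
      t_on <- target$t[which(above)[1]]
      t_off <- target$t[tail(which(above), 1)]
      # small start jitter, kept below the threshold spacing so that
      # recruitment order always follows threshold order
      t <- t_on + runif(1) * 0.2 / synth_rate(cfg, pct_at(t_on), thr)
      times <- numeric(0)
      while (t <= t_off && t <= t_total) {
        times <- c(times, t)
        r <- synth_rate(cfg, pct_at(t), thr)
        if (r <= 0) break
        t <- t + synth_isi(cfg, r)
      }
      if (length(times) < 2) return(NULL)
      mu_spike_train(sprintf("MU%02d", i), times, pnrs[i],
                     subject_id = subject_id, trial_id = trial_id,
                     mvc_level = cfg$mvc_level)
    })
  })
  mus <- Filter(Negate(is.null), mus)
  mu_decomposition(mus, duration = t_total)
}

#' Generate a synthetic experimental force trace
#'
#' The target trace in newtons plus band-limited (<= 3 Hz) multiplicative
#' Gaussian noise scaled so the plateau CoV matches `force_noise_cov`
#' within sampling error. Noise scales with the instantaneous force, so
#' ramps fluctuate proportionally less and the rest baseline is silent.
#'
#' @param target A materialized trapezoid (columns `t`, `newtons`).
#' @param force_noise_cov Plateau CoV in percent.
#' @param seed Seed (deterministic trace for a given seed).
#' @return A `force_profile` with attribute `source = "experimental"`.
#' @export
synth_experimental_force <- function(target, force_noise_cov, seed = 1) {
  fs <- 1 / (target$t[2] - target$t[1])
  if (fs <= 6) stop("target must be sampled above 6 Hz for 3-Hz noise")
  n <- nrow(target)
  e <- if (force_noise_cov > 0) {
    with_seed(derive_seed(seed, 202), function() {
      w <- rnorm(n)
      bf <- signal::butter(4, 3 / (fs / 2), type = "low")
      x <- signal::filtfilt(bf, w)
      x / sd_pop(x) * force_noise_cov / 100
    })
  } else rep(0, n)
  out <- data.frame(t = target$t, force = target$newtons * (1 + e))
  class(out) <- c("force_profile", "data.frame")
  attr(out, "source") <- "experimental"
  attr(out, "landmarks") <- attr(target, "landmarks")
  out
}
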