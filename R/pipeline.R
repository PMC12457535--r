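#' Run configuration for the forward pipeline
#'
#' Collects every knob of an end-to-end run. Exactly one input source must
#' be given: file paths (`spike_csv`, optionally `force_csv`) or a
#' synthetic-subject block (`synth`, a list of [synth_subject_config()]
#' arguments).
#'
#' @param subject_id,trial_id Identifiers.
#' @param spike_csv,force_csv Optional input paths.
#' @param synth Optional list of [synth_subject_config()] arguments.
#' @param mvc_level Target level (%MVC).
#' @param mvc_force_N Subject MVC force (N).
#' @param w_target,w_cst CSI weights.
#' @param fir_cutoff CST-rate low-pass cutoff (Hz).
#' @param noise List: `bound_nA`, `sigma_nA`, `update_hz`.
#' @param sim_ramp_s,sim_plateau_s Compressed simulation time base.
#' @param pool List of [pool_spec()] arguments.
#' @param dt_ms Pool integrator step (ms).
#' @param dt_act Activation/force sample interval (s).
#' @param dt_csi CSI sample interval (s).
#' @param seed Global seed; fans out to all stochastic stages.
#' @param out_dir Optional artifact directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(subject_id = "S1", trial_id = "T1",
                       spike_csv = NULL, force_csv = NULL, synth = NULL,
                       mvc_level = 60, mvc_force_N = 170,
                       w_target = 0.90, w_cst = 0.20, fir_cutoff = 2,
                       noise = list(bound_nA = 1, sigma_nA = 1/3,
                                    update_hz = 100),
                       sim_ramp_s = 2, sim_plateau_s = 3,
                       pool = list(n_neurons = 200),
                       dt_ms = 0.025, dt_act = 0.001, dt_csi = 0.01,
                       seed = 1, out_dir = NULL) {
  if (is.null(spike_csv) == is.null(synth))
    stop("config validation: provide exactly one of spike_csv or synth")
  if (!is.null(spike_csv) && !file.exists(spike_csv))
    stop("config validation: spike_csv not found: ", spike_csv)
  if (!is.null(force_csv) && !file.exists(force_csv))
    stop("config validation: force_csv not found: ", force_csv)
  cfg <- structure(list(subject_id = subject_id, trial_id = trial_id,
                        spike_csv = spike_csv, force_csv = force_csv,
                        synth = synth, mvc_level = mvc_level,
                        mvc_force_N = mvc_force_N, w_target = w_target,
                        w_cst = w_cst, fir_cutoff = fir_cutoff,
                        noise = noise, sim_ramp_s = sim_ramp_s,
                        sim_plateau_s = sim_plateau_s, pool = pool,
                        dt_ms = dt_ms, dt_act = dt_act, dt_csi = dt_csi,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "run_config")
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' @param path Config file; keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

# Canonical JSON + md5 of a config for provenance. The artifact directory
# does not affect the science, so it is excluded from the hash.
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

stage_log <- function(stage, seed, t0) {
  message(sprintf("[nmspool] stage=%s seed=%s elapsed=%.2fs",
                  stage, as.character(seed),
                  as.numeric(proc.time()[3]) - t0))
}

#' Run the forward pipeline end to end
#'
#' filter -> CST -> CSI -> motoneuron pool -> calcium activation -> Hill
#' force -> steadiest-window metrics. All stochastic stages derive their
#' seeds from the config seed, so a run is bit-reproducible from its
#' config; with noise disabled it is bit-reproducible by construction.
#'
#' @param cfg A [run_config()].
#' @return An object of class `run_result` with the intermediate artifacts
#'   (decomposition, CSI, pool spikes, activation, force profiles), the
#'   steadiest-window statistics, an [agreement_report()] when a reference
#'   force exists, and provenance (config hash, seeds).
#' @export
run_forward <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- as.numeric(proc.time()[3])
  profile <- target_profile(cfg$mvc_level, cfg$mvc_force_N,
                            sim_ramp_s = cfg$sim_ramp_s,
                            sim_plateau_s = cfg$sim_plateau_s)
  trap <- make_trapezoid(profile, dt = cfg$dt_csi, compressed = TRUE)

  # --- input stage ---
  if (!is.null(cfg$synth)) {
    syn_args <- cfg$synth
    syn_args$mvc_force_N <- cfg$mvc_force_N
    syn_args$mvc_level <- cfg$mvc_level
    if (is.null(syn_args$seed)) syn_args$seed <- cfg$seed
    scfg <- do.call(synth_subject_config, syn_args)
    decomp <- synth_decomposition(scfg, trap, subject_id = cfg$subject_id,
                                  trial_id = cfg$trial_id)
    trap_full <- make_trapezoid(profile, dt = cfg$dt_csi, compressed = FALSE)
    exp_force <- synth_experimental_force(trap_full, scfg$force_noise_cov,
                                          seed = scfg$seed)
  } else {
    decomp <- read_spike_csv(cfg$spike_csv, mvc_level = cfg$mvc_level)
    exp_force <- if (!is.null(cfg$force_csv)) read_force_csv(cfg$force_csv)
                 else NULL
  }
  stage_log("input", cfg$seed, t0)

  # --- spike-train stage ---
  fdecomp <- filter_mus(decomp)
  cst <- build_cst(fdecomp)
  rate <- smoothed_cst_rate(cst, fs_out = 1 / cfg$dt_csi,
                            fir_cutoff = cfg$fir_cutoff,
                            t_end = max(trap$t))
  stage_log("cst", cfg$seed, t0)

  # --- CSI and pool stage ---
  csi <- build_csi(trap, rate, w_target = cfg$w_target, w_cst = cfg$w_cst)
  pool <- build_pool(do.call(pool_spec, cfg$pool))
  gain <- calibrate_gain(pool)
  calib <- calibrate_mvc(hill_params(pool = pool), pool, cfg$mvc_force_N,
                         gain)
  stage_log("calibration", cfg$seed, t0)

  nm <- noise_model(bound_nA = cfg$noise$bound_nA,
                    sigma_nA = cfg$noise$sigma_nA,
                    update_hz = cfg$noise$update_hz,
                    seed = derive_seed(cfg$seed, 303))
  spikes <- simulate_pool(pool, pool_input(csi, gain_nA = gain, noise = nm),
                          dt_ms = cfg$dt_ms)
  stage_log("pool", derive_seed(cfg$seed, 303), t0)

  # --- muscle stage ---
  act <- spikes_to_activation(spikes, pool, calib$ca, dt = cfg$dt_act)
  force <- activation_to_force(act, calib$hill)
  attr(force, "landmarks") <- attr(trap, "landmarks")
  stage_log("muscle", cfg$seed, t0)

  # --- metrics stage ---
  plateau <- trapezoid_plateau(trap)
  window <- steadiest_window(force, 1, plateau = plateau)
  stats <- force_stats(force, window)
  report <- NULL
  if (!is.null(exp_force)) {
    exp_plateau <- if (!is.null(cfg$synth))
      trapezoid_plateau(make_trapezoid(profile, dt = cfg$dt_csi)) else NULL
    report <- agreement_report(force, exp_force, sim_window_s = 1,
                               exp_window_s = 6, sim_plateau = plateau,
                               exp_plateau = exp_plateau)
  }
  stage_log("metrics", cfg$seed, t0)

  res <- structure(
    list(config = cfg, decomposition = fdecomp, cst = cst, csi = csi,
         pool = pool, gain_nA = gain, calibration = calib,
         spikes = spikes, activation = act, force = force,
         exp_force = exp_force, window = window, stats = stats,
         report = report, plateau = plateau,
         provenance = list(config_hash = config_hash(cfg),
                           seed = cfg$seed,
                           package_version = as.character(
                             utils::packageVersion("nmspool")))),
    class = "run_result")
  if (!is.null(cfg$out_dir)) write_run_artifacts(res, cfg$out_dir)
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Forward run %s/%s (seed %d): plateau force %.1f N, STD %.3f N, CoV %.3f%%\n",
              x$config$subject_id, x$config$trial_id, x$config$seed,
              x$stats$mean, x$stats$std, x$stats$cov_pct))
  if (!is.null(x$report))
    cat(sprintf("  vs reference: RMSE %.2f N, R2 %.3f\n",
                x$report$rmse, x$report$r2))
  invisible(x)
}

# Write all artifacts of a run (plain CSV/JSON; deterministic formatting).
write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  write_force_csv(res$force, file.path(out_dir, "simulated_force.csv"))
  if (!is.null(res$exp_force))
    write_force_csv(res$exp_force, file.path(out_dir, "experimental_force.csv"))
  write_pool_spikes_csv(res$spikes, file.path(out_dir, "pool_spikes.csv"),
                        subject_id = cfg$subject_id, trial_id = cfg$trial_id)
  utils::write.csv(data.frame(time_s = sprintf("%.6f", res$csi$t),
                              drive = sprintf("%.8f", res$csi$drive)),
                   file.path(out_dir, "csi.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(jsonlite::toJSON(
    c(list(stats = res$stats[c("std", "cov_pct", "mean")],
           gain_nA = res$gain_nA,
           provenance = res$provenance),
      if (!is.null(res$report)) list(agreement = unclass(res$report))),
    auto_unbox = TRUE, digits = NA, na = "null"),
    file.path(out_dir, "report.json"))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "config.json"))
  invisible(out_dir)
}

#' Validate a simulated force trace against a reference
#'
#' @param sim,exp `force_profile` objects or CSV paths.
#' @param sim_plateau,exp_plateau Optional plateau windows (s).
#' @param multi Optional multi-subject statistics input, see
#'   [agreement_report()].
#' @return An [agreement_report()].
#' @export
run_validation <- function(sim, exp, sim_plateau = NULL, exp_plateau = NULL,
                           multi = NULL) {
  if (is.character(sim)) sim <- read_force_csv(sim, source = "simulated")
  if (is.character(exp)) exp <- read_force_csv(exp, source = "experimental")
  agreement_report(sim, exp, sim_plateau = sim_plateau,
                   exp_plateau = exp_plateau, multi = multi)
}

#' Run a cohort of subjects and pool their statistics
#'
#' Runs the forward pipeline for each config and assembles the
#' across-subject statistics: mean plateau force STD and CoV, per-subject
#' RMSE/R2 against each reference trace, the windowed CST STD variability
#' comparison (z-score median correlation) and the variability t tests.
#'
#' @param cfgs List of [run_config()] objects.
#' @return List of class `cohort_result`: `runs`, `summary` (data frame of
#'   per-subject metrics), and `report` (an [agreement_report()] with the
#'   multi-subject fields populated when references exist).
#' @export
run_cohort <- function(cfgs) {
  runs <- lapply(cfgs, run_forward)
  summary <- do.call(rbind, lapply(runs, function(r)
    data.frame(subject_id = r$config$subject_id, seed = r$config$seed,
               n_mus = r$decomposition$n_mus,
               plateau_mean_N = r$stats$mean, force_std_N = r$stats$std,
               force_cov_pct = r$stats$cov_pct,
               rmse = if (!is.null(r$report)) r$report$rmse else NA_real_,
               r2 = if (!is.null(r$report)) r$report$r2 else NA_real_,
               stringsAsFactors = FALSE)))
  report <- NULL
  if (all(vapply(runs, function(r) !is.null(r$exp_force), logical(1))) &&
      length(runs) >= 3) {
    # per-subject windowed CST STDs on the shared (compressed) clock:
    # simulated pool CST vs the decomposition CST that shaped the CSI
    sim_cst_stds <- lapply(runs, function(r)
      windowed_cst_stds(build_cst(pool_spikes_to_decomposition(r$spikes)),
                        r$plateau))
    exp_cst_stds <- lapply(runs, function(r)
      windowed_cst_stds(r$cst, r$plateau))
    multi <- list(sim_cst_stds = sim_cst_stds, exp_cst_stds = exp_cst_stds,
                  sim_force_stds = summary$force_std_N,
                  exp_force_stds = vapply(runs, function(r)
                    r$report$std_exp, numeric(1)),
                  sim_force_covs = summary$force_cov_pct,
                  exp_force_covs = vapply(runs, function(r)
                    r$report$cov_exp, numeric(1)))
    report <- agreement_report(runs[[1]]$force, runs[[1]]$exp_force,
                               sim_plateau = runs[[1]]$plateau,
                               multi = multi)
    report$rmse <- mean(summary$rmse)
    report$r2 <- mean(summary$r2)
    report$std_sim <- mean(summary$force_std_N)
    report$cov_sim <- mean(summary$force_cov_pct)
    report$std_exp <- mean(multi$exp_force_stds)
    report$cov_exp <- mean(multi$exp_force_covs)
  }
  structure(list(runs = runs, summary = summary, report = report),
            class = "cohort_result")
}

# STDs of CST counts in sliding half-splits of the plateau: several 500-ms
# window groups per subject so the z-score median has spread.
windowed_cst_stds <- function(cst, region, window_s = 0.5, group = 4) {
  ws <- cst_window_stats(cst, window_s, t_start = region[1],
                         t_end = region[2])
  counts <- ws$counts
  n <- length(counts)
  if (n < group) return(sd_pop(counts))
  starts <- seq(1, n - group + 1)
  vapply(starts, function(s) sd_pop(counts[s:(s + group - 1)]), numeric(1))
}
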