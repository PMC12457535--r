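#' Motor-unit spike train
#'
#' A single decomposed motor unit (MU): its discharge times, decomposition
#' quality (pulse-to-noise ratio, PNR) and recording metadata.
#'
#' @param mu_id MU identifier (coerced to character).
#' @param discharge_times Numeric vector of discharge times in seconds,
#'   strictly increasing, at least two (one interspike interval).
#' @param pnr Pulse-to-noise ratio of the decomposed train, dB (>= 0).
#' @param subject_id,trial_id Recording identifiers.
#' @param mvc_level Target contraction level, percent of maximal voluntary
#'   contraction (MVC).
#' @return An object of class `mu_spike_train`.
#' @export
mu_spike_train <- function(mu_id, discharge_times, pnr,
                           subject_id = "S1", trial_id = "T1",
                           mvc_level = 60) {
  discharge_times <- as.numeric(discharge_times)
  if (length(discharge_times) < 2)
    stop("a MU spike train needs at least 2 discharges to define an ISI")
  if (any(diff(discharge_times) <= 0))
    stop("discharge_times must be strictly increasing")
  if (!is.finite(pnr) || pnr < 0)
    stop("pnr must be a non-negative finite value (dB)")
  structure(
    list(mu_id = as.character(mu_id), discharge_times = discharge_times,
         pnr = as.numeric(pnr), subject_id = as.character(subject_id),
         trial_id = as.character(trial_id), mvc_level = as.numeric(mvc_level)),
    class = "mu_spike_train")
}

#' Decomposition: a set of MU spike trains from one trial
#'
#' @param mus List of [mu_spike_train()] objects.
#' @param duration Trial duration in seconds; defaults to the last discharge.
#' @return An object of class `mu_decomposition` with elements `mus`,
#'   `duration` and `n_mus`.
#' @export
mu_decomposition <- function(mus, duration = NULL) {
  if (!length(mus)) stop("empty decomposition")
  stopifnot(all(vapply(mus, inherits, logical(1), "mu_spike_train")))
  last <- max(vapply(mus, function(m) max(m$discharge_times), numeric(1)))
  if (is.null(duration)) duration <- last
  if (last > duration + 1e-9)
    stop("discharge times exceed the stated trial duration")
  structure(list(mus = mus, duration = as.numeric(duration),
                 n_mus = length(mus)),
            class = "mu_decomposition")
}

#' @export
print.mu_decomposition <- function(x, ...) {
  cat(sprintf("MU decomposition: %d MUs, %.2f s\n", x$n_mus, x$duration))
  pnr <- vapply(x$mus, `[[`, numeric(1), "pnr")
  nd <- vapply(x$mus, function(m) length(m$discharge_times), integer(1))
  cat(sprintf("  discharges/MU: %d-%d, PNR: %.1f-%.1f dB\n",
              min(nd), max(nd), min(pnr), max(pnr)))
  invisible(x)
}

#' Quality-filter configuration for decomposed MUs
#'
#' Defaults follow standard decomposition quality practice: only MUs with
#' PNR above 29 dB are analysed, and interspike intervals (ISIs) shorter
#' than 20 ms or longer than 250 ms are treated as decomposition artifacts.
#'
#' @param pnr_min Minimum PNR in dB (exclusive bound).
#' @param isi_min,isi_max Valid ISI range in milliseconds.
#' @param min_valid_isis A MU is dropped when fewer valid ISIs remain.
#' @return An object of class `quality_filter_config`.
#' @export
quality_filter_config <- function(pnr_min = 29, isi_min = 20, isi_max = 250,
                                  min_valid_isis = 10) {
  if (!(isi_min > 0 && isi_min < isi_max))
    stop("need 0 < isi_min < isi_max")
  structure(list(pnr_min = pnr_min, isi_min = isi_min, isi_max = isi_max,
                 min_valid_isis = min_valid_isis),
            class = "quality_filter_config")
}

# ISIs of a MU in ms, optionally restricted to a time region [t0, t1] (s).
mu_isis_ms <- function(mu, region = NULL) {
  tt <- mu$discharge_times
  if (!is.null(region)) tt <- tt[tt >= region[1] & tt <= region[2]]
  if (length(tt) < 2) return(numeric(0))
  diff(tt) * 1000
}

#' Quality-filter a decomposition
#'
#' MUs with PNR at or below `pnr_min` are discarded. ISIs outside
#' `[isi_min, isi_max]` are flagged invalid and excluded from all
#' statistics; a MU is dropped entirely when fewer than `min_valid_isis`
#' valid ISIs remain. Every exclusion is recorded in a provenance log
#' attached as attribute `"filter_log"` (one record per exclusion, with a
#' reason code), which [write_filter_log()] serializes as JSON lines.
#'
#' @param decomp A [mu_decomposition()].
#' @param cfg A [quality_filter_config()].
#' @return The filtered `mu_decomposition`; MUs retain their full discharge
#'   trains (invalid ISIs are excluded at the statistics stage, not edited
#'   out of the train).
#' @export
filter_mus <- function(decomp, cfg = quality_filter_config()) {
  stopifnot(inherits(decomp, "mu_decomposition"))
  log <- list()
  keep <- logical(decomp$n_mus)
  reasons <- character(0)
  for (i in seq_len(decomp$n_mus)) {
    mu <- decomp$mus[[i]]
    if (mu$pnr <= cfg$pnr_min) {
      log[[length(log) + 1]] <- list(mu_id = mu$mu_id, reason = "pnr_low",
                                     pnr = mu$pnr, threshold = cfg$pnr_min)
      reasons <- c(reasons, "pnr_low")
      next
    }
    isis <- mu_isis_ms(mu)
    bad <- which(isis < cfg$isi_min | isis > cfg$isi_max)
    for (b in bad) {
      log[[length(log) + 1]] <- list(mu_id = mu$mu_id, reason = "isi_out_of_range",
                                     isi_ms = isis[b], index = b)
    }
    n_valid <- length(isis) - length(bad)
    if (n_valid < cfg$min_valid_isis) {
      log[[length(log) + 1]] <- list(mu_id = mu$mu_id, reason = "too_few_valid_isis",
                                     n_valid = n_valid,
                                     required = cfg$min_valid_isis)
      reasons <- c(reasons, "too_few_valid_isis")
      next
    }
    keep[i] <- TRUE
  }
  if (!any(keep)) {
    dominant <- names(sort(table(reasons), decreasing = TRUE))[1]
    stop(sprintf("no valid MUs after quality filtering (dominant filter: %s)",
                 dominant))
  }
  out <- mu_decomposition(decomp$mus[keep], duration = decomp$duration)
  attr(out, "filter_log") <- log
  attr(out, "filter_cfg") <- cfg
  out
}

#' Write the quality-filter provenance log as JSON lines
#'
#' @param decomp A decomposition returned by [filter_mus()].
#' @param path Output file; one JSON record per line.
#' @return Invisibly, the number of records written.
#' @export
write_filter_log <- function(decomp, path) {
  log <- attr(decomp, "filter_log")
  if (is.null(log)) log <- list()
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  for (rec in log)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  invisible(length(log))
}

#' Cumulative spike train (CST)
#'
#' The sorted multiset union of all MU discharge times in a decomposition.
#' Its smoothed discharge rate estimates the neural drive to the muscle.
#'
#' @param decomp A (typically quality-filtered) [mu_decomposition()].
#' @return An object of class `cst` with `spike_times` (sorted, seconds),
#'   `n_sources` and `duration`.
#' @export
build_cst <- function(decomp) {
  stopifnot(inherits(decomp, "mu_decomposition"))
  st <- sort(unlist(lapply(decomp$mus, `[[`, "discharge_times"),
                    use.names = FALSE))
  structure(list(spike_times = st, n_sources = decomp$n_mus,
                 duration = decomp$duration),
            class = "cst")
}

#' Windowed CST counts and their variability
#'
#' Counts pool discharges in contiguous non-overlapping windows (default
#' 500 ms) anchored at `t_start`; a trailing partial window is dropped. The
#' spread of these counts (population STD) indexes the variability of the
#' neural drive.
#'
#' @param cst A [build_cst()] object.
#' @param window_s Window width in seconds.
#' @param t_start,t_end Analysis region (defaults: 0 to `cst$duration`).
#' @return List with `counts`, `window_starts`, `mean` and `std`.
#' @export
cst_window_stats <- function(cst, window_s = 0.5, t_start = 0, t_end = NULL) {
  stopifnot(inherits(cst, "cst"), window_s > 0)
  if (is.null(t_end)) t_end <- cst$duration
  span <- t_end - t_start
  if (span < window_s)
    stop("analysis region is shorter than one window")
  n_win <- floor(span / window_s + 1e-9)
  starts <- t_start + (seq_len(n_win) - 1) * window_s
  counts <- vapply(starts, function(s)
    sum(cst$spike_times >= s & cst$spike_times < s + window_s), numeric(1))
  list(counts = counts, window_starts = starts,
       mean = mean(counts), std = sd_pop(counts))
}

#' Coefficient of variation of the interspike interval
#'
#' `100 * STD(ISI) / mean(ISI)` over the valid ISIs (those inside the
#' configured bounds) of one MU, optionally restricted to a time region.
#' Too few valid ISIs yield `NA` with attribute `"reason"`, never a silent
#' zero.
#'
#' @param mu A [mu_spike_train()].
#' @param region Optional `c(t0, t1)` region in seconds.
#' @param cfg A [quality_filter_config()] supplying the ISI bounds.
#' @return CoV of the ISI in percent, or flagged `NA`.
#' @export
isi_cov <- function(mu, region = NULL, cfg = quality_filter_config()) {
  isis <- mu_isis_ms(mu, region)
  isis <- isis[isis >= cfg$isi_min & isis <= cfg$isi_max]
  if (length(isis) < cfg$min_valid_isis) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("only %d valid ISIs (need %d)",
                                   length(isis), cfg$min_valid_isis)
    return(out)
  }
  100 * sd_pop(isis) / mean(isis)
}

#' Smoothed CST discharge rate
#'
#' Bins the CST at `fs_out`, converts counts to pulses/s, and low-pass
#' filters with a linear-phase FIR (Hamming window design, order
#' `2 * fs_out / fir_cutoff`, unit DC gain) applied as a centered
#' convolution so the group delay is compensated and peaks are not shifted
#' in time. Ringing undershoot is clamped at zero.
#'
#' @param cst A [build_cst()] object.
#' @param fs_out Output sampling rate, Hz.
#' @param fir_cutoff Low-pass cutoff, Hz (must be below `fs_out / 2`).
#' @param t_start,t_end Analysis region in seconds.
#' @return Data frame with columns `t` (s) and `rate` (pulses/s).
#' @export
smoothed_cst_rate <- function(cst, fs_out = 100, fir_cutoff = 2,
                              t_start = 0, t_end = NULL) {
  stopifnot(inherits(cst, "cst"))
  if (is.null(t_end)) t_end <- cst$duration
  if (fir_cutoff >= fs_out / 2)
    stop("fir_cutoff must be below the Nyquist rate of fs_out")
  if ((t_end - t_start) <= 1 / fir_cutoff)
    stop("record shorter than one filter period (1/fir_cutoff)")
  dt <- 1 / fs_out
  n_bins <- ceiling((t_end - t_start) / dt)
  st <- cst$spike_times
  st <- st[st >= t_start & st < t_start + n_bins * dt]
  counts <- tabulate(floor((st - t_start) / dt) + 1L, nbins = n_bins)
  rate <- counts * fs_out
  ord <- max(4, round(2 * fs_out / fir_cutoff))
  if (ord %% 2 == 1) ord <- ord + 1
  b <- as.numeric(signal::fir1(ord, fir_cutoff / (fs_out / 2), type = "low"))
  b <- b / sum(b)  # unit DC gain so the total spike count is conserved
  # symmetric FIR applied as a centered convolution: linear phase with the
  # group delay compensated exactly, so rate peaks are not shifted in time
  half <- ord / 2
  padded <- c(rep(0, half), rate, rep(0, half))
  sm <- as.numeric(stats::filter(padded, b, method = "convolution",
                                 sides = 2))[(half + 1):(half + n_bins)]
  sm[sm < 0] <- 0
  data.frame(t = t_start + (seq_len(n_bins) - 1) * dt, rate = sm)
}

#' Read / write the spike-train CSV dialect
#'
#' Plain UTF-8 CSV with columns `subject_id, trial_id, mu_id,
#' discharge_time_s, pnr_db` ("." decimal separator), one row per
#' discharge. The same dialect is used for experimental input and for
#' simulated pool output, so both feed the same metrics path.
#'
#' @param path File path.
#' @param mvc_level MVC level annotation attached to each MU on read.
#' @param duration Optional trial duration override.
#' @return `read_spike_csv()` returns a [mu_decomposition()];
#'   `write_spike_csv()` invisibly returns `path`.
#' @export
read_spike_csv <- function(path, mvc_level = 60, duration = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_id", "mu_id", "discharge_time_s", "pnr_db")
  if (!all(need %in% names(df)))
    stop("spike CSV must have columns: ", paste(need, collapse = ", "))
  mus <- lapply(split(df, df$mu_id), function(g) {
    g <- g[order(g$discharge_time_s), ]
    mu_spike_train(g$mu_id[1], g$discharge_time_s, g$pnr_db[1],
                   subject_id = g$subject_id[1], trial_id = g$trial_id[1],
                   mvc_level = mvc_level)
  })
  mus <- mus[order(as.numeric(factor(names(mus), levels = unique(df$mu_id))))]
  mu_decomposition(unname(mus), duration = duration)
}

#' @rdname read_spike_csv
#' @param decomp A [mu_decomposition()] to serialize.
#' @export
write_spike_csv <- function(decomp, path) {
  rows <- do.call(rbind, lapply(decomp$mus, function(m)
    data.frame(subject_id = m$subject_id, trial_id = m$trial_id,
               mu_id = m$mu_id,
               discharge_time_s = sprintf("%.6f", m$discharge_times),
               pnr_db = sprintf("%.2f", m$pnr),
               stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_spike_csv
#' @export
read_spike_json <- function(path, mvc_level = 60, duration = NULL) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  mus <- lapply(x$mus, function(m)
    mu_spike_train(m$mu_id, unlist(m$discharge_times_s), m$pnr_db,
                   subject_id = m$subject_id, trial_id = m$trial_id,
                   mvc_level = mvc_level))
  if (is.null(duration)) duration <- x$duration_s
  mu_decomposition(mus, duration = duration)
}

#' @rdname read_spike_csv
#' @export
write_spike_json <- function(decomp, path) {
  x <- list(duration_s = decomp$duration,
            mus = lapply(decomp$mus, function(m)
              list(subject_id = m$subject_id, trial_id = m$trial_id,
                   mu_id = m$mu_id, pnr_db = m$pnr,
                   discharge_times_s = m$discharge_times)))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
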