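#' Steadiest window of a force record
#'
#' The contiguous window of given width with minimal force STD (population
#' convention), searched at one-sample stride; ties break to the earliest
#' start. By convention the steadiest interval is 6 s for experimental
#' records and 1 s for time-compressed simulated records.
#'
#' @param force A `force_profile` (data frame with `t`, `force`).
#' @param width_s Window width in seconds.
#' @param plateau Optional `c(t0, t1)` restricting the search to the
#'   plateau segment.
#' @return List of class `steady_window`: `start_s`, `width_s`, `std`,
#'   `idx` (sample index range).
#' @export
steadiest_window <- function(force, width_s, plateau = NULL) {
  t <- force$t; x <- force$force
  if (!is.null(plateau)) {
    keep <- which(t >= plateau[1] & t <= plateau[2])
    t <- t[keep]; x <- x[keep]
    offset <- keep[1] - 1L
  } else offset <- 0L
  n <- length(x)
  dt <- t[2] - t[1]
  w <- round(width_s / dt)
  if (w < 2 || w > n) stop("record shorter than the requested window")
  # O(n) running mean/variance via cumulative sums (population variance)
  c1 <- cumsum(c(0, x)); c2 <- cumsum(c(0, x^2))
  starts <- seq_len(n - w + 1)
  s1 <- c1[starts + w] - c1[starts]
  s2 <- c2[starts + w] - c2[starts]
  v <- pmax(s2 / w - (s1 / w)^2, 0)
  best <- which.min(v)  # which.min takes the first minimum: earliest tie
  structure(list(start_s = t[best], width_s = w * dt, std = sqrt(v[best]),
                 idx = c(offset + best, offset + best + w - 1L)),
            class = "steady_window")
}

#' Force STD and CoV over a window
#'
#' @param force A `force_profile`.
#' @param window A [steadiest_window()] result or `c(t0, t1)` in seconds.
#' @return List with `std` (N), `cov_pct` (percent, `NA` with a reason if
#'   the mean is not positive) and `mean` (N).
#' @export
force_stats <- function(force, window) {
  if (inherits(window, "steady_window")) {
    x <- force$force[window$idx[1]:window$idx[2]]
  } else {
    x <- force$force[force$t >= window[1] & force$t <= window[2]]
  }
  if (!length(x)) stop("empty window")
  m <- mean(x)
  std <- sd_pop(x)
  if (m <= 0) {
    cov <- NA_real_
    attr(cov, "reason") <- "non-positive mean force; CoV undefined"
  } else cov <- 100 * std / m
  list(std = std, cov_pct = cov, mean = m)
}

# Resample a profile onto a reference grid. When both profiles carry
# trapezoid landmarks (attribute "landmarks": ramp start, ramp end,
# plateau end, record end) the simulated time axis is piecewise-linearly
# warped so the segments coincide -- a time-compressed simulation has
# different ramp/plateau proportions than a full-length experimental
# record, so plain duration normalization would misalign them. Without
# landmarks the time axes are normalized to [0, 1].
align_profiles <- function(sim, exp) {
  ls <- attr(sim, "landmarks"); le <- attr(exp, "landmarks")
  if (!is.null(ls) && !is.null(le) && length(ls) == length(le)) {
    mapped <- approx(ls, le, xout = sim$t, rule = 2)$y
    return(approx(mapped, sim$force, xout = exp$t, rule = 2)$y)
  }
  span_s <- diff(range(sim$t)); span_e <- diff(range(exp$t))
  if (abs(span_s - span_e) / max(span_e, 1e-12) > 1e-6) {
    xs <- (sim$t - min(sim$t)) / span_s
    xe <- (exp$t - min(exp$t)) / span_e
    approx(xs, sim$force, xout = xe, rule = 2)$y
  } else if (isTRUE(all.equal(sim$t, exp$t))) {
    sim$force
  } else {
    approx(sim$t, sim$force, xout = exp$t, rule = 2)$y
  }
}

#' RMSE and R-squared between simulated and experimental force
#'
#' The simulated record is resampled onto the experimental grid; when both
#' records carry trapezoid landmarks (attribute `"landmarks"`) the ramp
#' start/end anchor a piecewise time warp between the compressed
#' simulation clock and the experimental clock, otherwise the time axes
#' are normalized to `[0, 1]`. `r2 = 1 - SS_res / SS_tot` with the
#' experimental record as reference.
#'
#' @param sim,exp `force_profile` objects.
#' @return List with `rmse` (N) and `r2` (flagged `NA` if the reference
#'   has zero variance).
#' @export
rmse_r2 <- function(sim, exp) {
  s <- align_profiles(sim, exp)
  e <- exp$force
  rmse <- sqrt(mean((s - e)^2))
  ss_tot <- sum((e - mean(e))^2)
  if (ss_tot <= 0) {
    r2 <- NA_real_
    attr(r2, "reason") <- "zero-variance reference; R2 undefined"
  } else r2 <- 1 - sum((s - e)^2) / ss_tot
  list(rmse = rmse, r2 = r2)
}

#' Correlation of per-subject median z-scored CST variability
#'
#' Within each condition (simulated, experimental) the windowed CST STD
#' values of all subjects are z-scored together; each subject is then
#' summarized by the median of its z-scores, and the paired medians are
#' correlated across subjects (Pearson by default).
#'
#' @param sim_stds,exp_stds Lists (one element per subject) of numeric
#'   vectors of windowed CST STD values.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p`, `medians_sim`, `medians_exp`.
#' @export
zscore_median_correlation <- function(sim_stds, exp_stds,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(sim_stds) != length(exp_stds))
    stop("need paired per-subject inputs")
  if (length(sim_stds) < 3)
    stop("need at least 3 subjects for the correlation analysis")
  zmed <- function(lst) {
    all <- unlist(lst)
    mu <- mean(all); s <- sd_pop(all)
    if (s == 0) s <- 1
    vapply(lst, function(v) median((v - mu) / s), numeric(1))
  }
  ms <- zmed(sim_stds); me <- zmed(exp_stds)
  ct <- cor.test(ms, me, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value,
       medians_sim = ms, medians_exp = me)
}

#' t test on per-subject variability metrics
#'
#' Compares simulated against experimental variability (force STD or CoV)
#' across subjects. Default is a one-tailed Welch two-sample test of
#' simulated < experimental; the sign of `t` is negative when the
#' simulated values are smaller on average.
#'
#' @param sim_values,exp_values Per-subject metric values.
#' @param alternative Tail convention (`"less"`, `"two.sided"`,
#'   `"greater"`).
#' @param paired Paired test?
#' @param var.equal Pooled-variance test instead of Welch?
#' @return List with `t`, `p`, `df`.
#' @export
variability_ttest <- function(sim_values, exp_values,
                              alternative = "less", paired = FALSE,
                              var.equal = FALSE) {
  if (length(sim_values) < 2 || length(exp_values) < 2)
    stop("need at least 2 values per group")
  # degenerate case: identical constant groups carry no evidence of a
  # difference; report t = 0 rather than failing
  if (sd(sim_values) == 0 && sd(exp_values) == 0 &&
      mean(sim_values) == mean(exp_values)) {
    return(list(t = 0,
                p = if (alternative == "two.sided") 1 else 0.5,
                df = length(sim_values) + length(exp_values) - 2))
  }
  ht <- t.test(sim_values, exp_values, alternative = alternative,
               paired = paired, var.equal = var.equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Agreement report between simulated and experimental recordings
#'
#' Bundles every agreement and variability statistic: RMSE, R-squared,
#' steadiest-window force STD/CoV for both records, and (when several
#' subjects are supplied) the z-score median correlation of CST STDs and
#' the variability t tests.
#'
#' @param sim,exp `force_profile` objects (one subject).
#' @param sim_window_s,exp_window_s Steadiest-window widths (1 s for
#'   time-compressed simulations, 6 s for experimental records).
#' @param sim_plateau,exp_plateau Optional plateau bounds for the window
#'   search.
#' @param multi Optional list for multi-subject statistics with elements
#'   `sim_cst_stds`, `exp_cst_stds` (lists of windowed CST STDs),
#'   `sim_force_stds`, `exp_force_stds`, `sim_force_covs`,
#'   `exp_force_covs` (per-subject numeric vectors).
#' @return An object of class `agreement_report` (list).
#' @export
agreement_report <- function(sim, exp, sim_window_s = 1, exp_window_s = 6,
                             sim_plateau = NULL, exp_plateau = NULL,
                             multi = NULL) {
  fit <- rmse_r2(sim, exp)
  # clamp the window widths to the searchable (plateau-restricted) spans
  span <- function(f, plateau) {
    if (is.null(plateau)) diff(range(f$t))
    else min(plateau[2], max(f$t)) - max(plateau[1], min(f$t))
  }
  ws <- steadiest_window(sim, min(sim_window_s, span(sim, sim_plateau)),
                         sim_plateau)
  we <- steadiest_window(exp, min(exp_window_s, span(exp, exp_plateau)),
                         exp_plateau)
  fs <- force_stats(sim, ws); fe <- force_stats(exp, we)
  rep <- list(rmse = fit$rmse, r2 = fit$r2,
              std_sim = fs$std, cov_sim = fs$cov_pct,
              std_exp = fe$std, cov_exp = fe$cov_pct,
              window_sim = c(ws$start_s, ws$start_s + ws$width_s),
              window_exp = c(we$start_s, we$start_s + we$width_s))
  if (!is.null(multi)) {
    if (!is.null(multi$sim_cst_stds)) {
      zc <- zscore_median_correlation(multi$sim_cst_stds, multi$exp_cst_stds)
      rep$zscore_corr_r <- zc$r
      rep$zscore_corr_p <- zc$p
    }
    if (!is.null(multi$sim_force_stds)) {
      tt <- variability_ttest(multi$sim_force_stds, multi$exp_force_stds)
      rep$ttest_std <- c(t = tt$t, p = tt$p)
    }
    if (!is.null(multi$sim_force_covs)) {
      tt <- variability_ttest(multi$sim_force_covs, multi$exp_force_covs)
      rep$ttest_cov <- c(t = tt$t, p = tt$p)
    }
  } else {
    rep$note <- "multi-subject statistics unavailable for a single subject"
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report\n")
  cat(sprintf("  RMSE: %.3f N   R2: %.4f\n", x$rmse, x$r2))
  cat(sprintf("  force STD (N):  sim %.3f  exp %.3f\n", x$std_sim, x$std_exp))
  cat(sprintf("  force CoV (%%):  sim %.3f  exp %.3f\n", x$cov_sim, x$cov_exp))
  if (!is.null(x$zscore_corr_r))
    cat(sprintf("  CST STD z-score median correlation: r = %.3f, p = %.4g\n",
                x$zscore_corr_r, x$zscore_corr_p))
  if (!is.null(x$ttest_std))
    cat(sprintf("  t test on STDs: t = %.3f, p = %.4g\n",
                x$ttest_std["t"], x$ttest_std["p"]))
  if (!is.null(x$ttest_cov))
    cat(sprintf("  t test on CoVs: t = %.3f, p = %.4g\n",
                x$ttest_cov["t"], x$ttest_cov["p"]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Write an agreement report as JSON
#'
#' @param report An [agreement_report()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_agreement_json <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, na = "null"), path)
  invisible(path)
}
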