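#' Calcium release/reuptake parameters of the neuromuscular junction stage
#'
#' Each motoneuron spike opens sarcoplasmic-reticulum release for a short
#' period; sarcoplasmic calcium is pumped back with first-order kinetics.
#' The three-state linear system per motor unit is
#' \deqn{s' = -k2 s, \quad c' = k1 s - c/\tau_u - k5 c + k6 b, \quad
#'       b' = k5 c - k6 b}
#' with a spike adding `ca_pulse` to the release gate `s`. Here `c` is
#' free sarcoplasmic calcium (arbitrary concentration units), `b` a bound
#' buffer pool, `k1`/`k2` the release rate constants, `k5`/`k6` the
#' buffer exchange rates and `tau_reuptake` the pump clearance time.
#' Muscle activation is a saturating Hill function of `c`, bounded in
#' `[0, 1]`. Fiber types II are faster than type I: all rates are scaled
#' by the inverse of `type_time_scale`.
#'
#' @param k1,k2 Release rate constants (1/s).
#' @param k5,k6 Buffer exchange rate constants (1/s).
#' @param tau_reuptake Pump clearance time constant (s).
#' @param ca_pulse Release-gate increment per spike (dimensionless).
#' @param hill_n,hill_K Activation saturation exponent and half-activation
#'   constant; `hill_K` is normally set by [calibrate_mvc()].
#' @param type_time_scale Relative time constants of fiber types I/IIa/IIb.
#' @return An object of class `calcium_params`.
#' @export
calcium_params <- function(k1 = 40, k2 = 12, k5 = 3, k6 = 10,
                           tau_reuptake = 0.1, ca_pulse = 1,
                           hill_n = 2, hill_K = 2,
                           type_time_scale = c(I = 1, IIa = 0.6, IIb = 0.4)) {
  stopifnot(k1 > 0, k2 > 0, k5 > 0, k6 > 0, tau_reuptake > 0, ca_pulse > 0,
            hill_n > 0, hill_K > 0, all(type_time_scale > 0))
  structure(list(k1 = k1, k2 = k2, k5 = k5, k6 = k6,
                 tau_reuptake = tau_reuptake, ca_pulse = ca_pulse,
                 hill_n = hill_n, hill_K = hill_K,
                 type_time_scale = type_time_scale),
            class = "calcium_params")
}

# System matrix (1/s) of the release/reuptake ODE for one fiber type.
ca_system_matrix <- function(ca, type = "I") {
  sc <- 1 / ca$type_time_scale[[type]]
  k1 <- ca$k1 * sc; k2 <- ca$k2 * sc; k5 <- ca$k5 * sc; k6 <- ca$k6 * sc
  tau <- ca$tau_reuptake / sc
  matrix(c(-k2,            0,   0,
            k1, -(k5 + 1/tau),  k6,
             0,           k5, -k6),
         3, 3, byrow = TRUE)
}

# Matrix exponential via eigendecomposition (3x3, generically
# diagonalizable); used for the exact per-step propagator.
expm_small <- function(A) {
  e <- eigen(A)
  Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
}

# Exact trajectory of the linear system from a single release event at
# t = 0: state over time grid tt (s). Reference solution for tests.
ca_single_pulse <- function(ca, tt, type = "I") {
  A <- ca_system_matrix(ca, type)
  x0 <- c(ca$ca_pulse, 0, 0)
  t(vapply(tt, function(s) as.numeric(expm_small(A * s) %*% x0), numeric(3)))
}

hill_saturation <- function(c, K, n) {
  a <- c^n / (c^n + K^n)
  pmin(pmax(a, 0), 1)
}

#' Convert pool spike trains to fiber-type muscle activation
#'
#' Integrates the calcium release/reuptake system per motor unit (exact
#' matrix-exponential stepping of the linear dynamics, spikes binned at
#' `dt`), applies the saturating Hill function, and aggregates per fiber
#' type as the twitch-scale-weighted mean of that type's units.
#'
#' @param spikes A [simulate_pool()] result (or a compatible list with a
#'   `spikes` element).
#' @param pool The pool that produced the spikes (supplies fiber types and
#'   twitch scales).
#' @param ca A [calcium_params()].
#' @param dt Output sample interval in seconds.
#' @param t_end Horizon in seconds (defaults to `spikes$t_end`).
#' @param keep_mu Keep per-MU activation and calcium matrices (attributes
#'   `"a_mu"` and `"ca_mu"`)? Needed by the MVC calibration.
#' @return An object of class `activation_trace`: data frame with `t`,
#'   `a_I`, `a_IIa`, `a_IIb` in `[0, 1]`.
#' @export
spikes_to_activation <- function(spikes, pool, ca = calcium_params(),
                                 dt = 0.001, t_end = NULL, keep_mu = FALSE) {
  stopifnot(inherits(pool, "motoneuron_pool"))
  if (is.null(t_end)) t_end <- spikes$t_end
  n_steps <- ceiling(t_end / dt)
  # row k holds the state after k exact propagation steps, i.e. at k * dt
  tt <- seq_len(n_steps) * dt
  n <- nrow(pool)
  stopifnot(length(spikes$spikes) == n)

  types <- levels(pool$fiber_type)
  a_type <- matrix(0, n_steps, length(types),
                   dimnames = list(NULL, paste0("a_", types)))
  a_mu <- if (keep_mu) matrix(0, n_steps, n) else NULL
  ca_mu <- if (keep_mu) matrix(0, n_steps, n) else NULL

  for (ty in types) {
    members <- which(pool$fiber_type == ty)
    if (!length(members)) next
    A <- ca_system_matrix(ca, ty)
    Phi <- expm_small(A * dt)
    X <- matrix(0, 3, length(members))
    # spike counts per bin per member
    binned <- lapply(spikes$spikes[members], function(st) {
      st <- st[st >= 0 & st < n_steps * dt]
      tabulate(floor(st / dt) + 1L, nbins = n_steps)
    })
    Cmat <- matrix(0, n_steps, length(members))
    for (k in seq_len(n_steps)) {
      add <- vapply(binned, `[[`, numeric(1), k)
      X[1, ] <- X[1, ] + ca$ca_pulse * add
      X <- Phi %*% X
      Cmat[k, ] <- X[2, ]
    }
    Amat <- hill_saturation(Cmat, ca$hill_K, ca$hill_n)
    w <- pool$twitch_scale[members]
    a_type[, paste0("a_", ty)] <- as.numeric(Amat %*% w) / sum(w)
    if (keep_mu) {
      a_mu[, members] <- Amat
      ca_mu[, members] <- Cmat
    }
  }
  stopifnot(all(a_type >= 0 & a_type <= 1))
  out <- data.frame(t = tt, a_type, check.names = FALSE)
  class(out) <- c("activation_trace", "data.frame")
  attr(out, "calcium") <- ca
  if (keep_mu) {
    attr(out, "a_mu") <- a_mu
    attr(out, "ca_mu") <- ca_mu
  }
  out
}

#' Lumped Hill-type muscle parameters
#'
#' Zero-dimensional three-element muscle for isometric contraction: the
#' contractile element produces `f_max * sum(gain_t * massfrac_t * a_t)`
#' and the series elastic element low-pass filters it with time constant
#' `tau_series`. Gains are normalized so that full activation yields
#' exactly `f_max`. Mass fractions default to the fiber-count fractions of
#' the pool (each motoneuron group innervates a muscle-volume share
#' proportional to its type's fiber fraction; twitch scales weight units
#' within a type at the activation-aggregation stage).
#'
#' @param f_max Maximal isometric force (N); set by [calibrate_mvc()].
#' @param gains Relative activation-to-force gains per fiber type.
#' @param tau_series Series-elastic time constant (s).
#' @param mass_fractions Named fiber-type mass fractions (sum to 1).
#' @param pool Optional pool from which mass fractions are derived.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(f_max = NULL, gains = c(I = 1, IIa = 1, IIb = 1),
                        tau_series = 0.01, mass_fractions = NULL,
                        pool = NULL) {
  if (is.null(mass_fractions)) {
    if (is.null(pool)) stop("supply mass_fractions or a pool")
    counts <- table(pool$fiber_type)
    mass_fractions <- stats::setNames(as.numeric(counts) / sum(counts),
                                      names(counts))
  }
  mass_fractions <- mass_fractions / sum(mass_fractions)
  wsum <- sum(gains[names(mass_fractions)] * mass_fractions)
  gains <- gains / wsum  # so that all-ones activation gives exactly f_max
  structure(list(f_max = f_max, gains = gains, tau_series = tau_series,
                 mass_fractions = mass_fractions),
            class = "hill_params")
}

#' Muscle force from fiber-type activation
#'
#' @param act An [spikes_to_activation()] trace.
#' @param hill A calibrated [hill_params()] (requires `f_max`).
#' @return An object of class `force_profile`: data frame `t`, `force` (N),
#'   with attribute `source = "simulated"`.
#' @export
activation_to_force <- function(act, hill) {
  stopifnot(inherits(hill, "hill_params"))
  if (is.null(hill$f_max)) stop("uncalibrated Hill muscle: f_max not set")
  types <- names(hill$mass_fractions)
  f_ce <- rep(0, nrow(act))
  for (ty in types) {
    col <- paste0("a_", ty)
    if (col %in% names(act))
      f_ce <- f_ce + hill$gains[[ty]] * hill$mass_fractions[[ty]] * act[[col]]
  }
  f_ce <- hill$f_max * f_ce
  dt <- act$t[2] - act$t[1]
  alpha <- 1 - exp(-dt / hill$tau_series)
  force <- numeric(length(f_ce))
  f <- 0
  for (k in seq_along(f_ce)) {
    f <- f + alpha * (f_ce[k] - f)
    force[k] <- f
  }
  force[force < 0] <- 0
  out <- data.frame(t = act$t, force = force)
  class(out) <- c("force_profile", "data.frame")
  attr(out, "source") <- "simulated"
  out
}

#' Read / write the force-trace CSV dialect
#'
#' Two columns, `time_s` and `force_N`, UTF-8, "." decimal separator.
#'
#' @param path File path.
#' @param source Label attached on read (`simulated`, `experimental`,
#'   `target`).
#' @return `read_force_csv()` returns a `force_profile`;
#'   `write_force_csv()` invisibly returns `path`.
#' @export
read_force_csv <- function(path, source = "experimental") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "force_N") %in% names(df)))
    stop("force CSV must have columns time_s, force_N")
  out <- data.frame(t = df$time_s, force = df$force_N)
  class(out) <- c("force_profile", "data.frame")
  attr(out, "source") <- source
  out
}

#' @rdname read_force_csv
#' @param force A `force_profile`.
#' @export
write_force_csv <- function(force, path) {
  df <- data.frame(time_s = sprintf("%.6f", force$t),
                   force_N = sprintf("%.6f", force$force))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Steady per-MU calcium traces under constant drive: simulate the pool at
# a constant drive (no noise), run the calcium stage, return the per-MU
# calcium matrix over the last `window` seconds.
steady_calcium <- function(pool, gain_nA, drive, ca, t_sim = 2.5,
                           window = 1, dt_ms = 0.05, dt_act = 0.001) {
  sp <- simulate_pool(pool, pool_input(drive, gain_nA = gain_nA),
                      dt_ms = dt_ms, t_end = t_sim)
  act <- spikes_to_activation(sp, pool, ca, dt = dt_act, keep_mu = TRUE)
  keep <- act$t >= t_sim - window
  attr(act, "ca_mu")[keep, , drop = FALSE]
}

#' Calibrate the muscle to a subject's MVC force
#'
#' Two-point closed-loop calibration at constant drives corresponding to
#' 100 %MVC (`1/0.6` on the 60 %MVC-normalized drive scale) and to the
#' 60 %MVC plateau (drive 1). The Hill half-activation constant `hill_K`
#' is root-found so that the plateau/maximal force ratio equals
#' `target_ratio`, then `f_max` is set so the maximal force equals
#' `mvc_force_N`. Results are cached per session (deterministic).
#'
#' @param hill A [hill_params()] (gains and mass fractions are kept).
#' @param pool The motoneuron pool.
#' @param mvc_force_N Subject MVC force in newtons.
#' @param gain_nA Pool gain from [calibrate_gain()].
#' @param ca A [calcium_params()]; its `hill_K` (and possibly `hill_n`) are
#'   replaced by calibrated values.
#' @param target_ratio Plateau-to-MVC force ratio (0.6 for the 60 % trial).
#' @param tol Relative tolerance on the achieved ratio.
#' @param max_iter Maximum root-finding iterations.
#' @return A list of class `mvc_calibration` with elements `hill`, `ca`
#'   and `report` (achieved ratio, f_max, K, n).
#' @export
calibrate_mvc <- function(hill, pool, mvc_force_N, gain_nA,
                          ca = calcium_params(), target_ratio = 0.6,
                          tol = 0.02, max_iter = 100) {
  key <- object_key("mvc", attr(pool, "channels"), pool$diameter_um,
                    unclass(ca), hill$gains, hill$mass_fractions,
                    mvc_force_N, gain_nA, target_ratio)
  cache_get_or(key, function() {
    c_sat <- steady_calcium(pool, gain_nA, 1 / target_ratio, ca)
    c_plat <- steady_calcium(pool, gain_nA, 1, ca)
    c_half <- steady_calcium(pool, gain_nA, 0.5, ca)
    c_threeq <- steady_calcium(pool, gain_nA, 0.75, ca)
    # per-MU weights reproducing gain_t * massfrac_t * (twitch-weighted
    # mean over that type): w_mu = gain_t * mf_t * P_mu / sum_type(P)
    ty <- as.character(pool$fiber_type)
    p_type_sum <- tapply(pool$twitch_scale, ty, sum)
    w_mu <- unname(hill$gains[ty] * hill$mass_fractions[ty] *
                     pool$twitch_scale / p_type_sum[ty])
    force_at <- function(cmat, K, n) {
      a <- hill_saturation(cmat, K, n)
      mean(a %*% w_mu)
    }
    # Several Hill exponents can reach the target plateau/MVC ratio; pick
    # the root whose force-drive curve is most proportional, checked at
    # half drive (the intact system produces force roughly proportional to
    # its common drive, which is what lets an open-loop trapezoidal drive
    # reproduce a trapezoidal force record).
    candidates <- list()
    for (n_hill in unique(c(ca$hill_n, 1.5, 2, 2.5, 3, 4))) {
      ratio_err <- function(logK) {
        K <- exp(logK)
        force_at(c_plat, K, n_hill) / force_at(c_sat, K, n_hill) - target_ratio
      }
      lo <- log(1e-3); hi <- log(1e3)
      if (ratio_err(lo) * ratio_err(hi) > 0) next
      root <- stats::uniroot(ratio_err, c(lo, hi), tol = 1e-10,
                             maxiter = max_iter)
      K <- exp(root$root)
      candidates[[length(candidates) + 1]] <-
        list(n = n_hill, K = K,
             lin_err = abs(force_at(c_half, K, n_hill) /
                             force_at(c_plat, K, n_hill) - 0.5) +
                       abs(force_at(c_threeq, K, n_hill) /
                             force_at(c_plat, K, n_hill) - 0.75))
    }
    if (!length(candidates))
      stop("MVC calibration failed: plateau/MVC force ratio ", target_ratio,
           " is unattainable for any tested Hill exponent")
    best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1),
                                         "lin_err"))]]
    n_hill <- best$n
    K <- best$K
    s_sat <- force_at(c_sat, K, n_hill)
    achieved <- force_at(c_plat, K, n_hill) / s_sat
    if (abs(achieved - target_ratio) > tol)
      stop(sprintf("MVC calibration did not converge: ratio %.4f vs target %.2f",
                   achieved, target_ratio))
    hill$f_max <- mvc_force_N / s_sat
    ca$hill_K <- K
    ca$hill_n <- n_hill
    structure(list(hill = hill, ca = ca,
                   report = list(f_max = hill$f_max, hill_K = K,
                                 hill_n = n_hill, ratio = achieved,
                                 sat_activation = s_sat,
                                 mvc_force_N = mvc_force_N)),
              class = "mvc_calibration")
  })
}

#' @export
print.mvc_calibration <- function(x, ...) {
  r <- x$report
  cat(sprintf("MVC calibration: f_max = %.1f N, hill_K = %.3f (n = %g), plateau/MVC = %.3f\n",
              r$f_max, r$hill_K, r$hill_n, r$ratio))
  invisible(x)
}
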