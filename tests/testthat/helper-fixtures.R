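# Shared in-code fixtures; everything is generated, nothing is stored.

# A periodic MU train: n discharges at a fixed ISI (s), starting at t0.
periodic_mu <- function(mu_id = "MU01", isi = 0.1, n = 21, t0 = 0,
                        pnr = 35) {
  mu_spike_train(mu_id, t0 + (seq_len(n) - 1) * isi, pnr)
}

# A gamma-renewal MU train over [0, dur] at a mean rate (Hz) and ISI CoV.
gamma_mu <- function(mu_id, rate = 10, cov = 0.2, dur = 20, pnr = 35,
                     seed = 1) {
  shape <- if (cov > 0) 1 / cov^2 else Inf
  times <- with_seed(seed, function() {
    t <- 0; out <- numeric(0)
    while (t < dur) {
      isi <- if (is.finite(shape))
        stats::rgamma(1, shape = shape, scale = 1 / rate / shape)
      else 1 / rate
      isi <- min(max(isi, 0.021), 0.249)
      t <- t + isi
      if (t < dur) out <- c(out, t)
    }
    out
  })
  mu_spike_train(mu_id, times, pnr)
}

with_seed <- nmspool:::with_seed

# A small decomposition of well-behaved gamma trains.
toy_decomp <- function(n_mus = 4, dur = 20, seed = 1) {
  mus <- lapply(seq_len(n_mus), function(i)
    gamma_mu(sprintf("MU%02d", i), rate = 8 + 2 * i, cov = 0.15,
             dur = dur, seed = seed * 100 + i))
  mu_decomposition(mus, duration = dur)
}

# A tiny pool that simulates fast; channels/geometry are the defaults.
small_pool <- function(n = 12) build_pool(pool_spec(n_neurons = n))

# Pool spikes stub from explicit spike-time lists.
fake_spikes <- function(spike_list, t_end) {
  structure(list(spikes = spike_list, n_neurons = length(spike_list),
                 t_end = t_end, dt_ms = NA_real_),
            class = "pool_spikes")
}

# Poisson spike train at a given rate over [0, dur].
poisson_train <- function(rate, dur, seed) {
  with_seed(seed, function() {
    n <- stats::rpois(1, rate * dur)
    sort(stats::runif(n, 0, dur))
  })
}

# Force profile from a plain vector at sampling interval dt.
force_from_vector <- function(x, dt = 0.01, source = "simulated") {
  out <- data.frame(t = (seq_along(x) - 1) * dt, force = x)
  class(out) <- c("force_profile", "data.frame")
  attr(out, "source") <- source
  out
}
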