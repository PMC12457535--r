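test_that("pool construction matches the anatomical specification", {
  pool <- build_pool(pool_spec(n_neurons = 200))
  expect_equal(pool$diameter_um[1], 48.8)
  expect_equal(pool$diameter_um[200], 99.7)
  expect_equal(pool$twitch_scale[200] / pool$twitch_scale[1], 100)
  expect_true(all(diff(pool$diameter_um) > 0))
  counts <- table(pool$fiber_type)
  expect_equal(as.numeric(counts), c(146, 42, 12))
  expect_equal(names(counts), c("I", "IIa", "IIb"))
  # types ordered by size: all I below all IIa below all IIb
  expect_true(max(which(pool$fiber_type == "I")) <
                min(which(pool$fiber_type == "IIa")))
  expect_true(max(which(pool$fiber_type == "IIa")) <
                min(which(pool$fiber_type == "IIb")))

  # largest-remainder apportionment at reduced pool size
  expect_equal(as.numeric(fiber_type_counts(50, c(I = 0.73, IIa = 0.21,
                                                  IIb = 0.06))),
               c(37, 10, 3))

  expect_error(pool_spec(fiber_fractions = c(I = 0.7, IIa = 0.2, IIb = 0.2)),
               "sum to 1")
})

test_that("zero input current produces zero spikes", {
  pool <- small_pool(4)
  sp <- simulate_pool(pool, pool_input(0, gain_nA = 0), dt_ms = 0.05,
                      t_end = 0.5)
  expect_equal(sum(lengths(sp$spikes)), 0)
})

test_that("constant suprathreshold current gives a stable limit cycle", {
  pool <- small_pool(4)
  p1 <- pool[1, , drop = FALSE]
  attr(p1, "channels") <- attr(pool, "channels")
  attr(p1, "fixed") <- attr(pool, "fixed")
  class(p1) <- class(pool)
  sp <- simulate_pool(p1, pool_input(1, gain_nA = 4), dt_ms = 0.025,
                      t_end = 3)$spikes[[1]]
  isis <- diff(sp[sp > 1])  # discard the onset transient
  expect_gt(length(isis), 10)
  expect_lt(sd(isis) / mean(isis), 0.01)

  # integration convergence: halving dt moves spike times < 0.5 ms
  sp2 <- simulate_pool(p1, pool_input(1, gain_nA = 4), dt_ms = 0.0125,
                       t_end = 3)$spikes[[1]]
  k <- min(length(sp), length(sp2))
  expect_lt(max(abs(sp[1:k] - sp2[1:k])), 5e-4)

  # bit-reproducibility with identical noise-free input
  sp3 <- simulate_pool(p1, pool_input(1, gain_nA = 4), dt_ms = 0.025,
                       t_end = 3)$spikes[[1]]
  expect_identical(sp, sp3)
})

test_that("a slow noise-free common ramp recruits in size order", {
  pool <- build_pool(pool_spec(n_neurons = 24))
  gain <- calibrate_gain(pool)
  # slow ramp past full drive with a short hold so the last-recruited
  # neuron (whose near-rheobase firing latency is long) spikes in-window
  drive <- c(seq(0, 1.3, length.out = 781), rep(1.3, 100))
  sp <- simulate_pool(pool, pool_input(drive, drive_dt = 0.01,
                                       gain_nA = gain), dt_ms = 0.05)
  first <- vapply(sp$spikes, function(s)
    if (length(s)) s[1] else NA_real_, numeric(1))
  expect_true(all(is.finite(first)))
  expect_equal(cor(first, pool$diameter_um, method = "kendall"), 1)
})

test_that("pool rate coding is monotone in drive amplitude", {
  pool <- build_pool(pool_spec(n_neurons = 10))
  gain <- calibrate_gain(pool)
  mean_rate <- vapply(c(0.5, 0.75, 1.0, 1.3), function(a) {
    sp <- simulate_pool(pool, pool_input(a, gain_nA = gain), dt_ms = 0.05,
                        t_end = 2)
    mean(vapply(sp$spikes, function(s) sum(s > 1), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rate) > 0))
})

test_that("gain calibration is deterministic and scales with rheobase", {
  pool <- build_pool(pool_spec(n_neurons = 6))
  g1 <- calibrate_gain(pool)
  expect_identical(calibrate_gain(pool), g1)
  clear_calibration_cache()
  expect_equal(calibrate_gain(pool), g1)

  # one-neuron pool: gain equals that neuron's rheobase
  p1 <- build_pool(pool_spec(n_neurons = 6))[6, , drop = FALSE]
  attr(p1, "channels") <- channel_defaults()
  attr(p1, "fixed") <- nmspool:::pool_fixed()
  class(p1) <- c("motoneuron_pool", "data.frame")
  expect_equal(calibrate_gain(p1), rheobase(p1, 1), tolerance = 0.02)

  # doubling every conductance density and capacitance doubles all
  # membrane currents at identical voltage trajectories, so rheobase and
  # hence the calibrated gain double exactly (up to bisection tolerance)
  ch2 <- lapply(channel_defaults(), function(v) v)
  for (nm in names(ch2))
    if (grepl("\\.g_|\\.cm", nm)) ch2[[nm]] <- ch2[[nm]] * 2
  pool2 <- build_pool(pool_spec(n_neurons = 6), channels = ch2)
  fx <- attr(pool2, "fixed")
  fx$gc_ds <- fx$gc_ds * 2; fx$gc_sh <- fx$gc_sh * 2; fx$gc_hi <- fx$gc_hi * 2
  fx$alpha_ca <- fx$alpha_ca / 2  # keep Ca influx per unit area unchanged
  attr(pool2, "fixed") <- fx
  expect_equal(calibrate_gain(pool2), 2 * g1, tolerance = 0.05)
})

test_that("the integrator guards its own validity", {
  pool <- small_pool(3)
  expect_error(simulate_pool(pool, pool_input(1, gain_nA = 1), dt_ms = 0.2,
                             t_end = 0.1), "dt_ms")
  expect_error(simulate_pool(pool, pool_input(0.5, gain_nA = 1),
                             dt_ms = 0.05), "t_end")
})

test_that("pool serialization and spike export keep the analysis contract", {
  pool <- small_pool(10)
  f <- tempfile(fileext = ".json")
  write_pool_json(pool, f)
  x <- jsonlite::fromJSON(f, simplifyDataFrame = FALSE)
  expect_length(x$neurons, 10)
  expect_equal(x$neurons[[10]]$fiber_type, "IIb")

  sp <- fake_spikes(list(c(0.1, 0.2, 0.3), numeric(0), c(0.15, 0.35),
                         c(0.5), c(0.2, 0.4)), t_end = 1)
  csv <- tempfile(fileext = ".csv")
  write_pool_spikes_csv(sp, csv)
  dec <- read_spike_csv(csv, duration = 1)
  expect_equal(dec$n_mus, 3)  # neurons with < 2 spikes are omitted
  cst <- build_cst(dec)
  expect_equal(cst$spike_times, c(0.1, 0.15, 0.2, 0.2, 0.3, 0.35, 0.4))
})
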