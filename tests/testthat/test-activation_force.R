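test_that("no spikes yield identically zero activation", {
  pool <- small_pool(6)
  act <- spikes_to_activation(fake_spikes(rep(list(numeric(0)), 6), 1),
                              pool, dt = 0.001)
  expect_true(all(act$a_I == 0 & act$a_IIa == 0 & act$a_IIb == 0))
})

test_that("a single spike reproduces the closed-form pulse response", {
  pool <- small_pool(3)
  ca <- calcium_params(hill_K = 1.5)
  sp <- fake_spikes(list(c(0), numeric(0), numeric(0)), t_end = 1)
  act <- spikes_to_activation(sp, pool, ca, dt = 0.001, keep_mu = TRUE)
  c_sim <- attr(act, "ca_mu")[, 1]

  # independent oracle: numerically integrate the release/reuptake ODE
  A <- nmspool:::ca_system_matrix(ca, "I")
  sol <- deSolve::lsoda(y = c(s = ca$ca_pulse, c = 0, b = 0),
                        times = c(0, act$t),
                        func = function(t, y, p) list(as.numeric(A %*% y)),
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(c_sim - sol[-1, "c"])), 1e-6)

  # single transient: rises then decays, peak below full activation
  a1 <- attr(act, "a_mu")[, 1]
  expect_lt(max(a1), 1)
  expect_gt(max(a1), 0)
  expect_lt(a1[length(a1)], max(a1) / 2)
})

test_that("steady activation is monotone in discharge rate", {
  pool <- small_pool(3)
  ca <- calcium_params(hill_K = 3)
  rate_act <- vapply(c(10, 30), function(r) {
    sp <- fake_spikes(list(seq(0, 3, by = 1 / r), numeric(0), numeric(0)),
                      t_end = 3)
    act <- spikes_to_activation(sp, pool, ca, dt = 0.001, keep_mu = TRUE)
    mean(attr(act, "a_mu")[act$t > 2, 1])
  }, numeric(1))
  expect_gt(rate_act[2], rate_act[1])
})

test_that("activation stays in [0, 1] under Poisson stress inputs", {
  pool <- small_pool(8)
  for (rate in c(5, 20, 60, 100)) {
    sp <- fake_spikes(lapply(1:8, function(i)
      poisson_train(rate, 2, seed = rate * 10 + i)), t_end = 2)
    act <- spikes_to_activation(sp, pool, calcium_params(hill_K = 1),
                                dt = 0.001)
    a <- as.matrix(act[, -1])
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("the Hill muscle converts activation by the stated arithmetic", {
  pool <- small_pool(10)
  hill <- hill_params(f_max = 500, pool = pool)
  # mass fractions are the fiber-count shares and gains are normalized
  expect_equal(sum(hill$gains[names(hill$mass_fractions)] *
                     hill$mass_fractions), 1)

  mk_act <- function(aI, aIIa, aIIb, n = 2000) {
    out <- data.frame(t = (seq_len(n) - 1) * 0.001, a_I = aI, a_IIa = aIIa,
                      a_IIb = aIIb)
    class(out) <- c("activation_trace", "data.frame")
    out
  }
  # zero activation -> zero force; full activation -> f_max within 0.5%
  expect_equal(max(activation_to_force(mk_act(0, 0, 0), hill)$force), 0)
  f_full <- activation_to_force(mk_act(1, 1, 1), hill)$force
  expect_equal(tail(f_full, 1), 500, tolerance = 0.005)

  # hand-computed weighted product for a single active type
  f_half <- activation_to_force(mk_act(0.5, 0, 0), hill)$force
  expected <- 500 * hill$gains[["I"]] * hill$mass_fractions[["I"]] * 0.5
  expect_equal(tail(f_half, 1), expected, tolerance = 1e-6)

  # monotone in any single fiber-type activation
  f_more <- activation_to_force(mk_act(0.7, 0, 0), hill)$force
  expect_true(tail(f_more, 1) > tail(f_half, 1))

  expect_error(activation_to_force(mk_act(1, 1, 1), hill_params(
    mass_fractions = c(I = 0.7, IIa = 0.2, IIb = 0.1))), "f_max")
})

test_that("MVC calibration reproduces the subject maximum and is linear", {
  pool <- build_pool(pool_spec(n_neurons = 30))
  gain <- calibrate_gain(pool)
  cal <- calibrate_mvc(hill_params(pool = pool), pool, 400, gain)
  expect_equal(cal$report$ratio, 0.6, tolerance = 0.02)

  # closed loop: steady saturating drive reproduces the MVC force +/- 2%
  sp <- simulate_pool(pool, pool_input(1 / 0.6, gain_nA = gain),
                      dt_ms = 0.05, t_end = 2.5)
  act <- spikes_to_activation(sp, pool, cal$ca, dt = 0.001)
  f <- activation_to_force(act, cal$hill)
  expect_equal(mean(f$force[f$t > 1.5]), 400, tolerance = 0.02)

  # doubling the target MVC doubles the calibrated maximum exactly
  cal2 <- calibrate_mvc(hill_params(pool = pool), pool, 800, gain)
  expect_equal(cal2$hill$f_max, 2 * cal$hill$f_max, tolerance = 1e-6)

  # idempotence (also across a cache reset)
  expect_identical(calibrate_mvc(hill_params(pool = pool), pool, 400, gain),
                   cal)
})

test_that("aggregate variability shrinks with the number of active units", {
  # matched mean drive: n units at the same rate; the twitch-weighted mean
  # activation of a larger population fluctuates less (uncorrelated spike
  # timing cancels out)
  cov_of <- function(n_active, seed0) {
    pool <- build_pool(pool_spec(n_neurons = n_active, twitch_ratio = 1.0001))
    sp <- fake_spikes(lapply(seq_len(n_active), function(i)
      poisson_train(15, 4, seed = seed0 + i)), t_end = 4)
    act <- spikes_to_activation(sp, pool, calcium_params(hill_K = 3),
                                dt = 0.001)
    a <- act$a_I[act$t > 1]
    sd(a) / mean(a)
  }
  expect_gt(cov_of(8, 100), cov_of(64, 200))
})

test_that("type IIb activation is more dispersed than type I at matched drive", {
  # 146 type-I units vs 12 IIb units in the standard pool: same per-unit
  # Poisson rate, aggregate IIb trace has the larger relative variability
  pool <- build_pool(pool_spec(n_neurons = 200))
  sp <- fake_spikes(lapply(1:200, function(i) poisson_train(12, 3, seed = i)),
                    t_end = 3)
  act <- spikes_to_activation(sp, pool, calcium_params(hill_K = 2), dt = 0.001)
  keep <- act$t > 1
  cov_I <- sd(act$a_I[keep]) / mean(act$a_I[keep])
  cov_IIb <- sd(act$a_IIb[keep]) / mean(act$a_IIb[keep])
  expect_gt(cov_IIb, cov_I)
})

test_that("force CSV round-trips", {
  f <- force_from_vector(c(0, 10, 20, 20, 10, 0))
  path <- tempfile(fileext = ".csv")
  write_force_csv(f, path)
  back <- read_force_csv(path)
  expect_equal(back$force, f$force, tolerance = 1e-6)
  expect_equal(back$t, f$t, tolerance = 1e-6)
})
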