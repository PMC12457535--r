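test_that("the parameter registry is complete and self-consistent", {
  reg <- param_registry()
  expect_equal(nrow(reg), 37)
  expect_equal(sum(reg$significant), 16)
  expect_equal(sort(unique(reg$compartment)),
               c("dendrite", "hillock", "initial_segment", "nmj", "soma"))

  # every accessor resolves and round-trips through set/get
  ch <- channel_defaults(); ca <- calcium_params()
  for (acc in reg$accessor) {
    v <- nmspool:::get_param(ch, ca, acc)
    expect_true(is.numeric(v) && length(v) == 1, info = acc)
    upd <- nmspool:::set_param(ch, ca, acc, v * 1.2)
    expect_equal(nmspool:::get_param(upd$channels, upd$ca, acc), v * 1.2,
                 info = acc)
  }
  expect_error(nmspool:::get_param(ch, ca, "soma.g_nonexistent"), "unknown")
})

make_tiny_scenario <- function(n = 8) {
  pool <- build_pool(pool_spec(n_neurons = n))
  gain <- calibrate_gain(pool)
  t <- seq(0, 1.6, by = 0.01)
  drive <- approx(c(0, 0.5, 1.1, 1.6), c(0, 1, 1, 0), xout = t)$y
  csi <- structure(data.frame(t = t, drive = drive),
                   class = c("csi_signal", "data.frame"))
  sweep_scenario(pool, csi, gain, noise_model(seed = 7),
                 calcium_params(hill_K = 2), plateau = c(0.6, 1.0),
                 dt_ms = 0.05)
}

test_that("the zero level is the exact identity perturbation", {
  sc <- make_tiny_scenario()
  res <- run_sweep("soma.g_kdr", sc, levels = c(-10, 0, 10))
  zero <- res[res$level_pct == 0, ]
  expect_equal(zero$delta_discharge_pct, 0)
  expect_equal(zero$delta_a_I, 0)
  expect_false(any(res$failed))
  expect_equal(nrow(res), 3)
})

test_that("sweeps use common random numbers and are reproducible", {
  sc <- make_tiny_scenario()
  r1 <- run_sweep("nmj.k2", sc, levels = c(-20, 0, 20))
  r2 <- run_sweep("nmj.k2", sc, levels = c(-20, 0, 20))
  expect_identical(r1$delta_a_I, r2$delta_a_I)
  # NMJ perturbations reuse the baseline pool spikes: no discharge change
  expect_equal(r1$delta_discharge_pct, c(0, 0, 0))
  # but they do move activation
  expect_false(all(r1$delta_a_I == 0))
})

test_that("sweep report ranks by maximal absolute effect and keeps NAs", {
  mk <- function(acc, deltas, failed = FALSE) {
    out <- data.frame(level_pct = c(-5, 0, 5),
                      delta_discharge_pct = deltas,
                      delta_a_I = 0, delta_a_IIa = 0, delta_a_IIb = 0,
                      failed = failed)
    attr(out, "accessor") <- acc
    class(out) <- c("sweep_result", "data.frame")
    out
  }
  results <- list(
    "soma.g_kdr" = mk("soma.g_kdr", c(-2, 0, 8)),
    "soma.g_leak" = mk("soma.g_leak", c(-30, 0, 12)),
    "soma.cm" = mk("soma.cm", c(NA, 0, NA), failed = c(TRUE, FALSE, TRUE)))
  rep <- sweep_report(results)
  expect_equal(rep$ranking$parameter[1], "soma.g_leak")
  expect_equal(rep$ranking$max_abs_delta_pct[1], 30)
  expect_equal(rep$ranking$parameter[2], "soma.g_kdr")
  # the failed parameter's ranking uses its only measured level (the
  # zero-level identity), not the missing ones
  expect_equal(rep$ranking$max_abs_delta_pct[3], 0)
  expect_equal(rep$ranking$n_failed_levels[3], 2)

  # failed levels appear as missing, never as zero
  long <- rep$long
  failed_rows <- long[long$parameter == "soma.cm" & long$level_pct != 0 &
                        long$metric == "discharge_pct", ]
  expect_true(all(is.na(failed_rows$delta_pct)))

  csv <- tempfile(fileext = ".csv")
  write_sweep_csv(rep, csv)
  expect_true(file.exists(csv))
})
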