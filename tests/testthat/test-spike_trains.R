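test_that("quality filter applies the PNR and ISI rules", {
  low_pnr <- periodic_mu("A", pnr = 25)
  clean <- periodic_mu("B", isi = 0.1, n = 21, pnr = 35)
  # ISIs 10, 100, 100 ms: one flagged, 2 valid < 10 required
  short_isi <- mu_spike_train("C", c(0, 0.010, 0.110, 0.210), 35)
  dec <- mu_decomposition(list(low_pnr, clean, short_isi), duration = 21)
  out <- filter_mus(dec)
  expect_equal(vapply(out$mus, `[[`, character(1), "mu_id"), "B")
  expect_identical(out$mus[[1]]$discharge_times, clean$discharge_times)
  reasons <- vapply(attr(out, "filter_log"), `[[`, character(1), "reason")
  expect_true("pnr_low" %in% reasons)
  expect_true("too_few_valid_isis" %in% reasons)
  expect_true("isi_out_of_range" %in% reasons)
})

test_that("filtering everything raises an error naming the filter", {
  dec <- mu_decomposition(list(periodic_mu("A", pnr = 20),
                               periodic_mu("B", pnr = 10)))
  expect_error(filter_mus(dec), "no valid MUs.*pnr")
})

test_that("quality filtering is idempotent", {
  for (seed in 1:5) {
    dec <- toy_decomp(n_mus = 5, seed = seed)
    once <- filter_mus(dec)
    twice <- filter_mus(once)
    expect_equal(twice$n_mus, once$n_mus)
    expect_equal(lapply(twice$mus, `[[`, "discharge_times"),
                 lapply(once$mus, `[[`, "discharge_times"))
    expect_length(attr(twice, "filter_log"), 0)
  }
})

test_that("CST is the sorted multiset union and conserves spike counts", {
  a <- mu_spike_train("A", c(0.1, 0.2), 35)
  b <- mu_spike_train("B", c(0.15, 0.3), 35)
  cst <- build_cst(mu_decomposition(list(a, b)))
  expect_equal(cst$spike_times, c(0.1, 0.15, 0.2, 0.3))
  expect_equal(cst$n_sources, 2)

  single <- build_cst(mu_decomposition(list(a)))
  expect_equal(single$spike_times, a$discharge_times)

  dec <- mu_decomposition(lapply(1:3, function(i)
    mu_spike_train(i, seq(0.05 * i, by = 0.13, length.out = 10), 35)))
  expect_length(build_cst(dec)$spike_times, 30)

  for (seed in 1:5) {
    dec <- toy_decomp(seed = seed)
    expect_length(build_cst(dec)$spike_times,
                  sum(vapply(dec$mus, function(m)
                    length(m$discharge_times), integer(1))))
  }
})

test_that("windowed CST counts match a brute-force recomputation", {
  # constant counts give zero STD
  cst <- build_cst(mu_decomposition(list(periodic_mu(isi = 0.05, n = 60))))
  ws <- cst_window_stats(cst, 0.5, t_start = 0, t_end = 2.95)
  expect_equal(ws$std, 0)
  expect_true(all(ws$counts == 10))

  # direct formula on a hand-made count pattern {8, 10, 12}
  times <- c(seq(0, by = 0.49 / 7, length.out = 8),
             0.5 + seq(0, by = 0.49 / 9, length.out = 10),
             1.0 + seq(0, by = 0.49 / 11, length.out = 12))
  cst2 <- build_cst(mu_decomposition(list(
    mu_spike_train("X", sort(times), 35)), duration = 1.5))
  ws2 <- cst_window_stats(cst2, 0.5)
  expect_equal(ws2$counts, c(8, 10, 12))
  expect_equal(ws2$std, sqrt(mean((c(8, 10, 12) - 10)^2)))

  expect_error(cst_window_stats(cst2, 0.5, t_end = 0.3), "shorter")

  # random instances against explicit enumeration
  for (seed in 1:20) {
    dec <- toy_decomp(n_mus = 3, dur = 6.3, seed = seed)
    cst3 <- build_cst(dec)
    ws3 <- cst_window_stats(cst3, 0.5)
    n_win <- floor(6.3 / 0.5)
    brute <- vapply(seq_len(n_win) - 1, function(k)
      sum(cst3$spike_times >= k * 0.5 & cst3$spike_times < (k + 1) * 0.5),
      numeric(1))
    expect_equal(ws3$counts, brute)
    expect_equal(ws3$std, sqrt(mean((brute - mean(brute))^2)))
  }
})

test_that("ISI CoV follows the population formula and the ISI bounds", {
  expect_equal(isi_cov(periodic_mu(isi = 0.1, n = 30)), 0)

  # ISIs 80, 100, 120 ms repeated to pass the minimum-count rule
  times <- cumsum(c(0, rep(c(0.08, 0.10, 0.12), 5)))
  mu <- mu_spike_train("X", times, 35)
  isis <- rep(c(80, 100, 120), 5)
  expect_equal(isi_cov(mu),
               100 * sqrt(mean((isis - mean(isis))^2)) / mean(isis))

  # a 300-ms ISI inside the region is excluded before computing
  times2 <- c(times, max(times) + 0.3, max(times) + 0.4)
  mu2 <- mu_spike_train("Y", times2, 35)
  expect_equal(isi_cov(mu2),
               100 * sqrt(mean((c(isis, 100) - mean(c(isis, 100)))^2)) /
                 mean(c(isis, 100)))

  # scale invariance: multiplying all ISIs by c > 0 keeps CoV (within bounds)
  base <- cumsum(c(0, rep(c(0.05, 0.06, 0.07), 6)))
  cov1 <- isi_cov(mu_spike_train("Z", base, 35))
  cov2 <- isi_cov(mu_spike_train("Z", base * 2, 35))
  expect_equal(cov1, cov2)

  short <- mu_spike_train("W", c(0, 0.1, 0.2), 35)
  out <- isi_cov(short)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "valid ISIs")
})

test_that("smoothed CST rate conserves spike count and tracks the mean", {
  # stationary gamma CST near 100 pulses/s over 30 s
  dec <- mu_decomposition(lapply(1:10, function(i)
    gamma_mu(i, rate = 10, cov = 0.2, dur = 30, seed = i)), duration = 30)
  cst <- build_cst(dec)
  sm <- smoothed_cst_rate(cst, fs_out = 100, fir_cutoff = 2)
  n_spk <- length(cst$spike_times)
  expect_lt(abs(sum(sm$rate) * 0.01 - n_spk) / n_spk, 0.01)
  expect_lt(abs(mean(sm$rate) - n_spk / 30) / (n_spk / 30), 0.02)
  expect_true(all(sm$rate >= 0))

  # silence stays at zero rate
  quiet <- build_cst(mu_decomposition(list(
    mu_spike_train("Q", c(28, 28.5, 29, 29.5), 35)), duration = 30))
  sm2 <- smoothed_cst_rate(quiet, fs_out = 100, fir_cutoff = 2)
  expect_equal(sm2$rate[sm2$t < 20], rep(0, sum(sm2$t < 20)), tolerance = 1e-8)

  expect_error(smoothed_cst_rate(cst, fs_out = 100, fir_cutoff = 60),
               "Nyquist")
})

test_that("spike CSV and JSON round-trip the decomposition", {
  dec <- toy_decomp(n_mus = 3)
  csv <- tempfile(fileext = ".csv")
  write_spike_csv(dec, csv)
  back <- read_spike_csv(csv, duration = dec$duration)
  expect_equal(back$n_mus, dec$n_mus)
  expect_equal(lapply(back$mus, `[[`, "discharge_times"),
               lapply(dec$mus, `[[`, "discharge_times"),
               tolerance = 1e-6)

  js <- tempfile(fileext = ".json")
  write_spike_json(dec, js)
  back2 <- read_spike_json(js)
  expect_equal(back2$n_mus, dec$n_mus)
  expect_equal(back2$mus[[2]]$discharge_times,
               dec$mus[[2]]$discharge_times)

  log <- tempfile(fileext = ".jsonl")
  filtered <- filter_mus(mu_decomposition(list(periodic_mu("A"),
                                               periodic_mu("B", pnr = 12))))
  write_filter_log(filtered, log)
  expect_equal(length(readLines(log)), 1L)
})
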