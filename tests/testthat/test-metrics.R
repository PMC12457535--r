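test_that("steadiest window matches exhaustive search", {
  # constant force: tie broken to the earliest start
  f <- force_from_vector(rep(10, 300))
  w <- steadiest_window(f, 0.5)
  expect_equal(w$start_s, 0)
  expect_equal(w$std, 0)

  # noisy first half, quiet second half
  x <- c(10 + sin(1:150), rep(10, 150))
  w2 <- steadiest_window(force_from_vector(x), 0.5)
  expect_gte(w2$start_s, 1.49)

  # window equal to the full (restricted) record
  f3 <- force_from_vector(c(5, 7, 9, 9, 7, 5), dt = 0.5)
  w3 <- steadiest_window(f3, 3)
  expect_equal(w3$idx, c(1, 6))

  # random instances against brute force, including plateau restriction
  for (seed in 1:100) {
    x <- with_seed(seed, function() rnorm(200, 50, 5))
    f4 <- force_from_vector(x, dt = 0.01)
    w4 <- steadiest_window(f4, 0.25)
    wlen <- 25
    brute <- vapply(seq_len(200 - wlen + 1), function(s) {
      v <- x[s:(s + wlen - 1)]
      sqrt(mean((v - mean(v))^2))
    }, numeric(1))
    expect_equal(w4$idx[1], which.min(brute))
    expect_equal(w4$std, min(brute), tolerance = 1e-10)
  }

  expect_error(steadiest_window(force_from_vector(rep(1, 10)), 5), "shorter")
})

test_that("force statistics follow the population formulas", {
  f <- force_from_vector(c(10, 10, 10))
  s <- force_stats(f, c(0, 1))
  expect_equal(s$std, 0)
  expect_equal(s$cov_pct, 0)

  f2 <- force_from_vector(c(99, 100, 101))
  s2 <- force_stats(f2, c(0, 1))
  expect_equal(s2$std, sqrt(2 / 3))
  expect_equal(s2$cov_pct, 100 * sqrt(2 / 3) / 100)

  # homogeneity: scaling the force scales STD, leaves CoV unchanged
  s3 <- force_stats(force_from_vector(7 * c(99, 100, 101)), c(0, 1))
  expect_equal(s3$std, 7 * s2$std)
  expect_equal(s3$cov_pct, s2$cov_pct)

  s4 <- force_stats(force_from_vector(c(-1, 0, 1)), c(0, 1))
  expect_true(is.na(s4$cov_pct))
  expect_match(attr(s4$cov_pct, "reason"), "undefined")
})

test_that("RMSE and R2 behave like their definitions", {
  e <- force_from_vector(50 + sin(seq(0, 6, 0.01)) * 10,
                         source = "experimental")
  expect_equal(rmse_r2(e, e), list(rmse = 0, r2 = 1))

  shifted <- e; shifted$force <- e$force + 2
  fit <- rmse_r2(shifted, e)
  expect_equal(fit$rmse, 2)
  expect_lt(fit$r2, 1)

  flat <- e; flat$force <- rep(mean(e$force), nrow(e))
  expect_equal(rmse_r2(flat, e)$r2, 0)

  const <- force_from_vector(rep(5, 100))
  out <- rmse_r2(e[1:100, ], const)
  expect_true(is.na(out$r2))

  # rmse is symmetric, r2 is reference-dependent
  a <- force_from_vector(with_seed(1, function() rnorm(100, 20)))
  b <- force_from_vector(with_seed(2, function() rnorm(100, 20, 3)))
  expect_equal(rmse_r2(a, b)$rmse, rmse_r2(b, a)$rmse)
  expect_false(isTRUE(all.equal(rmse_r2(a, b)$r2, rmse_r2(b, a)$r2)))

  # landmark-anchored alignment: a compressed trapezoid matches its
  # full-length self after the piecewise time warp
  pr <- target_profile(60, 170)
  full <- make_trapezoid(pr, dt = 0.01)
  comp <- make_trapezoid(pr, dt = 0.01, compressed = TRUE)
  sim <- data.frame(t = comp$t, force = comp$newtons)
  class(sim) <- c("force_profile", "data.frame")
  attr(sim, "landmarks") <- attr(comp, "landmarks")
  ref <- data.frame(t = full$t, force = full$newtons)
  class(ref) <- c("force_profile", "data.frame")
  attr(ref, "landmarks") <- attr(full, "landmarks")
  fit2 <- rmse_r2(sim, ref)
  expect_lt(fit2$rmse, 1e-8)
  expect_equal(fit2$r2, 1)
})

test_that("z-score median correlation recovers perfect and inverted order", {
  sims <- list(c(1, 2), c(3, 4), c(5, 7), c(8, 9))
  zc <- zscore_median_correlation(sims, sims)
  expect_equal(zc$r, 1)

  anti <- zscore_median_correlation(list(1:2, 3:4, 5:6),
                                    list(6:7, 3:4, 0:1))
  expect_equal(anti$r, -1)

  expect_error(zscore_median_correlation(list(1:2, 3:4), list(1:2, 3:4)),
               "3 subjects")
})

test_that("variability t test matches the textbook formula and sign", {
  expect_equal(variability_ttest(c(1, 2, 3), c(1, 2, 3),
                                 alternative = "two.sided")$t, 0)

  # Welch statistic for {1,2,3} vs {2,3,4}: t = -1 / sqrt(2/3)
  tt <- variability_ttest(c(1, 2, 3), c(2, 3, 4),
                          alternative = "two.sided")
  expect_equal(tt$t, -1 / sqrt(2 / 3))

  # simulated smaller than experimental on average -> negative statistic
  expect_lt(variability_ttest(c(0.8, 0.9, 1.0), c(1.2, 1.3, 1.4))$t, 0)
  expect_error(variability_ttest(1, c(1, 2)), "at least 2")
})

test_that("closed-loop self-validation is exact", {
  f <- force_from_vector(50 + cos(seq(0, 10, 0.01)))
  rep <- agreement_report(f, f, sim_window_s = 1, exp_window_s = 1)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$r2, 1)
  expect_equal(rep$std_sim, rep$std_exp)
  expect_match(rep$note, "unavailable")

  multi <- list(sim_force_stds = c(1, 2, 3), exp_force_stds = c(1, 2, 3),
                sim_force_covs = c(1, 2, 3), exp_force_covs = c(1, 2, 3))
  rep2 <- agreement_report(f, f, sim_window_s = 1, exp_window_s = 1,
                           multi = multi)
  expect_equal(unname(rep2$ttest_std["t"]), 0)
  expect_equal(unname(rep2$ttest_cov["t"]), 0)

  path <- tempfile(fileext = ".json")
  write_agreement_json(rep2, path)
  x <- jsonlite::fromJSON(path)
  expect_equal(x$r2, 1)
})
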