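test_that("task_schedule has the standard flanker layout", {
  sched <- task_schedule(seed = 2L)
  expect_equal(nrow(sched), 120L)
  expect_equal(unname(table(sched$type)[c("congruent", "incongruent", "neutral")]),
               rep(40L, 3), ignore_attr = TRUE)
  expect_equal(diff(sched$onset_ms), rep(2000, 119))
  expect_equal(attr(sched, "duration_ms"), 240000)
  # permutation is seeded
  expect_equal(task_schedule(seed = 2L)$type, sched$type)
  expect_false(identical(task_schedule(seed = 3L)$type, sched$type))
})

test_that("simulate_recording plants recoverable bouts", {
  sched <- task_schedule(n_per_type = 1, seed = 1L)

  # occupancy 0 + no noise: derivative identically zero
  still <- fidget_profile(bout_occupancy = 0, noise_sd = 0)
  rec <- simulate_recording(still, sched, 100, seed = 1)
  expect_equal(max(abs(differentiate(rec)$axes)), 0)
  # conservation: length = schedule duration x sample rate
  expect_equal(nrow(rec$axes), 100 * 6)

  # a 5 Hz bout filling one 2 s trial: exactly 10 local maxima there
  prof <- fidget_profile(bout_frequency_hz = 5, bout_amplitude = 1,
                         bout_occupancy = c(1, 0, 0), noise_sd = 0)
  rec <- simulate_recording(prof, sched, 500, seed = 1)
  mov <- differentiate(rec)
  m <- compute_fidget_metrics(detect_peaks(mov, 0.5)$x, c(0, 2000))
  expect_equal(m$n_fidgets, 10)
  expect_equal(m$variability_ms2, 0)
  expect_equal(m$intensity, 1)
  # bare-array cross-check with the brute-force scan
  expect_equal(length(oracle_peaks(mov$axes[1:1000, "x"])), 10L)

  # determinism: identical seed and arguments give identical samples
  noisy <- fidget_profile(bout_occupancy = 0.4, noise_sd = 0.1)
  r1 <- simulate_recording(noisy, sched, 100, seed = 9)
  r2 <- simulate_recording(noisy, sched, 100, seed = 9)
  expect_identical(r1$axes, r2$axes)
  r3 <- simulate_recording(noisy, sched, 100, seed = 10)
  expect_false(identical(r1$axes, r3$axes))

  # spectral placement: noiseless bout frequency is the spectral argmax
  pure <- fidget_profile(bout_frequency_hz = 6, bout_occupancy = 1,
                         noise_sd = 0)
  spec <- spectrum_table(differentiate(simulate_recording(pure, sched, 100,
                                                          seed = 1)))
  sx <- spec[spec$axis == "x", ]
  expect_equal(sx$frequency_hz[which.max(sx$magnitude)], 6, tolerance = 0.05)

  expect_error(simulate_recording(pure, sched, 10, seed = 1), "Nyquist")
  expect_error(fidget_profile(bout_amplitude = -1), "positive")
  expect_error(fidget_profile(bout_frequency_hz = 30), "inside the analysis band")
})

test_that("simulate_calibration produces the three regimes", {
  # stationary with zero noise: all-zero derivative
  quiet <- fidget_profile(noise_sd = 0)
  rec <- simulate_calibration("stationary", duration_s = 5, seed = 1,
                              profile = quiet, sample_rate_hz = 100)
  expect_equal(max(abs(differentiate(rec)$axes)), 0)

  # simulated fidgeting at 5 Hz: the 5 Hz bin dominates all out-of-band bins
  prof <- fidget_profile(bout_frequency_hz = 5, noise_sd = 0.05)
  fid <- simulate_calibration("simulated_fidget", duration_s = 10, seed = 2,
                              profile = prof, sample_rate_hz = 200)
  spec <- spectrum_table(differentiate(fid))
  sx <- spec[spec$axis == "x", ]
  in_peak <- max(sx$magnitude[abs(sx$frequency_hz - 5) < 0.5])
  out_band <- max(sx$magnitude[sx$frequency_hz < 1 | sx$frequency_hz > 20])
  expect_gt(in_peak, out_band)

  # rapid movement: smaller in-band/out-of-band energy ratio than fidgeting
  # (Parseval lets energy be summed in the frequency domain)
  rapid <- simulate_calibration("rapid", duration_s = 10, seed = 2,
                                profile = prof, sample_rate_hz = 200)
  ratio <- function(r) {
    s <- spectrum_table(differentiate(r))
    s <- s[s$axis == "x", ]
    inb <- s$frequency_hz >= 1 & s$frequency_hz <= 20
    sum(s$magnitude[inb]^2) / sum(s$magnitude[!inb]^2)
  }
  expect_lt(ratio(rapid), ratio(fid))
  # and out-of-band energy exceeds the simulated-fidget case
  out_energy <- function(r) {
    s <- spectrum_table(differentiate(r))
    s <- s[s$axis == "x", ]
    sum(s$magnitude[s$frequency_hz > 20]^2)
  }
  expect_gt(out_energy(rapid), out_energy(fid))

  expect_error(simulate_calibration("jogging", 5), "arg")
})

test_that("simulate_reaction_times draws from the ex-Gaussian with omissions", {
  # Gaussian limit: tau -> 0+ gives sample mean ~ mu within 3 sigma / sqrt(n)
  rt <- simulate_reaction_times(list(mu = 400, sigma = 50, tau = 1e-6),
                                4000, 0, seed = 1)
  expect_lt(abs(mean(rt$rt_ms) - 400), 3 * 50 / sqrt(4000))

  # closed-form mean mu + tau at the published parameter scale
  rt <- simulate_reaction_times(list(mu = 369.3, sigma = 51.9, tau = 70.0),
                                1e5, 0, seed = 2)
  expect_lt(abs(mean(rt$rt_ms) - 439.3) / 439.3, 0.01)
  # variance identity sigma^2 + tau^2 within Monte-Carlo error
  expect_lt(abs(var(rt$rt_ms) - (51.9^2 + 70^2)) / (51.9^2 + 70^2), 0.03)

  # omission count within the Binomial(1000, 0.5) 99% interval
  rt <- simulate_reaction_times(list(mu = 400, sigma = 50, tau = 60),
                                1000, 0.5, seed = 3)
  expect_true(all(is.na(rt$rt_ms[rt$omitted])))
  expect_gte(sum(rt$omitted), qbinom(0.005, 1000, 0.5))
  expect_lte(sum(rt$omitted), qbinom(0.995, 1000, 0.5))

  expect_error(simulate_reaction_times(list(mu = 1, sigma = 0, tau = 1), 10),
               "positive")
  expect_error(simulate_reaction_times(list(mu = 1, sigma = 1, tau = 1), 10,
                                       omission_rate = 1), "omission_rate")
})

test_that("simulate_participants couples scales to fidget predictors", {
  preds <- c("arm_n", "arm_var", "arm_int", "leg_n", "leg_var", "leg_int")
  coup <- list(baars = c(1, 0.02, 2, 1, 0.02, 2),
               bdefs_sec5 = rep(0, 6), ari = rep(0, 6))

  # zero noise + no clipping: the fit is exact, R = 1
  cohort <- simulate_participants(50, coupling = coup, noise_sd = 0, seed = 4)
  fit <- fit_linear_model(cohort[preds], cohort$baars)
  expect_equal(fit$R, 1, tolerance = 1e-6)

  # totals always inside the legal ranges
  cohort <- simulate_participants(200, noise_sd = 20, seed = 5)
  expect_true(all(cohort$baars >= 18 & cohort$baars <= 72))
  expect_true(all(cohort$bdefs_sec5 >= 13 & cohort$bdefs_sec5 <= 52))
  expect_true(all(cohort$ari >= 0 & cohort$ari <= 12))

  # determinism and the size precondition
  expect_identical(simulate_participants(10, seed = 6),
                   simulate_participants(10, seed = 6))
  expect_error(simulate_participants(7), "n >= 8")
})

test_that("null cohorts give mean R^2 near p/(n-1)", {
  # 200 seeded replicates, 6 null predictors, n = 70: E[R^2] = 6/69
  r2 <- vapply(1:200, function(s) {
    cohort <- simulate_participants(70, noise_sd = 4, seed = s)
    fit_linear_model(cohort[c("arm_n", "arm_var", "arm_int",
                              "leg_n", "leg_var", "leg_int")],
                     cohort$baars)$r_squared
  }, 0)
  expect_equal(mean(r2), 6 / 69, tolerance = 0.15)
  expect_lt(abs(mean(r2) - 6 / 69), 0.012)
})
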