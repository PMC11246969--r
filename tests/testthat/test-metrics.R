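test_that("detect_peaks matches the brute-force scan and handles plateaus", {
  rate <- 500
  t <- (0:999) / rate
  # 2 Hz sine over [0, 2) s has exactly 4 local maxima, heights ~ 1
  pk <- detect_peaks(mk_movement(sin(2 * pi * 2 * t), rate = rate), 0.5)
  expect_equal(nrow(pk$x), 4L)
  expect_true(all(abs(pk$x$height - 1) < 1e-3))
  expect_true(!is.unsorted(pk$x$time_ms, strictly = TRUE))

  expect_equal(nrow(detect_peaks(mk_movement(numeric(100)), 0)$x), 0L)

  # random signals: identical indices to the exhaustive triple-comparison scan
  # (at threshold 0 both routes keep only positive-height maxima)
  set.seed(41)
  for (i in 1:20) {
    s <- rnorm(200)
    pk <- detect_peaks(mk_movement(s, rate = 100), 0)
    idx <- oracle_peaks(s)
    idx <- idx[s[idx] > 0]
    expect_equal(pk$x$time_ms, (idx / 100) * 1000)
    expect_equal(pk$x$height, s[idx])
  }

  # plateau of equal values yields one peak at its first sample
  s <- c(0, 1, 1, 1, 0, 2, 0)
  pk <- detect_peaks(mk_movement(s, rate = 1000), 0)
  expect_equal(pk$x$time_ms, c(2, 6))
  expect_equal(pk$x$height, c(1, 2))

  expect_error(detect_peaks(mk_movement(c(0, 1)), 0), "3 samples")
})

test_that("compute_fidget_metrics: counts, population variance, intensity, NA flags", {
  mk_peaks <- function(time_ms, height = rep(1, length(time_ms))) {
    structure(data.frame(time_ms = time_ms, height = height),
              class = c("peak_series", "data.frame"))
  }
  m <- compute_fidget_metrics(mk_peaks(c(0, 200, 400, 600), rep(2.5, 4)),
                              c(0, 1000))
  expect_equal(m$n_fidgets, 4)
  expect_equal(m$variability_ms2, 0)
  expect_equal(m$intensity, 2.5)

  # intervals {100, 200}: population variance 2500 ms^2
  m <- compute_fidget_metrics(mk_peaks(c(0, 100, 300)), c(0, 1000))
  expect_equal(m$variability_ms2, 2500)

  # < 3 peaks: variability undefined, not zero
  m <- compute_fidget_metrics(mk_peaks(c(0, 100)), c(0, 1000))
  expect_equal(m$n_fidgets, 2)
  expect_true(is.na(m$variability_ms2))
  # no peaks: intensity undefined too
  m <- compute_fidget_metrics(mk_peaks(numeric(0)), c(0, 1000))
  expect_true(is.na(m$intensity))
  # window is half-open [start, end)
  m <- compute_fidget_metrics(mk_peaks(c(0, 500, 1000)), c(0, 1000))
  expect_equal(m$n_fidgets, 2)
})

test_that("peak-count additivity and scaling equivariance", {
  set.seed(51)
  s <- as.numeric(rnorm(400))
  mov <- mk_movement(s, rate = 100)
  pk <- detect_peaks(mov, 0)$x
  span <- c(0, 4001)
  whole <- compute_fidget_metrics(pk, span)$n_fidgets
  cuts <- c(span[1], 1203, 2407, span[2])
  parts <- vapply(1:3, function(i)
    compute_fidget_metrics(pk, cuts[i:(i + 1)])$n_fidgets, 0)
  expect_equal(sum(parts), whole)

  # c * signal with c * threshold: counts/variability unchanged, intensity scaled
  thr <- 0.4
  a <- compute_fidget_metrics(detect_peaks(mov, thr)$x, span)
  mov3 <- mk_movement(3 * s, rate = 100)
  b <- compute_fidget_metrics(detect_peaks(mov3, 3 * thr)$x, span)
  expect_equal(b$n_fidgets, a$n_fidgets)
  expect_equal(b$variability_ms2, a$variability_ms2)
  expect_equal(b$intensity, 3 * a$intensity)
})

test_that("combine_sensors follows the arm+leg summation convention", {
  arm <- fidget_metrics(2.1, 131.3, 0.1)
  leg <- fidget_metrics(2.6, 135.5, 0.5)
  both <- combine_sensors(arm, leg)
  expect_equal(both$n_fidgets, 4.7)
  expect_equal(both$intensity, 0.6)
  # (the published table prints 266.9 for this row; its own addends sum to
  # 266.8 — a rounding artifact of the printed means)
  expect_equal(both$variability_ms2, 266.8, tolerance = 1e-12)

  # additive identity, commutativity, associativity
  zero <- fidget_metrics(0, 0, 0)
  expect_equal(combine_sensors(arm, zero), arm)
  expect_equal(combine_sensors(arm, leg), combine_sensors(leg, arm))
  c3 <- fidget_metrics(1, 10, 0.2)
  expect_equal(combine_sensors(combine_sensors(arm, leg), c3),
               combine_sensors(arm, combine_sensors(leg, c3)))

  # undefined on one sensor is dropped, on both stays undefined
  na_leg <- fidget_metrics(0, NA, NA)
  expect_equal(combine_sensors(arm, na_leg)$variability_ms2, 131.3)
  expect_true(is.na(combine_sensors(na_leg, na_leg)$intensity))
})

test_that("epoch_metrics scores each trial and matches the per-window path", {
  sched <- task_schedule(seed = 3L)
  # bouts only in the last 30 trials
  occ <- c(rep(0, 90), rep(0.5, 30))
  prof <- fidget_profile(bout_frequency_hz = 4, bout_occupancy = occ,
                         noise_sd = 0.02)
  rec <- simulate_recording(prof, sched, 100, seed = 5)
  filt <- band_reconstruct(differentiate(rec), frequency_band(1, 20))
  em <- epoch_metrics(filt, sched, threshold = 0.2)
  expect_equal(nrow(em), 120L)
  expect_equal(em$trial_index, 1:120)
  expect_gt(mean(em$n_fidgets[91:120]), mean(em$n_fidgets[1:30]))

  # dual route: vectorized table vs per-window compute_fidget_metrics
  pk <- detect_peaks(filt, 0.2)
  for (i in c(1, 45, 95, 120)) {
    w <- sched$onset_ms[i] + c(0, 2000)
    ax <- lapply(pk, compute_fidget_metrics, window = w)
    expect_equal(em$n_fidgets[i], sum(vapply(ax, `[[`, 0, "n_fidgets")))
    expect_equal(em$intensity[i],
                 fidgetr:::.sum_defined(vapply(ax, `[[`, 0, "intensity")))
    expect_equal(em$variability_ms2[i],
                 fidgetr:::.sum_defined(vapply(ax, `[[`, 0, "variability_ms2")))
  }

  # flat signal -> all counts zero
  quiet <- mk_movement(numeric(24000), rate = 100)
  em0 <- epoch_metrics(quiet, sched, threshold = 0)
  expect_true(all(em0$n_fidgets == 0))

  # events outside the recording span are rejected
  bad <- sched
  bad$onset_ms <- bad$onset_ms + 1e6
  expect_error(epoch_metrics(filt, bad), "outside the recording span")
})

test_that("combine_sensor_tables and aggregate_metrics", {
  sched <- task_schedule(n_per_type = 2, seed = 7L)
  prof <- fidget_profile(bout_occupancy = 0.5, noise_sd = 0.05)
  mk <- function(seed, site) {
    rec <- simulate_recording(prof, sched, 100, seed = seed, sensor_site = site)
    epoch_metrics(band_reconstruct(differentiate(rec), frequency_band(1, 20)),
                  sched, threshold = 0.1)
  }
  arm <- mk(1, "wrist"); leg <- mk(2, "ankle")
  both <- combine_sensor_tables(arm, leg)
  expect_equal(both$n_fidgets, arm$n_fidgets + leg$n_fidgets)
  expect_equal(both$sensor_site, rep("arm+leg", 6))

  # aggregation vs hand-rolled mean/SD oracle, skipping undefined values
  agg <- aggregate_metrics(both)
  v <- both$variability_ms2[!is.na(both$variability_ms2)]
  row <- agg[agg$variable == "variability_ms2", ]
  expect_equal(row$mean, mean(v), tolerance = 1e-12)
  expect_equal(row$sd, sd(v), tolerance = 1e-12)
  expect_equal(row$n, length(v))

  one <- aggregate_metrics(both, subset = 3L)
  expect_equal(one$mean[one$variable == "n_fidgets"], both$n_fidgets[3])

  same <- both
  same$n_fidgets <- 5
  agg <- aggregate_metrics(same)
  expect_equal(agg$mean[agg$variable == "n_fidgets"], 5)
  expect_equal(agg$sd[agg$variable == "n_fidgets"], 0)

  expect_error(aggregate_metrics(both, subset = integer(0)), "empty")
})
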