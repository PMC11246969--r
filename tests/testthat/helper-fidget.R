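# shared fixtures and independent oracles

# movement signal straight from per-axis sample vectors (uniform grid)
mk_movement <- function(x, y = 0 * x, z = 0 * x, rate = 500,
                        site = "wrist") {
  t <- seq_along(x) / rate
  fidgetr:::new_movement_signal(t, cbind(x = x, y = y, z = z), site, rate)
}

# brute-force local-maximum scan: strict triple comparison (no plateaus)
oracle_peaks <- function(s) {
  idx <- integer(0)
  for (i in 2:(length(s) - 1L))
    if (s[i] > s[i - 1L] && s[i] > s[i + 1L]) idx <- c(idx, i)
  idx
}

# forward-difference oracle
oracle_diff <- function(s, rate) {
  out <- numeric(length(s) - 1L)
  for (i in seq_len(length(s) - 1L)) out[i] <- (s[i + 1L] - s[i]) * rate
  out
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# one participant's Q1/Q4 mean number-of-fidgets through the full pipeline;
# delta is the mean within-participant Q4 occupancy increase.
# threshold must clear not only the stationary noise floor (3 x band-limited
# noise SD ~ 0.09 here) but also the slow spectral-leakage ripple of the
# untapered per-session filter (~ 5-20% of bout amplitude): below it, counts
# track the leakage beat along the session and the null miscalibrates.
q1q4_participant <- function(seed, delta, sched, rate = 50,
                             occ_mean = 0.25, occ_sd = 0.06,
                             threshold = 0.3) {
  set.seed(seed)
  occ <- rep(pmin(pmax(stats::rnorm(1, occ_mean, occ_sd), 0.05), 0.9),
             nrow(sched))
  d <- stats::rnorm(1, delta, occ_sd)
  q4 <- seq.int(nrow(sched) - 29L, nrow(sched))
  occ[q4] <- pmin(pmax(occ[q4] + d, 0), 1)
  prof <- fidget_profile(bout_frequency_hz = 4, bout_occupancy = occ,
                         noise_sd = 0.05)
  rec <- simulate_recording(prof, sched, rate, seed = seed)
  filt <- band_reconstruct(differentiate(rec), frequency_band(1, 20))
  em <- epoch_metrics(filt, sched, threshold = threshold)
  c(q1 = mean(em$n_fidgets[1:30]), q4 = mean(em$n_fidgets[q4]))
}

# p value of the paired Q4-vs-Q1 comparison for one synthetic cohort
q1q4_cohort_p <- function(seed, n = 40, delta = 0.06, sched = task_schedule()) {
  m <- t(vapply(seq_len(n),
                function(i) q1q4_participant(seed * 1000L + i, delta, sched),
                c(q1 = 0, q4 = 0)))
  compare_groups(m[, "q4"], m[, "q1"], paired = TRUE)$p_value
}
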