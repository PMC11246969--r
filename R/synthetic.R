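#' Fidget profile for the synthetic actigraphy generator
#'
#' Describes the planted movement structure of a synthetic wearer: repetitive
#' in-band fidget bouts superimposed on device noise, optionally with a
#' high-frequency device artifact well above the analysis band.
#'
#' Units are arbitrary "signal units": the amplitude scale of real actigraphs
#' is device-specific, so the generator makes no attempt to mimic one.
#'
#' @param bout_frequency_hz Frequency of the repetitive bout movement, strictly
#'   inside `(band_low, band_high)`. Default 4 Hz — a typical leg-bounce /
#'   table-tap rate.
#' @param bout_amplitude Amplitude of the bout movement (signal units), `> 0`.
#' @param bout_occupancy Fraction of each trial epoch covered by a fidget bout,
#'   in `[0, 1]`; either a scalar or one value per trial.
#' @param noise_sd Baseline white-noise SD on the movement signal, `>= 0`.
#' @param hf_artifact_hz Optional device-artifact frequency, `> band_high`
#'   (`NULL` for none).
#' @param hf_artifact_amplitude Amplitude of the artifact, `>= 0`.
#' @param band_low,band_high The analysis band the bout must sit inside.
#' @return A `fidget_profile` object.
#' @export
fidget_profile <- function(bout_frequency_hz = 4, bout_amplitude = 1,
                           bout_occupancy = 0.3, noise_sd = 0.05,
                           hf_artifact_hz = NULL, hf_artifact_amplitude = 0,
                           band_low = 1, band_high = 20) {
  if (bout_frequency_hz <= band_low || bout_frequency_hz >= band_high)
    stop("bout_frequency_hz must lie strictly inside the analysis band")
  if (bout_amplitude <= 0) stop("bout_amplitude must be positive")
  if (any(bout_occupancy < 0 | bout_occupancy > 1))
    stop("bout_occupancy must be in [0, 1]")
  if (noise_sd < 0 || hf_artifact_amplitude < 0)
    stop("noise and artifact amplitudes must be non-negative")
  if (!is.null(hf_artifact_hz) && hf_artifact_hz <= band_high)
    stop("hf_artifact_hz must exceed the band's high edge")
  structure(list(bout_frequency_hz = bout_frequency_hz,
                 bout_amplitude = bout_amplitude,
                 bout_occupancy = bout_occupancy,
                 noise_sd = noise_sd,
                 hf_artifact_hz = hf_artifact_hz,
                 hf_artifact_amplitude = hf_artifact_amplitude,
                 band_low = band_low, band_high = band_high),
            class = "fidget_profile")
}

#' Flanker task schedule
#'
#' The default session is the standard flanker layout: three trial types
#' (congruent, incongruent, neutral), 40 trials of each for 120 in total, a
#' 1000 ms stimulus preceded by a 1000 ms inter-trial interval, so onsets are
#' spaced 2000 ms apart. Trial order is a seeded permutation.
#'
#' @param n_per_type Trials per type (default 40).
#' @param stimulus_ms,iti_ms Stimulus and inter-trial-interval durations.
#' @param seed Integer seed for the trial-order permutation.
#' @return A `task_schedule`: data.frame with `trial_index`, `type`,
#'   `onset_ms`, plus attributes `stimulus_ms`, `iti_ms` and
#'   `duration_ms` (total session length).
#' @export
task_schedule <- function(n_per_type = 40, stimulus_ms = 1000, iti_ms = 1000,
                          seed = 1L) {
  stopifnot(n_per_type >= 1, stimulus_ms > 0, iti_ms >= 0)
  types <- c("congruent", "incongruent", "neutral")
  order <- with_seed(seed, sample(rep(types, each = n_per_type)))
  n <- 3L * n_per_type
  sched <- data.frame(trial_index = seq_len(n),
                      type = order,
                      onset_ms = (seq_len(n) - 1L) * (stimulus_ms + iti_ms))
  attr(sched, "stimulus_ms") <- stimulus_ms
  attr(sched, "iti_ms") <- iti_ms
  attr(sched, "duration_ms") <- n * (stimulus_ms + iti_ms)
  class(sched) <- c("task_schedule", "data.frame")
  sched
}

# run code under a local RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# movement (derivative) samples for one axis at times t (seconds):
# in-band sinusoidal bouts + optional HF artifact + white noise
synth_movement_axis <- function(t, profile, bout_windows, amplitude_scale = 1,
                                rate = 1 / (t[2L] - t[1L])) {
  n <- length(t)
  m <- numeric(n)
  if (nrow(bout_windows) > 0L) {
    for (i in seq_len(nrow(bout_windows))) {
      a <- bout_windows$start_s[i]; b <- bout_windows$end_s[i]
      # t is the uniform grid i/rate: samples with a <= t < b by index
      i0 <- max(0L, as.integer(ceiling(a * rate - 1e-9)))
      i1 <- min(n - 1L, as.integer(ceiling(b * rate - 1e-9)) - 1L)
      if (i1 < i0) next
      idx <- seq.int(i0, i1)
      m[idx + 1L] <- m[idx + 1L] + amplitude_scale * profile$bout_amplitude *
        sin(2 * pi * profile$bout_frequency_hz * (idx / rate - a))
    }
  }
  if (!is.null(profile$hf_artifact_hz) && profile$hf_artifact_amplitude > 0)
    m <- m + profile$hf_artifact_amplitude *
      sin(2 * pi * profile$hf_artifact_hz * t)
  if (profile$noise_sd > 0)
    m <- m + stats::rnorm(length(t), sd = profile$noise_sd)
  m
}

#' Simulate a task-synchronized actigraphy recording
#'
#' Synthesizes the *movement* (time-derivative) signal first — within each
#' trial's bout window, a sinusoid at `bout_frequency_hz` with the profile's
#' amplitude, phase zero at the bout start — and cumulatively sums it into
#' position samples. Because the analysis pipeline begins by differentiating
#' raw position, the forward difference of the simulated recording recovers
#' the designed movement signal exactly, giving known ground truth after the
#' derivative step. Bout windows are contiguous intervals at the start of
#' each trial epoch, covering that trial's occupancy fraction.
#'
#' The planted bout appears on the x axis; y and z carry only the profile's
#' noise (and any high-frequency artifact), mimicking a dominant movement
#' direction.
#'
#' @param profile A [fidget_profile].
#' @param schedule A [task_schedule].
#' @param sample_rate_hz Sampling rate; must exceed twice the highest planted
#'   frequency (Nyquist). Default 500 Hz, the rate of a typical research
#'   actigraph; reduce (e.g. 100 Hz) for fast tests.
#' @param seed Integer seed; identical arguments and seed give identical
#'   samples.
#' @param sensor_site Sensor placement label for the recording.
#' @return An [accel_recording] spanning the whole session.
#' @export
simulate_recording <- function(profile, schedule, sample_rate_hz = 500,
                               seed = 1L, sensor_site = "wrist") {
  stopifnot(inherits(profile, "fidget_profile"),
            inherits(schedule, "task_schedule"))
  fmax <- max(profile$bout_frequency_hz,
              if (is.null(profile$hf_artifact_hz)) 0 else profile$hf_artifact_hz)
  if (sample_rate_hz <= 2 * fmax)
    stop(sprintf("sample rate %g Hz violates Nyquist for %g Hz content",
                 sample_rate_hz, fmax))
  n_trials <- nrow(schedule)
  occ <- rep_len(profile$bout_occupancy, n_trials)
  epoch_ms <- attr(schedule, "stimulus_ms") + attr(schedule, "iti_ms")
  bouts <- data.frame(start_s = schedule$onset_ms / 1000,
                      end_s = (schedule$onset_ms + occ * epoch_ms) / 1000)
  bouts <- bouts[occ > 0, , drop = FALSE]
  n <- round(attr(schedule, "duration_ms") / 1000 * sample_rate_hz)
  t <- (0:(n - 1L)) / sample_rate_hz
  m <- with_seed(seed, list(
    x = synth_movement_axis(t, profile, bouts, 1),
    y = synth_movement_axis(t, profile, bouts[0, ], 0),
    z = synth_movement_axis(t, profile, bouts[0, ], 0)))
  dt <- 1 / sample_rate_hz
  accel_recording(time_s = t,
                  x = cumsum(m$x) * dt, y = cumsum(m$y) * dt,
                  z = cumsum(m$z) * dt,
                  sensor_site = sensor_site, sample_rate_hz = sample_rate_hz)
}

#' Simulate a calibration recording
#'
#' Three calibration regimes precede an analysis session:
#' \describe{
#'   \item{stationary}{no movement — device noise only; establishes the
#'     detection threshold (see [calibration_threshold]);}
#'   \item{simulated_fidget}{sustained in-band repetitive movement (leg
#'     bouncing, table tapping) filling the whole recording;}
#'   \item{rapid}{erratic movement, stronger and more broadband than
#'     fidgeting — substantial energy above the analysis band.}
#' }
#'
#' @param kind One of `"stationary"`, `"simulated_fidget"`, `"rapid"`.
#' @param duration_s Recording length in seconds, `> 0`.
#' @param seed Integer seed.
#' @param profile A [fidget_profile] supplying frequencies/amplitudes.
#' @param sample_rate_hz Sampling rate.
#' @return An [accel_recording].
#' @export
simulate_calibration <- function(kind = c("stationary", "simulated_fidget",
                                          "rapid"),
                                 duration_s = 60, seed = 1L,
                                 profile = fidget_profile(),
                                 sample_rate_hz = 500) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0)
  n <- round(duration_s * sample_rate_hz)
  t <- (0:(n - 1L)) / sample_rate_hz
  nyq <- sample_rate_hz / 2
  m <- with_seed(seed, {
    base <- function() if (profile$noise_sd > 0)
      stats::rnorm(n, sd = profile$noise_sd) else numeric(n)
    switch(kind,
      stationary = list(x = base(), y = base(), z = base()),
      simulated_fidget = {
        bout <- profile$bout_amplitude *
          sin(2 * pi * profile$bout_frequency_hz * t)
        list(x = bout + base(), y = base(), z = base())
      },
      rapid = {
        # erratic and stronger than fidgeting: an in-band component plus a
        # strong out-of-band component and heavy broadband noise
        f_out <- min(2 * profile$band_high, 0.9 * nyq)
        amp <- 3 * profile$bout_amplitude
        wave <- amp * sin(2 * pi * profile$bout_frequency_hz * t) +
          amp * sin(2 * pi * f_out * t)
        nz <- function() stats::rnorm(n, sd = profile$noise_sd + amp / 3)
        list(x = wave + nz(), y = nz(), z = nz())
      })
  })
  dt <- 1 / sample_rate_hz
  accel_recording(time_s = t,
                  x = cumsum(m$x) * dt, y = cumsum(m$y) * dt,
                  z = cumsum(m$z) * dt,
                  sensor_site = "wrist", sample_rate_hz = sample_rate_hz)
}

#' Simulate ex-Gaussian reaction times with omissions
#'
#' Non-omitted reaction times are `Normal(mu, sigma) + Exponential(mean tau)`
#' draws; omitted trials are flagged missing-at-random with no RT.
#'
#' @param params Named list or vector with `mu`, `sigma` (`> 0`), `tau`
#'   (`> 0`), all in ms.
#' @param n Number of trials.
#' @param omission_rate Probability a trial is an omission, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A data.frame with `trial_index`, `rt_ms` (`NA` for omissions) and
#'   `omitted`.
#' @export
simulate_reaction_times <- function(params, n, omission_rate = 0, seed = 1L) {
  mu <- params[["mu"]]; sigma <- params[["sigma"]]; tau <- params[["tau"]]
  if (sigma <= 0 || tau <= 0) stop("sigma and tau must be positive")
  if (omission_rate < 0 || omission_rate >= 1)
    stop("omission_rate must be in [0, 1)")
  with_seed(seed, {
    rt <- stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
    omitted <- stats::runif(n) < omission_rate
    rt[omitted] <- NA_real_
    data.frame(trial_index = seq_len(n), rt_ms = rt, omitted = omitted)
  })
}

#' Simulate a full flanker session (trial events)
#'
#' Couples a [task_schedule] with simulated responses: ex-Gaussian reaction
#' times, missing-at-random omissions and an error rate, in the trial-event
#' layout the pipeline consumes.
#'
#' @param schedule A [task_schedule].
#' @param rt_params Ex-Gaussian parameters (see [simulate_reaction_times]).
#' @param omission_rate,error_rate Per-trial probabilities.
#' @param seed Integer seed.
#' @return A trial-event data.frame: `trial_index`, `type`, `onset_ms`,
#'   `response`, `correct`, `rt_ms`.
#' @export
simulate_session <- function(schedule,
                             rt_params = list(mu = 369.3, sigma = 51.9,
                                              tau = 70.0),
                             omission_rate = 0.022, error_rate = 0.03,
                             seed = 1L) {
  n <- nrow(schedule)
  rts <- simulate_reaction_times(rt_params, n, omission_rate, seed = seed)
  with_seed(seed + 1L, {
    target <- sample(c("left", "right"), n, replace = TRUE)
    err <- stats::runif(n) < error_rate
    response <- ifelse(target == "left", "left", "right")
    response[err] <- ifelse(target[err] == "left", "right", "left")
    response[rts$omitted] <- "none"
    correct <- !err & !rts$omitted
    data.frame(trial_index = schedule$trial_index, type = schedule$type,
               onset_ms = schedule$onset_ms, response = response,
               correct = correct, rt_ms = rts$rt_ms)
  })
}

# legal ranges of the rating-scale totals
scale_ranges <- list(baars = c(18, 72), bdefs_sec5 = c(13, 52), ari = c(0, 12))

#' Simulate a participant cohort with planted scale coupling
#'
#' Generates per-participant fidget variables (arm and leg values of the
#' three fidget metrics; defaults drawn around published cohort-scale means,
#' truncated at zero), ex-Gaussian reaction-time parameters, task covariates,
#' and rating-scale totals constructed as
#' `intercept + coupling %*% fidget_variables + Normal(0, noise_sd)`, then
#' clipped to each scale's legal range (BAARS 18-72, BDEFS section 5 13-52,
#' ARI 0-12).
#'
#' @param n Cohort size, at least 8 (more observations than the 6 predictors
#'   plus intercept).
#' @param coupling Named list of numeric length-6 coefficient vectors, one per
#'   scale in `c("baars", "bdefs_sec5", "ari")`, mapping the predictors
#'   `(arm_n, arm_var, arm_int, leg_n, leg_var, leg_int)` to the scale total.
#' @param noise_sd Residual SD added to each scale total.
#' @param intercepts Named vector of per-scale intercepts (defaults near each
#'   scale's midpoint).
#' @param seed Integer seed.
#' @return A data.frame, one row per participant, with fidget predictors,
#'   `mu`, `sigma`, `tau`, covariates and the three scale totals.
#' @export
simulate_participants <- function(n, coupling = NULL, noise_sd = 5,
                                  intercepts = c(baars = 45, bdefs_sec5 = 28,
                                                 ari = 6),
                                  seed = 1L) {
  if (n < 8) stop("need n >= 8 participants (6 predictors + intercept)")
  if (is.null(coupling))
    coupling <- list(baars = rep(0, 6), bdefs_sec5 = rep(0, 6),
                     ari = rep(0, 6))
  stopifnot(all(names(scale_ranges) %in% names(coupling)),
            all(vapply(coupling, length, 0L) == 6L))
  with_seed(seed, {
    trunc0 <- function(m, s) pmax(stats::rnorm(n, m, s), 0)
    X <- cbind(arm_n = trunc0(2.1, 1.5), arm_var = trunc0(131.3, 103.7),
               arm_int = trunc0(0.1, 0.2), leg_n = trunc0(2.6, 1.4),
               leg_var = trunc0(135.5, 80.4), leg_int = trunc0(0.5, 0.9))
    totals <- lapply(names(scale_ranges), function(sc) {
      raw <- intercepts[[sc]] + drop(X %*% coupling[[sc]]) +
        stats::rnorm(n, sd = noise_sd)
      pmin(pmax(raw, scale_ranges[[sc]][1]), scale_ranges[[sc]][2])
    })
    names(totals) <- names(scale_ranges)
    data.frame(participant_id = seq_len(n), X,
               mu = trunc0(369.3, 46.2), sigma = pmax(trunc0(51.9, 18.4), 1),
               tau = pmax(trunc0(70.0, 26.5), 1),
               digit_span = trunc0(11, 3.1), stroop_color = trunc0(70.4, 12.4),
               stroop_color_word = trunc0(49.8, 9.0),
               baars = totals$baars, bdefs_sec5 = totals$bdefs_sec5,
               ari = totals$ari)
  })
}
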