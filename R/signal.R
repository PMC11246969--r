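#' Construct a 3-axis accelerometer recording
#'
#' Container for one sensor site's raw actigraphy stream: uniformly sampled
#' position samples on three orthogonal axes, on a shared session clock.
#'
#' @param time_s Numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced.
#' @param x,y,z Numeric vectors of per-axis samples (device units), all the
#'   same length as `time_s`.
#' @param sensor_site `"wrist"` or `"ankle"`.
#' @param sample_rate_hz Sampling rate in Hz. Defaults to the reciprocal of
#'   the median inter-sample interval.
#'
#' @return An object of class `accel_recording`: a list with elements
#'   `time_s`, `axes` (an n x 3 matrix with columns x, y, z), `sensor_site`
#'   and `sample_rate_hz`.
#' @export
accel_recording <- function(time_s, x, y, z, sensor_site = c("wrist", "ankle"),
                            sample_rate_hz = NULL) {
  sensor_site <- match.arg(sensor_site)
  n <- length(time_s)
  if (n < 2L) stop("an accelerometer recording needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("all three axes must have the same length as time_s")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / stats::median(dt)
  jitter <- max(abs(dt - 1 / sample_rate_hz)) * sample_rate_hz
  if (jitter > 0.01)
    warning(sprintf("sampling jitter of %.1f%% relative to the nominal interval",
                    100 * jitter))
  axes <- cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(axes))) stop("samples must be finite")
  structure(
    list(time_s = as.numeric(time_s), axes = axes,
         sensor_site = sensor_site, sample_rate_hz = sample_rate_hz),
    class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %s, %d samples @ %g Hz, %.2f s\n",
              x$sensor_site, nrow(x$axes), x$sample_rate_hz,
              nrow(x$axes) / x$sample_rate_hz))
  invisible(x)
}

new_movement_signal <- function(time_s, axes, sensor_site, sample_rate_hz) {
  stopifnot(nrow(axes) == length(time_s), all(is.finite(axes)))
  structure(
    list(time_s = time_s, axes = axes, sensor_site = sensor_site,
         sample_rate_hz = sample_rate_hz),
    class = "movement_signal")
}

#' @export
print.movement_signal <- function(x, ...) {
  cat(sprintf("<movement_signal> %s, %d samples @ %g Hz\n",
              x$sensor_site, nrow(x$axes), x$sample_rate_hz))
  invisible(x)
}

#' Frequency band for band-limited reconstruction
#'
#' @param low_hz Lower band edge in Hz (inclusive), `>= 0`. The default low
#'   edge of 1 Hz excludes the DC bin; set `low_hz = 0` to retain it.
#' @param high_hz Upper band edge in Hz (inclusive), `> low_hz`.
#'
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(low_hz = 1, high_hz = 20) {
  if (low_hz < 0 || high_hz <= low_hz)
    stop("need 0 <= low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "frequency_band")
}

#' Differentiate a recording into a movement signal
#'
#' Raw actigraphy encodes position; repetitive movement is easier to see in
#' its time derivative. Each axis is differentiated separately as a forward
#' first difference scaled by the sampling interval,
#' `m[i] = (s[i+1] - s[i]) * rate`. The result is one sample shorter than the
#' recording; movement sample `i` carries the timestamp of position sample
#' `i + 1`, so downstream epoching stays aligned to the task clock.
#'
#' @param recording An [accel_recording].
#' @return A `movement_signal` with the recording's site and rate preserved.
#' @export
differentiate <- function(recording) {
  stopifnot(inherits(recording, "accel_recording"))
  n <- nrow(recording$axes)
  if (n < 2L) stop("cannot differentiate fewer than 2 samples")
  axes <- apply(recording$axes, 2L, diff) * recording$sample_rate_hz
  if (n == 2L) axes <- matrix(axes, nrow = 1L,
                              dimnames = list(NULL, c("x", "y", "z")))
  new_movement_signal(recording$time_s[-1L], axes,
                      recording$sensor_site, recording$sample_rate_hz)
}

band_mask <- function(n, rate, band) {
  # folded (two-sided) bin frequencies 0..Nyquist..0
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * rate / n
  f >= band$low_hz & f <= band$high_hz
}

#' Band-limited reconstruction of a movement signal
#'
#' Decomposes each axis with the FFT, zeroes every bin whose frequency lies
#' strictly outside the closed band `[low_hz, high_hz]` (symmetrically on the
#' negative frequencies, so the reconstruction is real), and inverts the
#' transform. With the default band of 1 to 20 Hz this isolates the smooth
#' repetitive component of movement that characterizes fidgeting, discarding
#' both the DC offset and high-frequency device noise. No taper is applied;
#' spectral leakage at the session edges is accepted.
#'
#' @param movement A `movement_signal` (see [differentiate]).
#' @param band A [frequency_band]; `high_hz` must not exceed the Nyquist
#'   frequency `sample_rate_hz / 2`.
#' @return A `movement_signal` of the same length, band-limited per axis.
#' @export
band_reconstruct <- function(movement, band = frequency_band()) {
  stopifnot(inherits(movement, "movement_signal"),
            inherits(band, "frequency_band"))
  rate <- movement$sample_rate_hz
  if (band$high_hz > rate / 2 + 1e-12)
    stop(sprintf("band high edge %g Hz exceeds the Nyquist frequency %g Hz",
                 band$high_hz, rate / 2))
  n <- nrow(movement$axes)
  keep <- band_mask(n, rate, band)
  axes <- apply(movement$axes, 2L, function(s) {
    spec <- stats::fft(s)
    spec[!keep] <- 0 + 0i
    rec <- stats::fft(spec, inverse = TRUE) / n
    resid <- sqrt(sum(Im(rec)^2))
    nrm <- sqrt(sum(Mod(rec)^2))
    if (nrm > 0 && resid > 1e-8 * nrm)
      warning("imaginary residue above 1e-8 of the signal norm; discarded")
    Re(rec)
  })
  if (n == 1L) axes <- matrix(axes, nrow = 1L,
                              dimnames = list(NULL, c("x", "y", "z")))
  new_movement_signal(movement$time_s, axes,
                      movement$sensor_site, rate)
}

#' One-sided magnitude spectrum of a movement signal
#'
#' @param movement A `movement_signal`.
#' @return A data.frame with columns `axis`, `frequency_hz` (0 to Nyquist) and
#'   `magnitude` (FFT modulus of the corresponding bin).
#' @export
spectrum_table <- function(movement) {
  stopifnot(inherits(movement, "movement_signal"))
  n <- nrow(movement$axes)
  rate <- movement$sample_rate_hz
  half <- 0:(n %/% 2L)
  freq <- half * rate / n
  out <- lapply(colnames(movement$axes), function(ax) {
    mag <- Mod(stats::fft(movement$axes[, ax]))[half + 1L]
    data.frame(axis = ax, frequency_hz = freq, magnitude = mag)
  })
  do.call(rbind, out)
}
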