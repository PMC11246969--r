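#' Detect peaks in a band-limited movement signal
#'
#' A peak is a sample strictly greater than both neighbours; a plateau of
#' equal values flanked by lower samples yields one peak at the plateau's
#' first sample. Only peaks whose height (the signal value at the maximum,
#' referenced to zero — the band-limited signal is mean-free when the DC bin
#' is excluded) strictly exceeds `threshold` are kept. Peak heights are not
#' peak-to-valley prominences.
#'
#' The input is expected to be band-limited (see [band_reconstruct]); this is
#' a documented contract, not enforced.
#'
#' @param movement A `movement_signal`.
#' @param threshold Detection threshold in signal units, `>= 0`. Use
#'   [calibration_threshold] for the recommended data-driven default; `0` is
#'   allowed (e.g. for oracle comparisons).
#' @return A named list (one element per axis) of `peak_series` data.frames
#'   with columns `time_ms` (strictly increasing) and `height`, carrying
#'   attributes `axis`, `sensor_site` and `span_ms` (the signal's time span).
#' @export
detect_peaks <- function(movement, threshold = 0) {
  stopifnot(inherits(movement, "movement_signal"), threshold >= 0)
  n <- nrow(movement$axes)
  if (n < 3L) stop("peak detection needs at least 3 samples")
  t_ms <- movement$time_s * 1000
  span <- c(t_ms[1L], t_ms[n])
  out <- lapply(colnames(movement$axes), function(ax) {
    s <- movement$axes[, ax]
    idx <- plateau_peaks(s)
    idx <- idx[s[idx] > threshold]
    ps <- data.frame(time_ms = t_ms[idx], height = s[idx])
    attr(ps, "axis") <- ax
    attr(ps, "sensor_site") <- movement$sensor_site
    attr(ps, "span_ms") <- span
    class(ps) <- c("peak_series", "data.frame")
    ps
  })
  names(out) <- colnames(movement$axes)
  out
}

# indices of local maxima, one per plateau (its first sample); endpoints are
# never peaks
plateau_peaks <- function(s) {
  r <- rle(s)
  v <- r$values
  k <- length(v)
  if (k < 3L) return(integer(0))
  run_start <- cumsum(c(1L, r$lengths[-k]))
  is_max <- c(FALSE, v[2:(k - 1L)] > v[1:(k - 2L)] & v[2:(k - 1L)] > v[3:k],
              FALSE)
  run_start[is_max]
}

#' Fidget variables for one set of peaks in one time window
#'
#' Computes the three fidget variables from a peak series restricted to a
#' half-open window `[start, end)`:
#' \describe{
#'   \item{number of fidgets}{count of peaks in the window;}
#'   \item{fidget time variability}{population variance (ms^2) of the
#'     intervals between consecutive peaks — undefined (`NA`) with fewer than
#'     3 peaks, i.e. fewer than 2 intervals;}
#'   \item{fidget intensity}{arithmetic mean of the peak heights — undefined
#'     (`NA`) with no peaks.}
#' }
#' Undefined values are flagged as `NA`, never zero-filled: a zero would
#' conflate "no fidgeting" with "perfectly regular fidgeting".
#'
#' @param peaks A `peak_series` (one axis) from [detect_peaks].
#' @param window Numeric length-2, `c(start_ms, end_ms)` with `start < end`.
#' @return A `fidget_metrics` object: a list with `n_fidgets`,
#'   `variability_ms2` and `intensity`.
#' @export
compute_fidget_metrics <- function(peaks, window) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  inside <- peaks$time_ms >= window[1L] & peaks$time_ms < window[2L]
  times <- peaks$time_ms[inside]
  heights <- peaks$height[inside]
  n <- length(times)
  variability <- if (n >= 3L) {
    iv <- diff(times)
    mean((iv - mean(iv))^2)          # population variance, ms^2
  } else NA_real_
  intensity <- if (n >= 1L) mean(heights) else NA_real_
  fidget_metrics(n, variability, intensity)
}

#' @rdname compute_fidget_metrics
#' @param n_fidgets,variability_ms2,intensity The three fidget variables.
#' @export
fidget_metrics <- function(n_fidgets, variability_ms2 = NA_real_,
                           intensity = NA_real_) {
  stopifnot(n_fidgets >= 0,
            is.na(variability_ms2) || variability_ms2 >= 0)
  structure(list(n_fidgets = as.numeric(n_fidgets),
                 variability_ms2 = as.numeric(variability_ms2),
                 intensity = as.numeric(intensity)),
            class = "fidget_metrics")
}

#' @export
print.fidget_metrics <- function(x, ...) {
  cat(sprintf("<fidget_metrics> n = %g, variability = %g ms^2, intensity = %g\n",
              x$n_fidgets, x$variability_ms2, x$intensity))
  invisible(x)
}

# sum respecting the "undefined stays undefined only if nothing is defined"
# convention used for both axis and sensor combination
.sum_defined <- function(...) {
  v <- c(...)
  if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
}

#' Per-trial fidget metrics for a movement signal
#'
#' Treats each task trial as an independent epoch: peaks are detected once on
#' the whole (already band-limited) session signal, then each trial's window
#' is scored. The epoch window is `[onset, onset + 1000)` ms
#' (`"stimulus_only"`) or `[onset, onset + 2000)` ms (`"stimulus_plus_iti"`,
#' the default — the stimulus plus the following inter-trial interval).
#'
#' Per-axis metrics are combined across the three axes by summation — counts,
#' variabilities and intensities each summed, the same rule used across
#' sensors by [combine_sensors] — with `NA` axes dropped unless all three are
#' undefined.
#'
#' @param movement A band-limited `movement_signal`.
#' @param events A data.frame of trial events as returned by [read_events]
#'   (needs `trial_index` and `onset_ms`; other columns are carried through).
#' @param epoch `"stimulus_plus_iti"` (default) or `"stimulus_only"`.
#' @param threshold Peak detection threshold (see [detect_peaks]).
#' @return An epoch metrics table: a data.frame with one row per trial and
#'   columns `trial_index`, `sensor_site`, `n_fidgets`, `variability_ms2`,
#'   `intensity`, plus any metadata columns present in `events`.
#' @export
epoch_metrics <- function(movement, events,
                          epoch = c("stimulus_plus_iti", "stimulus_only"),
                          threshold = 0) {
  epoch <- match.arg(epoch)
  stopifnot(is.data.frame(events),
            all(c("trial_index", "onset_ms") %in% names(events)))
  if (is.unsorted(events$onset_ms, strictly = TRUE))
    stop("trial onsets must be strictly increasing")
  win_ms <- if (epoch == "stimulus_only") 1000 else 2000
  span <- range(movement$time_s) * 1000
  if (any(events$onset_ms < span[1L] - 1000 * 1.5 / movement$sample_rate_hz) ||
      any(events$onset_ms + win_ms > span[2L] + 1000 * 1.5 / movement$sample_rate_hz))
    stop("trial events fall outside the recording span")
  peaks <- detect_peaks(movement, threshold)
  n_tr <- nrow(events)
  onsets <- events$onset_ms
  per_axis <- lapply(peaks, function(ps) {
    # assign each peak to its trial's half-open window [onset, onset + win)
    idx <- findInterval(ps$time_ms, onsets)
    keep <- idx >= 1L & ps$time_ms < onsets[pmax(idx, 1L)] + win_ms
    idx <- idx[keep]
    times <- ps$time_ms[keep]
    heights <- ps$height[keep]
    counts <- tabulate(idx, nbins = n_tr)
    hsum <- numeric(n_tr)
    if (length(idx)) hsum[sort(unique(idx))] <- rowsum(heights, idx)[, 1L]
    intensity <- ifelse(counts > 0L, hsum / counts, NA_real_)
    # population variance of intra-trial inter-peak intervals via E[x^2]-E[x]^2
    variability <- rep(NA_real_, n_tr)
    if (length(idx) > 1L) {
      same <- idx[-1L] == idx[-length(idx)]
      if (any(same)) {
        iv <- diff(times)[same]
        g <- idx[-1L][same]
        u <- sort(unique(g))
        m <- rowsum(cbind(iv, iv^2, 1), g)
        nn <- m[, 3L]
        variability[u] <- m[, 2L] / nn - (m[, 1L] / nn)^2
        variability[u][nn < 2] <- NA_real_   # < 3 peaks: undefined
      }
    }
    list(counts = counts, variability = pmax(variability, 0),
         intensity = intensity)
  })
  vmat <- sapply(per_axis, `[[`, "variability")
  imat <- sapply(per_axis, `[[`, "intensity")
  row_sum_defined <- function(m) {
    s <- rowSums(m, na.rm = TRUE)
    s[rowSums(!is.na(m)) == 0L] <- NA_real_
    s
  }
  out <- data.frame(
    trial_index = events$trial_index,
    sensor_site = movement$sensor_site,
    n_fidgets = rowSums(sapply(per_axis, `[[`, "counts")),
    variability_ms2 = row_sum_defined(vmat),
    intensity = row_sum_defined(imat))
  meta <- setdiff(names(events), names(out))
  cbind(out, events[meta])
}

#' Combine fidget metrics across sensor sites
#'
#' All three variables are summed across sensors: the "Arm + Leg" convention,
#' under which per-site mean counts of 2.1 and 2.6 fidgets per trial combine
#' to 4.7, and intensities 0.1 and 0.5 to 0.6. An `NA` (undefined) variable on
#' one sensor is dropped unless it is undefined on both. The operation is
#' commutative and associative.
#'
#' @param arm,leg `fidget_metrics` objects for the same trial/window.
#' @return A combined `fidget_metrics`.
#' @export
combine_sensors <- function(arm, leg) {
  stopifnot(inherits(arm, "fidget_metrics"), inherits(leg, "fidget_metrics"))
  fidget_metrics(
    n_fidgets = arm$n_fidgets + leg$n_fidgets,
    variability_ms2 = .sum_defined(arm$variability_ms2, leg$variability_ms2),
    intensity = .sum_defined(arm$intensity, leg$intensity))
}

#' Combine two per-trial metrics tables across sensors
#'
#' Row-wise [combine_sensors] for two epoch metrics tables over the same
#' trials (matched on `trial_index`).
#'
#' @param arm_table,leg_table Epoch metrics tables from [epoch_metrics].
#' @return A table with `sensor_site = "arm+leg"` and summed variables.
#' @export
combine_sensor_tables <- function(arm_table, leg_table) {
  if (!identical(arm_table$trial_index, leg_table$trial_index))
    stop("sensor tables cover different trials")
  out <- arm_table
  out$sensor_site <- "arm+leg"
  out$n_fidgets <- arm_table$n_fidgets + leg_table$n_fidgets
  out$variability_ms2 <- mapply(.sum_defined, arm_table$variability_ms2,
                                leg_table$variability_ms2)
  out$intensity <- mapply(.sum_defined, arm_table$intensity,
                          leg_table$intensity)
  out
}

#' Aggregate per-trial fidget metrics over a trial subset
#'
#' Mean and standard deviation of each fidget variable over the selected
#' trials, skipping undefined (`NA`) values, with the count of contributing
#' trials per variable.
#'
#' @param table An epoch metrics table from [epoch_metrics].
#' @param subset Logical vector (recycled against rows), integer trial
#'   indices, or `NULL` for all trials.
#' @return A data.frame with one row per variable: `variable`, `mean`, `sd`,
#'   `n` (trials contributing a defined value).
#' @export
aggregate_metrics <- function(table, subset = NULL) {
  rows <- if (is.null(subset)) rep(TRUE, nrow(table))
          else if (is.logical(subset)) subset
          else table$trial_index %in% subset
  if (!any(rows)) stop("empty trial subset")
  sel <- table[rows, , drop = FALSE]
  one <- function(v) {
    x <- sel[[v]][!is.na(sel[[v]])]
    data.frame(variable = v,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) stats::sd(x) else
                 if (length(x) == 1L) 0 else NA_real_,
               n = length(x))
  }
  do.call(rbind, lapply(c("n_fidgets", "variability_ms2", "intensity"), one))
}

#' Data-driven peak detection threshold from a stationary calibration
#'
#' The recommended threshold is 3 standard deviations of the band-limited
#' movement signal recorded while the wearer sits still, so that device noise
#' alone rarely crosses it.
#'
#' @param stationary An [accel_recording] of a no-movement calibration.
#' @param band The analysis [frequency_band].
#' @param k Multiplier on the noise SD (default 3).
#' @return A single threshold in signal units (max over axes).
#' @export
calibration_threshold <- function(stationary, band = frequency_band(), k = 3) {
  filtered <- band_reconstruct(differentiate(stationary), band)
  k * max(apply(filtered$axes, 2L, stats::sd))
}
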