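#' Read and write actigraphy CSV
#'
#' The interchange format is a plain CSV with header `time_s,x,y,z` — sample
#' timestamps in seconds on the session clock (starting at 0), one column per
#' axis in device units. The sample rate is inferred from the median
#' inter-sample interval; jitter above 1% of the nominal interval raises a
#' warning.
#'
#' @param path File path.
#' @param sensor_site Sensor placement label to attach on read.
#' @return `read_actigraphy`: an [accel_recording].
#' @export
read_actigraphy <- function(path, sensor_site = "wrist") {
  dt <- data.table::fread(path)
  need <- c("time_s", "x", "y", "z")
  if (!all(need %in% names(dt)))
    stop("actigraphy CSV must have columns time_s, x, y, z")
  if (nrow(dt) == 0L) stop("empty actigraphy file")
  if (is.unsorted(dt$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  accel_recording(dt$time_s, dt$x, dt$y, dt$z, sensor_site = sensor_site)
}

#' @rdname read_actigraphy
#' @param recording An [accel_recording] to write.
#' @export
write_actigraphy <- function(recording, path) {
  data.table::fwrite(
    data.frame(time_s = recording$time_s,
               x = recording$axes[, "x"], y = recording$axes[, "y"],
               z = recording$axes[, "z"]),
    path)
  invisible(path)
}

trial_types <- c("congruent", "incongruent", "neutral")

#' Read and write trial-event CSV
#'
#' Columns `trial_index,type,onset_ms,response,correct,rt_ms`; `rt_ms` is
#' empty for omissions (response `"none"`). Events are validated (known trial
#' types, omission consistency) and returned sorted by onset.
#'
#' @param path File path.
#' @return `read_events`: a validated trial-event data.frame.
#' @export
read_events <- function(path) {
  ev <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  need <- c("trial_index", "type", "onset_ms", "response", "correct", "rt_ms")
  if (!all(need %in% names(ev)))
    stop("events CSV must have columns ", paste(need, collapse = ", "))
  ev$type <- tolower(trimws(ev$type))
  if (!all(ev$type %in% trial_types))
    stop("unknown trial type label(s): ",
         paste(setdiff(unique(ev$type), trial_types), collapse = ", "))
  if (!is.logical(ev$correct)) {
    cv <- tolower(as.character(ev$correct))
    if (!all(cv %in% c("true", "false", "1", "0")))
      stop("malformed 'correct' column")
    ev$correct <- cv %in% c("true", "1")
  }
  omitted <- ev$response == "none"
  if (any(omitted & !is.na(ev$rt_ms)))
    stop("rt_ms present for a trial with response 'none'")
  if (any(!omitted & is.na(ev$rt_ms)))
    stop("rt_ms missing for a responded trial")
  ev[order(ev$onset_ms), , drop = FALSE]
}

#' @rdname read_events
#' @param events Trial-event data.frame to write.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' Assemble and validate a session bundle
#'
#' Resolves the file paths and analysis configuration for one session:
#' per-sensor actigraphy CSVs, the trial-events CSV, the frequency band, the
#' peak threshold, the epoch mode and the seed. Configuration errors (missing
#' files, band above Nyquist once checked against data) surface before any
#' computation.
#'
#' @param wrist_csv,ankle_csv Paths to per-sensor actigraphy CSVs
#'   (`ankle_csv` may be `NULL` for a single-sensor session).
#' @param events_csv Path to the trial-events CSV.
#' @param band A [frequency_band].
#' @param threshold Peak detection threshold (signal units).
#' @param epoch `"stimulus_plus_iti"` or `"stimulus_only"`.
#' @param seed Integer seed recorded for provenance.
#' @return A `session_bundle` list.
#' @export
session_bundle <- function(wrist_csv, events_csv, ankle_csv = NULL,
                           band = frequency_band(), threshold = 0,
                           epoch = "stimulus_plus_iti", seed = 1L) {
  for (p in c(wrist_csv, ankle_csv, events_csv))
    if (!file.exists(p)) stop("file not found: ", p)
  stopifnot(inherits(band, "frequency_band"), threshold >= 0,
            epoch %in% c("stimulus_plus_iti", "stimulus_only"))
  structure(list(wrist_csv = wrist_csv, ankle_csv = ankle_csv,
                 events_csv = events_csv, band = band, threshold = threshold,
                 epoch = epoch, seed = as.integer(seed)),
            class = "session_bundle")
}

process_sensor <- function(csv, site, bundle, events) {
  rec <- read_actigraphy(csv, sensor_site = site)
  if (bundle$band$high_hz > rec$sample_rate_hz / 2)
    stop(sprintf("configured band high edge %g Hz exceeds Nyquist %g Hz",
                 bundle$band$high_hz, rec$sample_rate_hz / 2))
  filtered <- band_reconstruct(differentiate(rec), bundle$band)
  epoch_metrics(filtered, events, epoch = bundle$epoch,
                threshold = bundle$threshold)
}

#' Run the full fidget-quantification pipeline on one session
#'
#' Executes differentiate, band-limited reconstruction, peak detection,
#' per-trial epoching, across-sensor combination, trial-subset aggregation
#' (overall, correct/incorrect, per type, Q1/Q4) and the ex-Gaussian
#' reaction-time fit, writing a per-trial metrics CSV and a JSON report that
#' embeds the resolved configuration for provenance. Deterministic given the
#' bundle.
#'
#' @param bundle A [session_bundle].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-trial `metrics` table and the
#'   `report` list; files `metrics.csv` and `report.json` in `out_dir`.
#' @export
run_pipeline <- function(bundle, out_dir = ".") {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- read_events(bundle$events_csv)
  tables <- list(process_sensor(bundle$wrist_csv, "wrist", bundle, events))
  if (!is.null(bundle$ankle_csv)) {
    tables[[2L]] <- process_sensor(bundle$ankle_csv, "ankle", bundle, events)
    tables[[3L]] <- combine_sensor_tables(tables[[1L]], tables[[2L]])
  }
  metrics <- do.call(rbind, tables)
  data.table::fwrite(metrics, file.path(out_dir, "metrics.csv"))

  primary <- tables[[length(tables)]]
  subsets <- c(list(all = events$trial_index),
               split_trials(events, "correctness"),
               split_trials(events, "trial_type"),
               split_trials(events, "quartile"))
  aggregates <- lapply(subsets, function(ids) {
    if (!length(ids)) return(NULL)
    agg <- aggregate_metrics(primary, ids)
    stats::setNames(lapply(seq_len(nrow(agg)), function(i)
      list(mean = agg$mean[i], sd = agg$sd[i], n = agg$n[i])), agg$variable)
  })
  perf <- performance_summary(events)
  rt_fit <- tryCatch({
    rts <- events$rt_ms[events$correct & events$response != "none"]
    unclass(fit_exgaussian(rts))
  }, error = function(e) list(error = conditionMessage(e)))
  report <- list(
    config = list(band = unclass(bundle$band), threshold = bundle$threshold,
                  epoch = bundle$epoch, seed = bundle$seed,
                  sensors = c("wrist", if (!is.null(bundle$ankle_csv)) "ankle")),
    performance = perf[setdiff(names(perf), "by_type")],
    performance_by_type = perf$by_type,
    exgaussian = rt_fit,
    aggregates = aggregates)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(list(metrics = metrics, report = report))
}
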