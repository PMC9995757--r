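#' Construct an IMU trace
#'
#' An IMU trace is a tibble of timestamped tri-axial accelerometer and
#' gyroscope samples from one body-worn sensor, with the placement and
#' nominal sampling rate carried as attributes.  Columns: `t` (seconds
#' since session start), `ax, ay, az` (m/s^2), `gx, gy, gz` (rad/s) and
#' optionally `mx, my, mz` (magnetometer, arbitrary units; parsed but
#' unused downstream).
#'
#' @param data Data frame with at least columns `t, ax, ay, az, gx, gy, gz`.
#' @param placement One of [sensor_placements()].
#' @param nominal_rate Nominal sampling rate in Hz (default 100).
#' @param validate Check invariants (strictly increasing finite
#'   timestamps, finite accel/gyro)?
#' @return A tibble of class `imu_trace`.
#' @export
imu_trace <- function(data, placement, nominal_rate = 100, validate = TRUE) {
  placement <- match.arg(placement, sensor_placements())
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1 || nominal_rate <= 0)
    abort("`nominal_rate` must be a single positive number",
          class = "nearfallr_validation_error")
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("trace is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "nearfallr_validation_error")
  out <- as_tibble(data)
  if (validate && nrow(out) > 0) {
    if (any(!is.finite(out$t)) || any(out$t < 0))
      abort("timestamps must be finite and non-negative",
            class = "nearfallr_validation_error")
    if (any(diff(out$t) <= 0))
      abort("timestamps must be strictly increasing",
            class = "nearfallr_validation_error")
    vals <- as.matrix(out[, c("ax", "ay", "az", "gx", "gy", "gz")])
    if (any(!is.finite(vals)))
      abort("accelerometer/gyroscope samples must be finite",
            class = "nearfallr_validation_error")
  }
  structure(out,
            class = c("imu_trace", class(as_tibble(out))),
            placement = placement,
            nominal_rate = nominal_rate)
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> placement=%s, %d samples, nominal %g Hz\n",
              attr(x, "placement"), nrow(x), attr(x, "nominal_rate")))
  NextMethod()
}

trace_placement <- function(trace) attr(trace, "placement")
trace_rate <- function(trace) attr(trace, "nominal_rate")

#' Read a per-sensor IMU log
#'
#' Reads a CSV sensor log with header `t,ax,ay,az,gx,gy,gz` (optionally
#' `,mx,my,mz`), sorts samples by timestamp and collapses duplicate
#' timestamps keeping the first occurrence.
#'
#' @param path Path to the CSV log.
#' @param placement One of [sensor_placements()].
#' @param nominal_rate Nominal sampling rate in Hz.
#' @return An [imu_trace()].
#' @export
read_imu_log <- function(path, placement, nominal_rate = 100) {
  if (!file.exists(path))
    abort(paste0("no such file: ", path), class = "nearfallr_io_error")
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed IMU log %s: cannot parse line %d (%s)",
                  path, probs$row[1], probs$expected[1]),
          class = "nearfallr_parse_error")
  }
  if (nrow(df) == 0)
    abort(paste0("empty IMU log: ", path), class = "nearfallr_empty_input")
  df <- dplyr::arrange(df, .data$t)
  df <- df[!duplicated(df$t), , drop = FALSE]
  imu_trace(df, placement = placement, nominal_rate = nominal_rate)
}

#' Write a per-sensor IMU log
#'
#' Writes the CSV dialect read by [read_imu_log()]; numbers use a
#' shortest round-trip representation so write-then-read reproduces the
#' trace to within floating-point round-trip tolerance.
#'
#' @param trace An [imu_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_log <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' Read an activity annotation stream
#'
#' Annotation files are CSV with header `start,end,label`, times in
#' session-relative seconds and labels in [activity_classes()].  Events
#' are returned ordered by start time; overlapping events are rejected.
#'
#' @param path Path to the annotation CSV.
#' @return A tibble of events with columns `start`, `end`, `label`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    abort(paste0("no such file: ", path), class = "nearfallr_io_error")
  df <- readr::read_csv(path, col_types = readr::cols(
    start = readr::col_double(),
    end = readr::col_double(),
    label = readr::col_character()), progress = FALSE)
  validate_events(tibble(start = df$start, end = df$end,
                         label = as_activity(df$label)))
}

#' Write an activity annotation stream
#'
#' @param events Event tibble (`start`, `end`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  events <- validate_events(events)
  readr::write_csv(
    tibble(start = events$start, end = events$end,
           label = as.character(events$label)),
    path, progress = FALSE)
  invisible(path)
}

#' Validate an event stream
#'
#' Checks `end > start`, known labels, and that events do not overlap;
#' returns the stream sorted by start time.
#'
#' @param events Data frame with columns `start`, `end`, `label`.
#' @return Validated tibble sorted by `start`.
#' @export
validate_events <- function(events) {
  events <- as_tibble(events)
  need <- c("start", "end", "label")
  if (!all(need %in% names(events)))
    abort("events need columns start, end, label",
          class = "nearfallr_validation_error")
  events$label <- as_activity(events$label)
  if (any(events$end <= events$start))
    abort("every event must have end > start",
          class = "nearfallr_validation_error")
  events <- dplyr::arrange(events, .data$start)
  if (nrow(events) > 1) {
    gap <- events$start[-1] - events$end[-nrow(events)]
    if (any(gap < -1e-9))
      abort("events overlap in time; annotation streams must be disjoint",
            class = "nearfallr_validation_error")
  }
  events
}

#' Assemble a synchronized five-sensor session
#'
#' Applies per-placement clock offsets, finds the common overlap of the
#' five corrected traces, and resamples every channel by linear
#' interpolation onto a uniform grid at `rate` Hz spanning the overlap.
#' Session time is re-zeroed so `t = 0` at the start of the overlap.
#'
#' @param traces Named list of five [imu_trace()]s, names =
#'   [sensor_placements()].
#' @param clock_offsets Named numeric vector of seconds added to each
#'   trace's timestamps to bring it onto the common clock (default all 0).
#' @param subject_id,day_index Session metadata.
#' @param rate Grid rate in Hz (default 100).
#' @return A `session_recording`: list with `traces` (the five resampled
#'   traces sharing one grid), `subject_id`, `day_index`, `rate`.
#' @export
assemble_session <- function(traces, clock_offsets = NULL,
                             subject_id = "subject", day_index = 1L,
                             rate = 100) {
  pl <- sensor_placements()
  missing_pl <- setdiff(pl, names(traces))
  if (length(missing_pl) > 0)
    abort(paste0("missing placement(s): ", paste(missing_pl, collapse = ", ")),
          class = "nearfallr_configuration_error")
  if (is.null(clock_offsets)) clock_offsets <- setNames(rep(0, 5), pl)
  if (!all(pl %in% names(clock_offsets)))
    abort("clock_offsets must cover all five placements",
          class = "nearfallr_configuration_error")

  corrected <- purrr::map(pl, function(p) {
    tr <- as_tibble(traces[[p]])
    tr$t <- tr$t + clock_offsets[[p]]
    tr
  })
  names(corrected) <- pl

  t_lo <- max(purrr::map_dbl(corrected, ~ min(.x$t)))
  t_hi <- min(purrr::map_dbl(corrected, ~ max(.x$t)))
  if (t_hi - t_lo <= 0)
    abort("traces share no overlapping time interval after offset correction",
          class = "nearfallr_alignment_error")

  dt <- 1 / rate
  grid <- t_lo + seq(0, floor((t_hi - t_lo) / dt)) * dt
  chans <- function(tr) setdiff(names(tr), "t")
  resampled <- purrr::imap(corrected, function(tr, p) {
    out <- tibble(t = grid - t_lo)
    for (ch in chans(tr))
      out[[ch]] <- approx(tr$t, tr[[ch]], xout = grid, rule = 2)$y
    imu_trace(out, placement = p, nominal_rate = rate, validate = FALSE)
  })

  structure(list(traces = resampled, subject_id = subject_id,
                 day_index = as.integer(day_index), rate = rate,
                 t_origin = t_lo),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> subject=%s day=%d, %g Hz, %.1f s, 5 traces\n",
              x$subject_id, x$day_index, x$rate, session_duration(x)))
  invisible(x)
}

#' Duration of an assembled session in seconds
#'
#' The span of the shared sampling grid, i.e. `n` samples at rate `r`
#' cover `n / r` seconds.
#'
#' @param session A `session_recording`.
#' @return Duration in seconds.
#' @export
session_duration <- function(session) {
  nrow(session$traces[[1]]) / session$rate
}

#' Write / read a session as one HDF5 file
#'
#' Mirrors the CSV dialect with one HDF5 group per placement (datasets
#' `t`, `accel`, `gyro`).  Requires the `rhdf5` package.
#'
#' @param session A `session_recording`.
#' @param path HDF5 file path.
#' @return `write_session_h5`: `path`, invisibly. `read_session_h5`: a
#'   `session_recording`.
#' @export
write_session_h5 <- function(session, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    abort("HDF5 support needs the 'rhdf5' package", class = "nearfallr_io_error")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (p in names(session$traces)) {
    tr <- session$traces[[p]]
    rhdf5::h5createGroup(path, p)
    rhdf5::h5write(tr$t, path, paste0(p, "/t"))
    rhdf5::h5write(as.matrix(tr[, c("ax", "ay", "az")]), path, paste0(p, "/accel"))
    rhdf5::h5write(as.matrix(tr[, c("gx", "gy", "gz")]), path, paste0(p, "/gyro"))
  }
  rhdf5::h5write(session$subject_id, path, "subject_id")
  rhdf5::h5write(session$day_index, path, "day_index")
  rhdf5::h5write(session$rate, path, "rate")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_session_h5
#' @export
read_session_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    abort("HDF5 support needs the 'rhdf5' package", class = "nearfallr_io_error")
  rate <- as.numeric(rhdf5::h5read(path, "rate"))
  traces <- purrr::map(sensor_placements(), function(p) {
    a <- rhdf5::h5read(path, paste0(p, "/accel"))
    g <- rhdf5::h5read(path, paste0(p, "/gyro"))
    imu_trace(tibble(
      t = as.numeric(rhdf5::h5read(path, paste0(p, "/t"))),
      ax = a[, 1], ay = a[, 2], az = a[, 3],
      gx = g[, 1], gy = g[, 2], gz = g[, 3]),
      placement = p, nominal_rate = rate, validate = FALSE)
  })
  names(traces) <- sensor_placements()
  out <- structure(list(
    traces = traces,
    subject_id = as.character(rhdf5::h5read(path, "subject_id")),
    day_index = as.integer(rhdf5::h5read(path, "day_index")),
    rate = rate, t_origin = 0),
    class = "session_recording")
  rhdf5::h5closeAll()
  out
}
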