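#' Construct a trials-by-time LFP array
#'
#' Container for one electrode's event-locked single-trial signal. The time
#' axis follows a half-open convention: for a window `[t0, t1)` sampled at
#' `fs_hz`, samples sit at `t0, t0 + dt, ..., t1 - dt` (so 1.5 s at 100 Hz is
#' 150 samples).
#'
#' @param data trials x time numeric matrix (arbitrary amplitude units).
#' @param time_ms numeric vector of sample times relative to choice onset,
#'   strictly increasing and uniformly spaced.
#' @param fs_hz sampling rate in Hz; must match `time_ms` spacing.
#' @param electrode_id,region,session_id,subject_id metadata carried along.
#' @return an object of class `lfp_array`.
#' @export
lfp_array <- function(data, time_ms, fs_hz,
                      electrode_id = 1L, region = "DLPFC",
                      session_id = 1L, subject_id = NA_integer_) {
  data <- as.matrix(data)
  if (ncol(data) != length(time_ms))
    stop("ncol(data) must equal length(time_ms)")
  dts <- diff(time_ms)
  if (length(dts) && (any(dts <= 0) || diff(range(dts)) > 1e-6))
    stop("time_ms must be strictly increasing and uniformly spaced")
  if (length(dts) && abs(dts[1] - 1000 / fs_hz) > 1e-6)
    stop("time_ms spacing does not match fs_hz")
  structure(
    list(data = data, time_ms = as.numeric(time_ms), fs_hz = fs_hz,
         electrode_id = electrode_id, region = region,
         session_id = as.integer(session_id), subject_id = subject_id),
    class = "lfp_array")
}

#' @export
print.lfp_array <- function(x, ...) {
  cat(sprintf(
    "<lfp_array> %d trials x %d samples @ %g Hz, [%g, %g) ms, %s electrode %s (session %s)\n",
    nrow(x$data), ncol(x$data), x$fs_hz, x$time_ms[1],
    x$time_ms[length(x$time_ms)] + 1000 / x$fs_hz,
    x$region, x$electrode_id, x$session_id))
  invisible(x)
}

#' @export
dim.lfp_array <- function(x) dim(x$data)

#' Standard half-open sample grid for a time window
#'
#' Sample times `t0, t0 + dt, ..., t1 - dt` for a window `c(t0, t1)` in ms
#' at `fs_hz`.
#'
#' @param window `c(t0, t1)` in ms.
#' @param fs_hz sampling rate.
#' @export
time_grid <- function(window, fs_hz) {
  dt <- 1000 / fs_hz
  seq(window[1], window[2] - dt, by = dt)
}

#' Anti-alias filter, decimate and crop an LFP array
#'
#' Downsamples by an integer factor after zero-phase low-pass filtering
#' (8th-order Butterworth at 0.4 of the target rate), then crops to the
#' requested analysis window. Typical use mirrors acquisition at 1 kHz
#' analysed at 100 Hz.
#'
#' @param raw an [lfp_array()].
#' @param target_fs target sampling rate (Hz); must divide `raw$fs_hz` and
#'   respect the Nyquist bound.
#' @param window `c(t0, t1)` crop window in ms (half-open), inside the
#'   recorded span.
#' @return an [lfp_array()] at `target_fs` over `window`.
#' @export
preprocess_lfp <- function(raw, target_fs = 100, window = c(-500, 1000)) {
  stopifnot(inherits(raw, "lfp_array"))
  if (target_fs > raw$fs_hz)
    stop("target_fs exceeds the recorded sampling rate")
  fac <- raw$fs_hz / target_fs
  if (abs(fac - round(fac)) > 1e-9)
    stop("raw fs must be an integer multiple of target_fs")
  fac <- as.integer(round(fac))
  dt_new <- 1000 / target_fs
  span <- c(raw$time_ms[1], raw$time_ms[length(raw$time_ms)] + 1000 / raw$fs_hz)
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9)
    stop("requested window lies outside the recorded span")

  x <- raw$data
  if (fac > 1L) {
    bf <- signal::butter(8, 0.8 * target_fs / raw$fs_hz, type = "low")
    x <- t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
    keep <- seq(1L, ncol(x), by = fac)
    x <- x[, keep, drop = FALSE]
  }
  t_new <- raw$time_ms[seq(1L, length(raw$time_ms), by = fac)]
  sel <- t_new >= window[1] - 1e-9 & t_new < window[2] - 1e-9
  lfp_array(x[, sel, drop = FALSE], t_new[sel], target_fs,
            electrode_id = raw$electrode_id, region = raw$region,
            session_id = raw$session_id, subject_id = raw$subject_id)
}
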