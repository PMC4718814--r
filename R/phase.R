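#' Time-frequency phase and power maps of single-trial LFP
#'
#' Band-passes each trial with a zero-phase Butterworth filter and takes the
#' analytic signal, returning instantaneous phase (radians, wrapped to
#' (-pi, pi]) and power per frequency band. Default bands are octave-spaced.
#'
#' @param arr an [lfp_array()].
#' @param bands list of `c(lo, hi)` band edges in Hz; all edges must be below
#'   the Nyquist frequency.
#' @param order Butterworth order (applied twice via forward-backward
#'   filtering).
#' @return list with `phase` and `power`, each a trials x bands x time array,
#'   plus `bands` and `time_ms`.
#' @examples
#' tms <- time_grid(c(0, 1000), 100)
#' arr <- lfp_array(matrix(sin(2 * pi * 6 * tms / 1000), 1), tms, 100)
#' m <- phase_power_map(arr, bands = list(c(4, 8)))
#' @export
phase_power_map <- function(arr, bands = list(c(2, 4), c(4, 8),
                                              c(8, 16), c(16, 32)),
                            order = 3) {
  stopifnot(inherits(arr, "lfp_array"))
  nyq <- arr$fs_hz / 2
  for (b in bands)
    if (max(b) >= nyq) stop("band edge at or above the Nyquist frequency")
  nt <- nrow(arr$data); np <- ncol(arr$data); nb <- length(bands)
  phase <- array(NA_real_, c(nt, nb, np))
  power <- array(NA_real_, c(nt, nb, np))
  for (bi in seq_len(nb)) {
    bf <- signal::butter(order, bands[[bi]] / nyq, type = "pass")
    for (i in seq_len(nt)) {
      xf <- signal::filtfilt(bf, arr$data[i, ])
      a <- analytic_signal(xf)
      phase[i, bi, ] <- Arg(a)
      power[i, bi, ] <- Mod(a)^2
    }
  }
  list(phase = phase, power = power, bands = bands, time_ms = arr$time_ms)
}

# analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}
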