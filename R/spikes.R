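#' Generative model for task-coupled spike rasters
#'
#' Units fire as inhomogeneous Poisson processes whose rate combines a
#' baseline, an early kernel carrying the left-minus-right action value
#' difference, a late kernel carrying the chosen action, and a mid-trial
#' kernel carrying chosen value and/or the trial's latent waveform latency.
#' This emulates the early action-value to late chosen-action transition
#' seen in prefrontal units, with optional coupling to LFP dynamics.
#'
#' The `mediation` knob routes chosen-value drive through the latency latent:
#' at 0 the mid-trial chosen-value signal is direct (`z(chosen value)`), at 1
#' it is carried entirely by the (value-correlated) latent `-z(tau)`; between,
#' a convex mixture. `latent_gain` adds pure latent coupling irrespective of
#' value.
#'
#' Kernels are unit-peak Gaussians; gains are in Hz at the kernel peak per
#' z-scored regressor.
#'
#' @param baseline_hz baseline rate (>= 0).
#' @param early_gain,late_gain,cv_gain,latent_gain kernel gains (Hz).
#' @param mediation fraction in [0, 1] of chosen-value drive routed through
#'   the latency latent.
#' @param early_peak_ms,late_peak_ms,mid_peak_ms,kernel_sd_ms kernel shapes.
#' @return object of class `spike_model`.
#' @export
spike_model <- function(baseline_hz = 10, early_gain = 4, late_gain = 5,
                        cv_gain = 3, latent_gain = 3, mediation = 0,
                        early_peak_ms = 300, late_peak_ms = 700,
                        mid_peak_ms = 500, kernel_sd_ms = 120) {
  if (baseline_hz < 0) stop("baseline rate must be non-negative")
  stopifnot(mediation >= 0, mediation <= 1)
  structure(list(baseline_hz = baseline_hz, early_gain = early_gain,
                 late_gain = late_gain, cv_gain = cv_gain,
                 latent_gain = latent_gain, mediation = mediation,
                 early_peak_ms = early_peak_ms, late_peak_ms = late_peak_ms,
                 mid_peak_ms = mid_peak_ms, kernel_sd_ms = kernel_sd_ms),
            class = "spike_model")
}

#' Construct a spike raster
#'
#' @param spike_times list with one numeric vector of spike times (ms,
#'   relative to choice onset) per trial.
#' @param window recording window `c(t0, t1)` in ms.
#' @param unit_id,region,electrode_id metadata.
#' @return object of class `spike_raster`.
#' @export
spike_raster <- function(spike_times, window = c(-1000, 2000),
                         unit_id = 1L, region = "DLPFC", electrode_id = 1L) {
  stopifnot(is.list(spike_times))
  structure(list(spike_times = lapply(spike_times, sort),
                 window = window, unit_id = unit_id, region = region,
                 electrode_id = electrode_id),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> unit %s (%s), %d trials, [%g, %g] ms, %.1f Hz mean\n",
              x$unit_id, x$region, length(x$spike_times),
              x$window[1], x$window[2],
              mean(vapply(x$spike_times, length, 1L)) /
                diff(x$window) * 1000))
  invisible(x)
}

#' Simulate inhomogeneous-Poisson spike rasters coupled to task and latents
#'
#' Each unit draws a selectivity sign applied to both its action-value and
#' chosen-action kernels (so early value-difference and late choice
#' selectivities correlate across units, as in prefrontal populations).
#' Rates are rectified at zero; spikes are drawn per 1 ms bin.
#'
#' @param trials a [sim_trials()] table.
#' @param model a [spike_model()].
#' @param latents per-trial latency latent tau (ms), usually one electrode's
#'   `tau` column of the [sim_lfp()] ground-truth table. `NULL` disables
#'   latent and mediated coupling.
#' @param n_units number of units to simulate.
#' @param window raster window (ms).
#' @param seed master seed.
#' @return list of [spike_raster()], with attribute `prefs` (per-unit
#'   selectivity signs).
#' @export
sim_spikes <- function(trials, model = spike_model(), latents = NULL,
                       n_units = 1, window = c(-1000, 2000), seed = NULL) {
  stopifnot(inherits(model, "spike_model"))
  if (!is.null(seed)) set.seed(derive_seed(seed, "spikes"))
  n <- nrow(trials)
  if (!is.null(latents) && length(latents) != n)
    stop("latents must align with trials")

  dt <- 1  # ms
  tms <- seq(window[1] + dt / 2, window[2] - dt / 2, by = dt)
  kern <- function(mu) exp(-0.5 * ((tms - mu) / model$kernel_sd_ms)^2)
  k_early <- kern(model$early_peak_ms)
  k_late <- kern(model$late_peak_ms)
  k_mid <- kern(model$mid_peak_ms)

  z_dv <- zscore(trials$value_left - trials$value_right)
  z_cv <- zscore(trials$chosen_value)
  side <- side_sign(trials)
  z_lat <- if (is.null(latents)) rep(0, n) else zscore(latents)
  # mid-trial chosen-value drive: direct vs routed through the latent
  cv_drive <- (1 - model$mediation) * z_cv + model$mediation * (-z_lat)

  prefs <- sample(c(-1, 1), n_units, replace = TRUE)
  rasters <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    p <- prefs[u]
    st <- vector("list", n)
    for (i in seq_len(n)) {
      rate <- model$baseline_hz +
        p * model$early_gain * k_early * z_dv[i] +
        p * model$late_gain * k_late * side[i] +
        model$cv_gain * k_mid * cv_drive[i] +
        model$latent_gain * k_mid * z_lat[i]
      rate <- pmax(rate, 0)
      counts <- rpois(length(tms), rate * dt / 1000)
      idx <- rep.int(seq_along(tms), counts)
      st[[i]] <- tms[idx] + runif(length(idx), -dt / 2, dt / 2)
    }
    rasters[[u]] <- spike_raster(st, window, unit_id = u)
  }
  attr(rasters, "prefs") <- prefs
  rasters
}
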