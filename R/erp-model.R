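#' Canonical evoked-response template
#'
#' Difference of two gamma-shaped bumps: a fast early positive deflection and
#' a slower, larger late wave of opposite sign. The exact shape is a free
#' parameter of the generator -- the analysis pipeline must not depend on it.
#' Each bump `(t/tp)^a * exp(a * (1 - t/tp))` peaks at `tp` with height 1.
#'
#' @param time_ms sample times (ms, relative to choice onset).
#' @param early_peak_ms,early_shape,late_peak_ms,late_shape bump peak times
#'   and sharpness.
#' @param late_gain amplitude of the late wave relative to the early bump.
#' @return numeric vector, one value per sample; zero before onset.
#' @export
erp_template <- function(time_ms, early_peak_ms = 150, early_shape = 4,
                         late_peak_ms = 550, late_shape = 6,
                         late_gain = 1.2) {
  bump <- function(t, tp, a) {
    y <- rep(0, length(t))
    pos <- t > 0
    y[pos] <- (t[pos] / tp)^a * exp(a * (1 - t[pos] / tp))
    y
  }
  bump(time_ms, early_peak_ms, early_shape) -
    late_gain * bump(time_ms, late_peak_ms, late_shape)
}

#' Generative model for single-trial evoked LFPs
#'
#' Parameterises how task variables drive the single-trial waveform: the
#' trial's response is `(1 + a_i) * g(t - tau_i) + noise`, where the
#' amplitude latent `a_i` follows the z-scored value sum and the latency
#' latent `tau_i` (ms; positive = later) is pushed *earlier* by higher
#' chosen value and by error trials, plus region-shared and electrode-local
#' Gaussian latents.
#'
#' Units: `amp_gain` is amplitude fraction per z-scored value sum;
#' `latency_gain` is ms of latency advance per z-scored chosen value;
#' `latency_error` is the additional advance (ms) on error trials; the
#' `sigma_*` are SDs of the corresponding Gaussian terms (ms for latency,
#' amplitude fraction for `sigma_amp`, signal units for `sigma_noise`).
#'
#' @param template function of `time_ms` returning the template waveform g.
#' @param amp_gain,sigma_amp amplitude latent: value-driven gain and noise SD.
#' @param latency_gain,latency_error value/error effects on latency (ms).
#' @param sigma_shared,sigma_local region-shared and electrode-local latency
#'   SDs (ms).
#' @param sigma_noise additive white noise SD per sample.
#' @param max_latency_ms latency shifts beyond this bound abort generation
#'   (they would push the template outside the analysis window).
#' @return object of class `erp_model`.
#' @export
erp_model <- function(template = erp_template,
                      amp_gain = 0.15, sigma_amp = 0.1,
                      latency_gain = 10, latency_error = 15,
                      sigma_shared = 15, sigma_local = 5,
                      sigma_noise = 0.1, max_latency_ms = 150) {
  stopifnot(is.function(template),
            sigma_amp >= 0, sigma_shared >= 0, sigma_local >= 0,
            sigma_noise >= 0, max_latency_ms > 0)
  structure(list(template = template, amp_gain = amp_gain,
                 sigma_amp = sigma_amp, latency_gain = latency_gain,
                 latency_error = latency_error, sigma_shared = sigma_shared,
                 sigma_local = sigma_local, sigma_noise = sigma_noise,
                 max_latency_ms = max_latency_ms),
            class = "erp_model")
}

# shift a sampled waveform by tau ms via linear interpolation on a shifted
# grid, padding with the boundary value (avoids wrap-around artifacts)
shift_waveform <- function(g, time_ms, tau) {
  stats::approx(time_ms, g, xout = time_ms - tau, rule = 2)$y
}

#' Simulate multi-electrode evoked LFPs with value-coupled latents
#'
#' For each region, every trial draws a region-shared latency latent; every
#' electrode adds a local latent. Trial i on electrode e is
#' `(1 + a_ie) * g(t - tau_ie) + noise`. The per-trial, per-electrode latents
#' are returned in a ground-truth side table (`attr(x, "truth")`), which is
#' what downstream recovery tests read -- they never re-derive latents.
#'
#' @param trials a [sim_trials()] table.
#' @param model an [erp_model()].
#' @param n_electrodes_per_region electrodes simulated per region.
#' @param regions character vector of region labels.
#' @param window,fs_hz analysis window (ms, half-open) and sampling rate.
#' @param seed master seed.
#' @return list of [lfp_array()] (one per electrode) with attribute `truth`:
#'   a data.frame with columns `trial_id`, `region`, `electrode_id`, `tau`,
#'   `amp`, `tau_value`, `tau_error`, `tau_shared`, `tau_local`.
#' @examples
#' tr <- sim_trials(50, seed = 1)
#' lfp <- sim_lfp(tr, erp_model(), n_electrodes_per_region = 2, seed = 1)
#' head(attr(lfp, "truth"))
#' @export
sim_lfp <- function(trials, model = erp_model(),
                    n_electrodes_per_region = 4, regions = "DLPFC",
                    window = c(-200, 1000), fs_hz = 100, seed = NULL) {
  stopifnot(inherits(model, "erp_model"), n_electrodes_per_region >= 1)
  if (!is.null(seed)) set.seed(derive_seed(seed, "lfp"))
  tms <- time_grid(window, fs_hz)
  g <- model$template(tms)
  n <- nrow(trials)
  z_cv <- zscore(trials$chosen_value)
  z_vsum <- zscore(trials$value_left + trials$value_right)

  out <- list()
  truth <- list()
  eid <- 0L
  for (r in regions) {
    tau_shared <- rnorm(n, 0, model$sigma_shared)
    for (e in seq_len(n_electrodes_per_region)) {
      eid <- eid + 1L
      tau_local <- rnorm(n, 0, model$sigma_local)
      tau_value <- -model$latency_gain * z_cv
      tau_error <- -model$latency_error * as.numeric(trials$is_error)
      tau <- tau_value + tau_error + tau_shared + tau_local
      if (any(abs(tau) > model$max_latency_ms))
        stop("latency shift exceeds max_latency_ms: template would leave the analysis window")
      amp <- model$amp_gain * z_vsum + rnorm(n, 0, model$sigma_amp)
      dat <- matrix(0, n, length(tms))
      for (i in seq_len(n))
        dat[i, ] <- (1 + amp[i]) * shift_waveform(g, tms, tau[i])
      if (model$sigma_noise > 0)
        dat <- dat + matrix(rnorm(n * length(tms), 0, model$sigma_noise),
                            n, length(tms))
      out[[eid]] <- lfp_array(dat, tms, fs_hz, electrode_id = eid,
                              region = r, session_id = trials$session_id[1])
      truth[[eid]] <- data.frame(
        trial_id = trials$trial_id, region = r, electrode_id = eid,
        tau = tau, amp = amp, tau_value = tau_value, tau_error = tau_error,
        tau_shared = tau_shared, tau_local = tau_local,
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "template") <- g
  attr(out, "time_ms") <- tms
  out
}
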