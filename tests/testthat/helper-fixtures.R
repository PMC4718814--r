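# Shared fixtures, all generated in code.

# a tiny deterministic trial table with both trial types and known values
tiny_trials <- function(n = 8) {
  tr <- data.frame(
    trial_id = seq_len(n),
    session_id = 1L,
    trial_type = rep(c("effort", "delay"), length.out = n),
    reward_left = rep(c(4L, 1L, 3L, 2L), length.out = n),
    reward_right = rep(c(1L, 4L, 2L, 3L), length.out = n),
    cost_left = rep(c(1L, 4L, 2L, 3L), length.out = n),
    cost_right = rep(c(4L, 1L, 3L, 2L), length.out = n),
    stringsAsFactors = FALSE)
  tr$value_left <- tr$reward_left - tr$cost_left
  tr$value_right <- tr$reward_right - tr$cost_right
  tr$chosen_side <- rep(c("L", "R"), length.out = n)
  tr$chosen_value <- ifelse(tr$chosen_side == "L", tr$value_left,
                            tr$value_right)
  tr$unchosen_value <- ifelse(tr$chosen_side == "L", tr$value_right,
                              tr$value_left)
  tr$is_error <- tr$chosen_value < tr$unchosen_value
  tr$rt_ms <- NA_real_
  class(tr) <- c("trial_table", "data.frame")
  tr
}

# a noise-free single-electrode lfp_array built directly from a template
template_array <- function(n_trials, tau = NULL, amp = NULL,
                           window = c(-200, 1000), fs = 100,
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tms <- time_grid(window, fs)
  g <- erp_template(tms)
  if (is.null(tau)) tau <- rep(0, n_trials)
  if (is.null(amp)) amp <- rep(0, n_trials)
  dat <- t(vapply(seq_len(n_trials), function(i)
    (1 + amp[i]) * stats::approx(tms, g, xout = tms - tau[i], rule = 2)$y,
    numeric(length(tms))))
  if (noise_sd > 0)
    dat <- dat + matrix(rnorm(length(dat), 0, noise_sd), nrow(dat))
  lfp_array(dat, tms, fs)
}

# homogeneous-Poisson raster at a fixed rate
poisson_raster <- function(n_trials, rate_hz, window = c(0, 1000),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- diff(window)
  st <- lapply(seq_len(n_trials), function(i) {
    k <- rpois(1, rate_hz * span / 1000)
    sort(runif(k, window[1], window[2]))
  })
  spike_raster(st, window = window)
}
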