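#' Winner-take-all attractor network configuration
#'
#' Parameters of the spiking decision network: 2000 leaky integrate-and-fire
#' neurons (1600 excitatory, 400 inhibitory), two selective excitatory pools
#' of fraction `f = 0.15` each (240 cells) plus a non-selective pool (1120),
#' all-to-all connectivity with within-pool potentiation `w_plus = 1.7` and
#' cross-pool depression `w_minus = 1 - f (w_plus - 1) / (1 - f)`. All cells
#' receive 2.4 kHz background Poisson input through AMPA synapses; selective
#' pools additionally receive value-coding Poisson input whose per-trial mean
#' is uniform on 20--60 Hz and whose instantaneous rate is resampled every
#' 50 ms from a Gaussian with SD 10 Hz (rectified at zero). A trial runs
#' 500 ms without selective input, then 2500 ms with it.
#'
#' The neuron and synapse constants (conductance-based AMPA/NMDA/GABA
#' synapses; see the `neuron_E`, `neuron_I` and `syn` entries) are the
#' standard parameter set of this two-pool decision-network family and are
#' fully editable here.
#'
#' @param N_total,N_I total and inhibitory cell counts.
#' @param f selective fraction of the excitatory population.
#' @param w_plus within-pool excitatory weight.
#' @param w_minus cross-pool weight; default from [w_minus_formula()].
#' @param bg_rate_khz background Poisson rate per cell (kHz).
#' @param input_range uniform range (Hz) of per-trial input means.
#' @param input_sd Gaussian SD (Hz) of the 50-ms resampled input rate.
#' @param resample_ms input resampling interval.
#' @param t_init_ms,t_stim_ms initialisation and stimulus durations.
#' @param dt_ms integration step; 0.02 ms default, 0.1 ms is the documented
#'   fast mode.
#' @param neuron_E,neuron_I,syn parameter lists (see defaults).
#' @return object of class `network_config`.
#' @export
network_config <- function(N_total = 2000L, N_I = 400L, f = 0.15,
                           w_plus = 1.7, w_minus = NULL,
                           bg_rate_khz = 2.4, input_range = c(20, 60),
                           input_sd = 10, resample_ms = 50,
                           t_init_ms = 500, t_stim_ms = 2500,
                           dt_ms = 0.02,
                           neuron_E = list(Cm_nF = 0.5, gL_nS = 25,
                                           EL_mV = -70, Vth_mV = -50,
                                           Vreset_mV = -55, tref_ms = 2),
                           neuron_I = list(Cm_nF = 0.2, gL_nS = 20,
                                           EL_mV = -70, Vth_mV = -50,
                                           Vreset_mV = -55, tref_ms = 1),
                           syn = list(g_ext_ampa_E_nS = 2.1,
                                      g_ext_ampa_I_nS = 1.62,
                                      g_rec_ampa_E_nS = 0.05,
                                      g_rec_ampa_I_nS = 0.04,
                                      g_nmda_E_nS = 0.165,
                                      g_nmda_I_nS = 0.13,
                                      g_gaba_E_nS = 1.3,
                                      g_gaba_I_nS = 1.0,
                                      tau_ampa_ms = 2,
                                      tau_nmda_rise_ms = 2,
                                      tau_nmda_decay_ms = 100,
                                      alpha_per_ms = 0.5,
                                      tau_gaba_ms = 5,
                                      V_E_mV = 0, V_I_mV = -70,
                                      Mg_mM = 1)) {
  N_E <- N_total - N_I
  n_sel <- round(f * N_E)
  n_ns <- N_E - 2L * n_sel
  if (is.null(w_minus)) w_minus <- w_minus_formula(w_plus, f)
  cfg <- list(N_total = as.integer(N_total), N_I = as.integer(N_I),
              N_E = as.integer(N_E), f = f,
              n_selective = as.integer(n_sel),
              n_nonselective = as.integer(n_ns),
              w_plus = w_plus, w_minus = w_minus,
              bg_rate_khz = bg_rate_khz, input_range = input_range,
              input_sd = input_sd, resample_ms = resample_ms,
              t_init_ms = t_init_ms, t_stim_ms = t_stim_ms,
              t_total_ms = t_init_ms + t_stim_ms, dt_ms = dt_ms,
              neuron_E = neuron_E, neuron_I = neuron_I, syn = syn)
  if (cfg$N_E + cfg$N_I != cfg$N_total)
    stop("excitatory and inhibitory counts do not sum to N_total")
  if (2L * cfg$n_selective + cfg$n_nonselective != cfg$N_E)
    stop("pool sizes do not sum to the excitatory count")
  if (!(cfg$w_minus < 1 && 1 < cfg$w_plus))
    stop("weights must satisfy w_minus < 1 < w_plus")
  class(cfg) <- "network_config"
  cfg
}

#' Cross-pool synaptic depression from the potentiation level
#'
#' `w_minus = 1 - f (w_plus - 1) / (1 - f)`: the Hebbian-balance value that
#' keeps total excitatory drive constant as within-pool weights potentiate.
#' At the defaults (`w_plus` 1.7, `f` 0.15) it is 0.8765 to four decimals.
#'
#' @param w_plus within-pool weight.
#' @param f selective fraction.
#' @export
w_minus_formula <- function(w_plus = 1.7, f = 0.15) {
  1 - f * (w_plus - 1) / (1 - f)
}

#' Build a network realisation from a configuration
#'
#' Checks the configuration invariants and materialises the pool structure
#' and the pool-to-pool excitatory weight matrix (within-pool `w_plus`,
#' cross-pool and non-selective-to-selective `w_minus`, all other weights 1).
#'
#' @param config a [network_config()].
#' @return object of class `lif_network` with `pools` (named sizes),
#'   `weights` (4 x 4 pool weight matrix, rows = source) and the config.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  pools <- c(A = config$n_selective, B = config$n_selective,
             NS = config$n_nonselective, I = config$N_I)
  W <- matrix(1, 4, 4, dimnames = list(names(pools), names(pools)))
  W["A", "A"] <- config$w_plus
  W["B", "B"] <- config$w_plus
  W["A", "B"] <- config$w_minus
  W["B", "A"] <- config$w_minus
  W["NS", "A"] <- config$w_minus
  W["NS", "B"] <- config$w_minus
  structure(list(pools = pools, weights = W, config = config),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat(sprintf("<lif_network> pools A/B/NS/I = %d/%d/%d/%d, w+ = %g, w- = %.4f\n",
              x$pools["A"], x$pools["B"], x$pools["NS"], x$pools["I"],
              x$config$w_plus, x$config$w_minus))
  invisible(x)
}

#' Draw per-trial input means
#'
#' Input means for the two options are drawn independently from a uniform
#' distribution on `range` Hz (not anticorrelated).
#'
#' @param n number of trials.
#' @param range uniform range in Hz.
#' @param seed optional seed.
#' @return data.frame with `mu_A`, `mu_B`.
#' @export
sample_inputs <- function(n = 1, range = c(20, 60), seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "inputs"))
  data.frame(mu_A = runif(n, range[1], range[2]),
             mu_B = runif(n, range[1], range[2]))
}

# piecewise-constant input rate streams: zero during initialisation, then
# Normal(mu, sd) per 50 ms segment, rectified at zero
input_streams <- function(mu_A, mu_B, config) {
  n_seg <- ceiling(config$t_total_ms / config$resample_ms)
  n_init <- floor(config$t_init_ms / config$resample_ms)
  n_stim <- n_seg - n_init
  rA <- c(rep(0, n_init), pmax(rnorm(n_stim, mu_A, config$input_sd), 0))
  rB <- c(rep(0, n_init), pmax(rnorm(n_stim, mu_B, config$input_sd), 0))
  list(rate_A = rA, rate_B = rB)
}

#' Apply the choice readout to pool rate traces
#'
#' The chosen option is the selective pool whose sliding-window rate first
#' exceeds `threshold_hz` while also being at least `margin_hz` above the
#' other pool's rate; if the conditions never hold, no choice is recorded.
#'
#' @param rate_A,rate_B pool rate traces (Hz) on a common time grid.
#' @param time_ms time grid (ms relative to stimulus onset).
#' @param threshold_hz,margin_hz readout parameters (25 and 15 Hz).
#' @return list with `choice` ("A", "B" or "none") and `decision_time_ms`
#'   (NA when no decision).
#' @export
readout <- function(rate_A, rate_B, time_ms, threshold_hz = 25,
                    margin_hz = 15) {
  stopifnot(length(rate_A) == length(rate_B),
            length(rate_A) == length(time_ms))
  valid <- time_ms >= 0
  a <- which(valid & rate_A > threshold_hz & rate_A - rate_B >= margin_hz)
  b <- which(valid & rate_B > threshold_hz & rate_B - rate_A >= margin_hz)
  ta <- if (length(a)) time_ms[a[1]] else Inf
  tb <- if (length(b)) time_ms[b[1]] else Inf
  if (!is.finite(ta) && !is.finite(tb))
    return(list(choice = "none", decision_time_ms = NA_real_))
  if (ta <= tb) list(choice = "A", decision_time_ms = ta)
  else list(choice = "B", decision_time_ms = tb)
}

#' Sliding-window pool rates from spike data
#'
#' Count-based rate: spikes of the pool inside a centred window, divided by
#' window length and pool size.
#'
#' @param spike_times spike times (ms).
#' @param n_cells number of cells in the pool.
#' @param t_eval times (ms) at which to evaluate the rate.
#' @param window_ms sliding-window length (50 ms default).
#' @return rate trace in Hz, one value per `t_eval`.
#' @export
pool_rates <- function(spike_times, n_cells, t_eval, window_ms = 50) {
  s <- sort(spike_times)
  half <- window_ms / 2
  counts <- findInterval(t_eval + half, s) - findInterval(t_eval - half, s)
  counts / n_cells / window_ms * 1000
}

# sliding-window rates from 1-ms pool spike counts; centred window with
# truncation at the edges (no NA padding)
rates_from_counts <- function(counts_ms, n_cells, window_ms = 50) {
  n <- length(counts_ms)
  half <- floor(window_ms / 2)
  cs <- cumsum(c(0, counts_ms))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1) / n_cells * 1000
}

#' Simulate one trial of the attractor network
#'
#' Integrates the network for 500 ms without selective input and 2500 ms
#' with it, applies the choice readout online to the 50-ms sliding pool
#' rates, and returns rate traces plus the summed-activity LFP proxy. The
#' simulation always runs the full 3 s; the decision only labels the trial.
#'
#' @param network a [build_network()] object.
#' @param mu_A,mu_B input means (Hz).
#' @param seed optional seed.
#' @param dt_ms integration step override (defaults to the config).
#' @param record_spikes also return individual spike times and cell ids.
#' @return object of class `trial_sim`: `time_ms` (1-ms grid relative to
#'   stimulus onset), `rates` (time x 4 pools, Hz), `lfp_proxy` (summed
#'   firing rate across all cells, spikes/s), `choice`, `decision_time_ms`,
#'   `mu_A`, `mu_B`, and optionally `spike_times`/`spike_ids`.
#' @export
simulate_trial <- function(network, mu_A, mu_B, seed = NULL, dt_ms = NULL,
                           record_spikes = FALSE) {
  stopifnot(inherits(network, "lif_network"))
  cfg <- network$config
  if (!is.null(seed)) set.seed(derive_seed(seed, "trial_sim"))
  if (is.null(dt_ms)) dt_ms <- cfg$dt_ms
  st <- input_streams(mu_A, mu_B, cfg)
  sim <- lif_simulate_cpp(cfg$n_selective, cfg$n_selective,
                          cfg$n_nonselective, cfg$N_I,
                          cfg$w_plus, cfg$w_minus,
                          cfg$neuron_E, cfg$neuron_I, cfg$syn,
                          st$rate_A, st$rate_B, cfg$resample_ms,
                          cfg$bg_rate_khz, cfg$t_total_ms, dt_ms,
                          record_spikes)
  counts <- sim$counts
  tgrid <- seq_len(nrow(counts)) - 0.5 - cfg$t_init_ms
  rates <- cbind(
    A = rates_from_counts(counts[, 1], cfg$n_selective),
    B = rates_from_counts(counts[, 2], cfg$n_selective),
    NS = rates_from_counts(counts[, 3], cfg$n_nonselective),
    I = rates_from_counts(counts[, 4], cfg$N_I))
  lfp <- rates_from_counts(rowSums(counts), 1)  # summed rate of all cells
  ok <- !is.na(rates[, 1])
  rd <- readout(rates[ok, "A"], rates[ok, "B"], tgrid[ok])
  structure(list(time_ms = tgrid, rates = rates, lfp_proxy = lfp,
                 counts = counts, choice = rd$choice,
                 decision_time_ms = rd$decision_time_ms,
                 mu_A = mu_A, mu_B = mu_B,
                 spike_times = sim$spike_times, spike_ids = sim$spike_ids),
            class = "trial_sim")
}

#' @export
print.trial_sim <- function(x, ...) {
  cat(sprintf("<trial_sim> mu_A = %.1f, mu_B = %.1f Hz -> choice %s%s\n",
              x$mu_A, x$mu_B, x$choice,
              if (!is.na(x$decision_time_ms))
                sprintf(" at %g ms", x$decision_time_ms) else ""))
  invisible(x)
}

#' Simulate an experiment of independent network trials
#'
#' Draws per-trial input means, simulates each trial with an independently
#' derived seed, and collects choices, decision times, pool rate traces and
#' LFP-proxy waveforms (downsampled to `out_fs_hz`) into one dataset in the
#' same shape the empirical pipeline consumes.
#'
#' @param n_trials number of trials (400 in the reference configuration).
#' @param config a [network_config()].
#' @param seed master seed (each trial derives its own stream).
#' @param dt_ms integration step override.
#' @param out_fs_hz sampling rate of the stored traces.
#' @return object of class `network_experiment`: `trials` (data.frame with
#'   mu_A, mu_B, choice, decision_time_ms, chosen_mu, unchosen_mu,
#'   is_error), `lfp` (trials x time matrix), `rates_A`/`rates_B` (trials x
#'   time), `time_ms`, `config`.
#' @export
simulate_experiment <- function(n_trials = 400, config = network_config(),
                                seed = 1, dt_ms = NULL, out_fs_hz = 100) {
  net <- build_network(config)
  mus <- sample_inputs(n_trials, config$input_range, seed = seed)
  step <- as.integer(1000 / out_fs_hz)
  lfp <- NULL
  rA <- NULL
  rB <- NULL
  res <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- simulate_trial(net, mus$mu_A[i], mus$mu_B[i],
                         seed = derive_seed(seed, paste0("exp", i)),
                         dt_ms = dt_ms)
    keep <- seq(step, length(tr$time_ms), by = step)
    if (is.null(lfp)) {
      lfp <- matrix(NA_real_, n_trials, length(keep))
      rA <- matrix(NA_real_, n_trials, length(keep))
      rB <- matrix(NA_real_, n_trials, length(keep))
      time_ms <- tr$time_ms[keep] - 0.5  # snap to the sample grid
    }
    lfp[i, ] <- tr$lfp_proxy[keep]
    rA[i, ] <- tr$rates[keep, "A"]
    rB[i, ] <- tr$rates[keep, "B"]
    res[[i]] <- list(choice = tr$choice, dt = tr$decision_time_ms)
  }
  choice <- vapply(res, function(r) r$choice, "")
  decided <- choice != "none"
  chosen_mu <- ifelse(choice == "A", mus$mu_A, mus$mu_B)
  unchosen_mu <- ifelse(choice == "A", mus$mu_B, mus$mu_A)
  chosen_mu[!decided] <- NA_real_
  unchosen_mu[!decided] <- NA_real_
  trials <- data.frame(
    trial_id = seq_len(n_trials), mu_A = mus$mu_A, mu_B = mus$mu_B,
    choice = choice,
    decision_time_ms = vapply(res, function(r) r$dt, 1),
    chosen_mu = chosen_mu, unchosen_mu = unchosen_mu,
    is_error = decided & (chosen_mu < unchosen_mu))
  structure(list(trials = trials, lfp = lfp, rates_A = rA, rates_B = rB,
                 time_ms = time_ms, config = config),
            class = "network_experiment")
}

#' @export
print.network_experiment <- function(x, ...) {
  dec <- x$trials$choice != "none"
  cat(sprintf("<network_experiment> %d trials (%d decided), median decision time %g ms\n",
              nrow(x$trials), sum(dec),
              median(x$trials$decision_time_ms[dec], na.rm = TRUE)))
  invisible(x)
}

# value-normalised model design: decision variables on the /80 scale
model_design <- function(trials) {
  cbind(intercept = 1,
        choice = ifelse(trials$choice == "A", 1, -1),
        value_diff = (trials$mu_A - trials$mu_B) / 80,
        chosen_value = trials$chosen_mu / 80)
}

#' Decision-variable regression on model pool rates
#'
#' Regresses the A-selective pool's firing rate, per timebin, on an
#' intercept, a chose-A indicator, the input value difference
#' `(mu_A - mu_B)/80` and the chosen value `mu_chosen/80`, across decided
#' trials. Mirrors the unit-level analysis of recorded neurons: value
#' difference dominates early, the chosen action late.
#'
#' @param experiment a [simulate_experiment()] result.
#' @return a `unit_regression` (coefficients, Z, CPD per factor per bin),
#'   with attribute `n_undecided`.
#' @export
model_regression <- function(experiment) {
  stopifnot(inherits(experiment, "network_experiment"))
  dec <- experiment$trials$choice != "none"
  if (!any(dec)) stop("all trials undecided; cannot fit the decision model")
  if (sum(dec) < 100)
    warning("only ", sum(dec), " decided trials; coefficients will be noisy")
  X <- model_design(experiment$trials[dec, ])
  R <- experiment$rates_A[dec, , drop = FALSE]
  out <- fit_timecourse(R, X, c("value_diff", "choice", "chosen_value"),
                        experiment$time_ms)
  attr(out, "n_undecided") <- sum(!dec)
  out
}

#' PCA of the model's LFP proxy and its coupling to model firing
#'
#' Runs the same stacked-trial decomposition on the network's summed-activity
#' waveforms as on recorded LFP, identifies the latency-like component by
#' derivative similarity (sign-aligned so that larger weights mean earlier
#' waveforms), regresses its single-trial weights on the model's decision
#' variables and decision time, and measures how including the component as
#' a coregressor changes the chosen-value CPD in A-pool firing (against a
#' noise-component control model).
#'
#' @param experiment a [simulate_experiment()] result.
#' @param window analysis window (ms relative to stimulus onset) for the
#'   decomposition.
#' @return list: `pca` (the `lfp_pca`), `latency` ([latency_component()]
#'   output), `weights` (per-decided-trial latency weights),
#'   `weight_regression` (coefficient table incl. orthogonalised decision
#'   time), `reduction` (per-factor CPD with the component vs noise-control
#'   coregressors), `decided` (logical).
#' @export
model_lfp_analysis <- function(experiment, window = c(-200, 1500)) {
  stopifnot(inherits(experiment, "network_experiment"))
  arr <- lfp_array(experiment$lfp, experiment$time_ms,
                   fs_hz = 1000 / diff(experiment$time_ms[1:2]),
                   region = "model")
  st <- stack_trials(arr, window = window)
  fit <- decompose_lfp(st, exclude = rep(FALSE, nrow(st$X)),
                       sign_anchors = list())
  # identify the latency component by crossing times: the model's summed
  # activity is a ramp whose single-trial amplitude barely varies, so the
  # crossing criterion is the reliable one here
  lat <- latency_component(fit, window = c(0, min(1400, max(fit$time_ms))),
                           method = "crossing")
  # orient the component so its weights index earliness
  if (lat$lag_cor > 0) {
    fit$V[, lat$component] <- -fit$V[, lat$component]
    fit$U[, lat$component] <- -fit$U[, lat$component]
    lat$lag_cor <- -lat$lag_cor
    lat$r <- -lat$r
  }
  w_all <- coef(fit)[, lat$component]
  dec <- experiment$trials$choice != "none"
  tr <- experiment$trials[dec, ]
  w <- w_all[dec]
  ptr <- data.frame(chosen_value = tr$chosen_mu / 80,
                    unchosen_value = tr$unchosen_mu / 80,
                    is_error = tr$is_error,
                    rt_ms = tr$decision_time_ms)
  wreg <- pc_weight_regression(w, ptr, include_rt = TRUE,
                               zscore_values = FALSE)

  X <- model_design(tr)
  ctl <- noise_components(fit)
  C <- coef(fit)[dec, ctl, drop = FALSE]
  R <- experiment$rates_A[dec, , drop = FALSE]
  factors <- c("value_diff", "choice", "chosen_value")
  m_pc <- fit_timecourse(R, cbind(X, pc = w), factors, experiment$time_ms)
  m_ctl <- fit_timecourse(R, cbind(X, ctl = C), factors, experiment$time_ms)
  list(pca = fit, latency = lat, weights = w, weight_regression = wreg,
       reduction = list(delta_cpd = m_ctl$cpd - m_pc$cpd,
                        cpd_pc_model = m_pc$cpd,
                        cpd_control_model = m_ctl$cpd,
                        bin_centers_ms = experiment$time_ms),
       decided = dec)
}
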