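#' Simulate multi-subject virtual-electrode (MEG-like) datasets
#'
#' Each subject contributes a single virtual electrode whose trials follow
#' the same generative evoked model as [sim_lfp()], then the whole subject's
#' data is multiplied by a random sign in {+1, -1} -- emulating the arbitrary
#' sign ambiguity that source reconstruction introduces per subject. The
#' applied signs are recorded so alignment procedures can be validated.
#' Reaction times are generated as
#' `rt = base - value_slope * chosen_value + latent_gain * tau + noise`,
#' truncated to be positive: faster decisions for higher-valued choices, and
#' slower ones on trials whose waveform latent is late.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param trials_per_subject trials per subject.
#' @param model an [erp_model()].
#' @param rt_model list with `base_ms`, `value_slope` (ms per value level),
#'   `latent_gain` (ms per ms of tau) and `noise_sd` (ms).
#' @param window,fs_hz analysis window and sampling rate.
#' @param seed master seed.
#' @return list with `lfp` (list of [lfp_array()], one per subject, with
#'   `subject_id` set), `trials` (row-bound trial table, `session_id` =
#'   subject, `rt_ms` filled), `signs` (applied per-subject signs) and
#'   `truth` (latent side table).
#' @export
sim_meg_subjects <- function(n_subjects, trials_per_subject = 200,
                             model = erp_model(),
                             rt_model = list(base_ms = 800, value_slope = 30,
                                             latent_gain = 1, noise_sd = 100),
                             window = c(-200, 1000), fs_hz = 100,
                             seed = NULL) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (!is.null(seed)) set.seed(derive_seed(seed, "meg"))
  signs <- sample(c(-1, 1), n_subjects, replace = TRUE)

  lfp <- vector("list", n_subjects)
  trs <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    tr <- sim_trials(trials_per_subject, session_id = s)
    arrs <- sim_lfp(tr, model, n_electrodes_per_region = 1,
                    regions = "vmPFC", window = window, fs_hz = fs_hz)
    gt <- attr(arrs, "truth")
    arr <- arrs[[1]]
    arr$data <- signs[s] * arr$data
    arr$electrode_id <- s
    arr$session_id <- s
    arr$subject_id <- s
    gt$electrode_id <- s
    rt <- rt_model$base_ms - rt_model$value_slope * tr$chosen_value +
      rt_model$latent_gain * gt$tau +
      rnorm(trials_per_subject, 0, rt_model$noise_sd)
    tr$rt_ms <- pmax(rt, 50)
    lfp[[s]] <- arr
    trs[[s]] <- tr
    truth[[s]] <- gt
  }
  list(lfp = lfp, trials = do.call(rbind, trs), signs = signs,
       truth = do.call(rbind, truth))
}
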